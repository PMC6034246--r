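#' Pipeline configuration
#'
#' Collects the thresholds and test settings used across the pipeline
#' stages.  Defaults: 5% common/low-frequency split, 1% reference-panel
#' frequency cutoff, 75% conservation-index cutoff, 40% heteroplasmic-
#' fraction metabolic threshold, alpha 0.05, Beta(1, 25) SKAT weights.
#'
#' @param common_threshold,panel_threshold,ci_threshold,hf_threshold
#'   Percent thresholds (all strict comparisons).
#' @param alpha Significance level for reporting.
#' @param expected_min Expected-count rule for the chi-square/exact switch.
#' @param skat_method,skat_B,weight_shape SKAT settings.
#' @param min_stars Minimum combined protein rating to shortlist.
#' @param seed Seed recorded in the manifest and used for any stochastic
#'   step.
#' @param outdir Output directory for report tables (`NULL` = do not
#'   write).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(common_threshold = 5, panel_threshold = 1,
                            ci_threshold = 75, hf_threshold = 40,
                            alpha = 0.05, expected_min = 5,
                            skat_method = "moment", skat_B = 2000,
                            weight_shape = c(1, 25), min_stars = 2,
                            seed = 1, outdir = NULL) {
  thr <- c(common_threshold, panel_threshold, ci_threshold, hf_threshold)
  if (any(thr <= 0 | thr >= 100)) abort("thresholds must lie in (0, 100)")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "pipeline_config")
}

#' Run the full case-control analysis pipeline
#'
#' Orchestrates the analysis end to end on a cohort (typically a
#' `mito_cohort` from [generate_cohort()], or an equivalent list built
#' from files): (1) allele grouping and per-gene carrier enrichment,
#' (2) burden-ratio-stratified SKAT per gene plus burden-interaction tests
#' among genes with associated positive allele sets, (3) pathogenicity
#' annotation — combined three-tool ratings with the HF threshold for
#' protein alleles, and the frequency/conservation/structure criterion for
#' tRNA alleles — and (5) phenotype comparison between case carriers and
#' non-carriers of the flagged alleles.  Any stage failure aborts with an
#' error naming the stage, and partially written report files are removed.
#'
#' @param cohort A `mito_cohort` (or compatible list with at least
#'   `observations`, `phenotypes` and `reference`; `ratings`,
#'   `panel_counts`, `panels`, `structures` enable the annotation stage).
#' @param config A [pipeline_config()].
#' @param gene_map Gene map, by default [mt_genes()].
#' @return List of class `mito_report`: `step1_enrichment`,
#'   `step1_burden`, `step2_association`, `step2_interaction`,
#'   `step3_protein`, `step3_trna`, `step5_phenotype`, `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         gene_map = mt_genes()) {
  stopifnot(inherits(config, "pipeline_config"))
  written <- character(0)
  emit <- function(tbl, name) {
    if (!is.null(config$outdir) && !is.null(tbl)) {
      dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
      p <- file.path(config$outdir, paste0(name, ".tsv"))
      write_tsv(tbl, p, progress = FALSE)
      written <<- c(written, p)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  obs <- cohort$observations
  if (!("hf" %in% names(obs))) obs <- compute_hf(obs)
  n_case <- n_distinct(obs$sample_id[obs$cohort == "case"])
  n_ctrl <- n_distinct(obs$sample_id[obs$cohort == "control"])

  # Step 1: grouping, enrichment, per-individual burden
  step1 <- stage("enrichment", {
    enrichment_table(obs, gene_map, expected_min = config$expected_min)
  })
  emit(step1, "step1_enrichment")
  burden <- stage("burden", burden_per_individual(obs, gene_map))
  emit(burden, "step1_burden")

  # Step 2: burden-ratio-stratified SKAT and interactions
  step2 <- stage("association", {
    skat_by_gene(obs, gene_map, reference = cohort$reference,
                 method = config$skat_method,
                 weight_shape = config$weight_shape,
                 B = config$skat_B, seed = config$seed)
  })
  emit(step2, "step2_association")
  interactions <- stage("interaction", {
    hits <- step2 |> filter(.data$allele_set == "positive",
                            .data$p_value < config$alpha)
    pairs <- if (nrow(hits) >= 2) utils::combn(hits$gene, 2) else NULL
    if (is.null(pairs)) NULL else {
      groups <- assign_groups(obs)
      part <- gene_burden_partition(groups, n_case, n_ctrl) |>
        add_gene(gene_map) |> filter(.data$allele_set == "positive")
      out <- map(seq_len(ncol(pairs)), function(j) {
        g1 <- filter(part, .data$gene == pairs[1, j])
        g2 <- filter(part, .data$gene == pairs[2, j])
        fit <- tryCatch(
          interaction_test(genotype_matrix(obs, g1),
                           genotype_matrix(obs, g2),
                           as.numeric(attr(genotype_matrix(obs, g1),
                                           "cohort") == "case")),
          error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        tibble(gene1 = pairs[1, j], gene2 = pairs[2, j],
               statistic = fit$statistic, p_value = fit$p_value,
               method = fit$method)
      })
      list_rbind(out)
    }
  })
  emit(interactions, "step2_interaction")

  assoc_genes <- unique(step2$gene[step2$p_value < config$alpha &
                                     step2$allele_set == "positive"])

  # Step 3a: protein-allele annotation
  step3_protein <- stage("protein_annotation", {
    if (is.null(cohort$ratings) || nrow(cohort$ratings) == 0) NULL else {
      case_hf <- obs |> filter(.data$cohort == "case") |>
        group_by(.data$pos, .data$ref, .data$alt) |>
        summarise(hf = max(.data$hf), .groups = "drop")
      ann <- cohort$ratings |>
        filter(.data$gene %in% assoc_genes) |>
        mutate(stars = combine_ratings(.data$polyphen, .data$sift,
                                       .data$pmut)) |>
        inner_join(case_hf, by = c("pos", "ref", "alt"))
      if (nrow(ann) == 0) NULL else {
        short <- protein_shortlist(ann, config$min_stars,
                                   config$hf_threshold)
        mutate(ann, flagged = paste0(.data$pos, .data$ref, ">", .data$alt)
               %in% paste0(short$pos, short$ref, ">", short$alt))
      }
    }
  })
  emit(step3_protein, "step3_protein")

  # Step 3b: tRNA-allele annotation
  step3_trna <- stage("trna_annotation", {
    if (is.null(cohort$panel_counts) || is.null(cohort$structures)) NULL else {
      groups <- assign_groups(obs)
      cand <- cohort$panel_counts |> filter(.data$gene %in% assoc_genes)
      if (nrow(cand) == 0) NULL else {
        sa <- structural_assessment(cand, cohort$structures)
        ci <- map_dbl(seq_len(nrow(sa)), function(i) {
          panel <- cohort$panels[[sa$gene[i]]]
          if (is.null(panel)) return(NA_real_)
          conservation_index(panel, sa$pos[i])
        })
        case_hf <- obs |> filter(.data$cohort == "case") |>
          group_by(.data$pos, .data$ref, .data$alt) |>
          summarise(hf = max(.data$hf), .groups = "drop")
        sa |>
          left_join(select(groups, "pos", "ref", "alt", "group"),
                    by = c("pos", "ref", "alt")) |>
          mutate(absent_in_controls = .data$group == "case_only",
                 ci = ci) |>
          classify_trna(ci_threshold = config$ci_threshold,
                        panel_threshold = config$panel_threshold) |>
          left_join(case_hf, by = c("pos", "ref", "alt")) |>
          select("gene", "pos", "ref", "alt", "region", "trna_number",
                 "hf", "absent_in_controls", "panel_count", "panel_ok",
                 "ci", "ci_ok", "alteration", "anticodon_loop",
                 "pathogenic")
      }
    }
  })
  emit(step3_trna, "step3_trna")

  # Step 5: genotype-phenotype comparison on flagged alleles
  step5 <- stage("phenotype", {
    flagged <- bind_rows(
      if (!is.null(step3_protein)) filter(step3_protein, .data$flagged),
      if (!is.null(step3_trna)) filter(step3_trna, .data$pathogenic)
    )
    if (is.null(cohort$phenotypes) || nrow(flagged) == 0) NULL else {
      phenotype_comparison_table(obs, cohort$phenotypes, flagged)
    }
  })
  emit(step5, "step5_phenotype")

  manifest <- list(
    package_version = as.character(utils::packageVersion("mitoburden")),
    seed = config$seed,
    thresholds = list(common = config$common_threshold,
                      panel = config$panel_threshold,
                      ci = config$ci_threshold, hf = config$hf_threshold,
                      alpha = config$alpha,
                      expected_min = config$expected_min),
    skat = list(method = config$skat_method, B = config$skat_B,
                weight_shape = config$weight_shape),
    n_cases = n_case, n_controls = n_ctrl,
    n_observations = nrow(obs),
    outputs = basename(written)
  )
  if (!is.null(config$outdir)) {
    mp <- file.path(config$outdir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, mp)
  }
  structure(list(step1_enrichment = step1, step1_burden = burden,
                 step2_association = step2,
                 step2_interaction = interactions,
                 step3_protein = step3_protein, step3_trna = step3_trna,
                 step5_phenotype = step5, manifest = manifest),
            class = "mito_report")
}

#' @export
print.mito_report <- function(x, ...) {
  cat("mitoburden pipeline report\n")
  for (nm in setdiff(names(x), "manifest")) {
    tbl <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(tbl)) "(skipped)" else paste0(nrow(tbl), " rows")))
  }
  invisible(x)
}
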