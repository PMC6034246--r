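#' Anchored bases of the synthetic reference
#'
#' Positions whose bases are pinned in [synthetic_reference()] so that the
#' substitutions used throughout the package documentation and examples
#' (MT-CO3 codon changes, tRNA stem geometries) are consistent with the
#' synthetic sequence.  Codon contexts are chosen to encode the documented
#' amino acids under the vertebrate mitochondrial code.
#'
#' @return Tibble with `pos` and `base` (H-strand).
#' @keywords internal
mt_anchor_bases <- function() {
  codons <- list(
    # MT-CO3 codons 78 (G), 95 (A), 183 (E), 217 (I), 251 (F)
    c(9438, "GGC"), c(9489, "GCC"), c(9753, "GAG"),
    c(9855, "ATC"), c(9957, "TTC")
  )
  codon_tbl <- list_rbind(map(codons, function(x) {
    tibble(pos = as.integer(x[1]) + 0:2,
           base = strsplit(x[2], "")[[1]])
  }))
  trna_tbl <- tibble(
    pos = c(4386L, 5528L, 5557L, 5563L, 5601L, 5628L, 5783L, 5814L,
            12172L, 12178L, 12234L, 12239L, 12248L, 15894L, 15940L),
    base = c("T", "T", "T", "G", "C", "T", "G", "T",
             "A", "C", "A", "C", "A", "G", "T")
  )
  bind_rows(codon_tbl, trna_tbl)
}

#' Synthetic mitochondrial reference sequence
#'
#' A 16,569-base synthetic stand-in for the mitochondrial reference: bases
#' are drawn at random, anchor positions ([mt_anchor_bases()]) are pinned,
#' and within every tRNA gene the 3' member of each cloverleaf stem pair is
#' set to the Watson-Crick complement of its 5' partner (on the gene
#' strand), so tRNA stems are canonically paired as in real tRNAs.  It is
#' NOT the rCRS sequence; analyses of real data should load the actual
#' reference with [read_reference()].
#'
#' @param seed Seed for the random bases.
#' @param gene_map Gene map, by default [mt_genes()].
#' @return Single character string of length 16,569.
#' @export
synthetic_reference <- function(seed = 1, gene_map = mt_genes()) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), MT_GENOME_LENGTH, replace = TRUE)
  anchors <- mt_anchor_bases()
  bases[anchors$pos] <- anchors$base
  for (g in gene_map$gene[gene_map$class == "tRNA"]) {
    st <- trna_structure(g, gene_map)
    stems <- filter(st, !is.na(.data$partner_number),
                    .data$trna_number < .data$partner_number)
    for (i in seq_len(nrow(stems))) {
      five_g <- bases[stems$pos[i]]
      if (st$strand[1] == "L") five_g <- complement_base(five_g)
      partner_gene_strand <- complement_base(five_g)   # Watson-Crick partner
      partner_genomic <- if (st$strand[1] == "L") {
        complement_base(partner_gene_strand)
      } else partner_gene_strand
      bases[stems$partner_pos[i]] <- partner_genomic
    }
  }
  paste(bases, collapse = "")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study design the package targets: 52 cases and 104
#' controls; a shared population allele pool with a 1/f frequency spectrum
#' (hence a large excess of alleles carried by fewer than 5% of a cohort)
#' plus cohort-private singleton alleles; bimodal heteroplasmic fractions
#' (a near-homoplasmic component uniform on 95-100% and an intermediate
#' component uniform on 40-80%); and per-site read depths from a normal
#' with mean 3251.22 and SD 964.63 truncated to the observed range
#' 2027.23-5612.43.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_pool Number of shared-pool polymorphic sites.
#' @param freq_rare,freq_common Population-frequency ranges of the rare
#'   and common pool components (each log-uniform, i.e. density
#'   proportional to 1/f).
#' @param prop_rare Proportion of pool sites drawn from the rare
#'   component.
#' @param private_rate Poisson mean of private singleton alleles per
#'   sample.
#' @param hf_weights Mixture weights (near-homoplasmic, intermediate).
#' @param hf_homoplasmic,hf_intermediate HF component ranges in percent.
#' @param depth_mean,depth_sd,depth_range Truncated-normal depth model.
#' @param causal_genes Genes whose pool alleles are enriched in cases.
#' @param causal_or Carrier odds ratio applied in cases for causal-gene
#'   sites.
#' @param hdl_shift HDL increase (mg/dl) for case carriers of
#'   causal-gene alleles.
#' @param planted_trna Optional tRNA gene symbol; a case-only, high-HF,
#'   stem-disrupting allele with high conservation and low panel frequency
#'   is planted there (recorded in the truth table).
#' @param seed Seed; recorded in the generated dataset.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 52, n_controls = 104,
                              n_pool = 450,
                              freq_rare = c(0.004, 0.03),
                              freq_common = c(0.03, 0.25),
                              prop_rare = 0.55,
                              private_rate = 2.6,
                              hf_weights = c(0.7, 0.3),
                              hf_homoplasmic = c(95, 100),
                              hf_intermediate = c(40, 80),
                              depth_mean = 3251.22, depth_sd = 964.63,
                              depth_range = c(2027.23, 5612.43),
                              causal_genes = character(0), causal_or = 1,
                              hdl_shift = 14,
                              planted_trna = NULL,
                              seed = 1) {
  stopifnot(n_cases > 0, n_controls > 0, n_pool > 0,
            all(hf_weights >= 0), abs(sum(hf_weights) - 1) < 1e-8)
  max_sites <- n_pool + 10 * (n_cases + n_controls) * private_rate
  if (max_sites > MT_GENOME_LENGTH) {
    abort("infeasible config: implied site count exceeds the genome length")
  }
  structure(as.list(environment()), class = "simulation_config")
}

rtruncnorm1 <- function(n, mean, sd, range) {
  lo <- pnorm(range[1], mean, sd); hi <- pnorm(range[2], mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

draw_hf <- function(n, cfg) {
  comp <- runif(n) < cfg$hf_weights[1]
  if_else(comp,
          runif(n, cfg$hf_homoplasmic[1], cfg$hf_homoplasmic[2]),
          runif(n, cfg$hf_intermediate[1], cfg$hf_intermediate[2]))
}

#' Generate a complete synthetic case-control cohort
#'
#' Draws a population allele pool with frequency spectrum proportional to
#' 1/f, assigns carriers by independent Bernoulli draws (with an odds-scale
#' enrichment of causal-gene sites in cases), adds cohort-private singleton
#' alleles, and emits per-observation read depths and heteroplasmic
#' fractions from the configured models.  Alongside the observations it
#' generates every ancillary input the pipeline consumes: a phenotype
#' table, per-allele pathogenicity-tool ratings for nonsynonymous protein
#' alleles, reference-panel allele counts, per-tRNA-gene conservation
#' panels and cloverleaf structure tables, plus a truth record of causal
#' and planted alleles.
#'
#' @param cfg A [simulation_config()].
#' @param gene_map Gene map, by default [mt_genes()].
#' @param reference Reference sequence; defaults to
#'   [synthetic_reference()] with the config seed.
#' @return A list of class `mito_cohort`: `observations` (with `hf`),
#'   `phenotypes`, `ratings`, `panel_counts`, `panels` (named list of
#'   conservation panels per tRNA gene), `structures`, `truth`,
#'   `reference`, `config`.
#' @export
generate_cohort <- function(cfg = simulation_config(), gene_map = mt_genes(),
                            reference = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  reference <- reference %||% synthetic_reference(cfg$seed, gene_map)
  set.seed(cfg$seed)
  samples <- tibble(
    sample_id = c(sprintf("case%03d", seq_len(cfg$n_cases)),
                  sprintf("ctrl%03d", seq_len(cfg$n_controls))),
    cohort = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  )

  # shared pool: two-component spectrum, density proportional to 1/f
  u <- runif(cfg$n_pool)
  rng <- map(runif(cfg$n_pool) < cfg$prop_rare,
             function(r) if (r) cfg$freq_rare else cfg$freq_common)
  f <- map_dbl(seq_len(cfg$n_pool), function(i) {
    rg <- rng[[i]]
    rg[1] * (rg[2] / rg[1])^u[i]
  })
  pool_pos <- sample(MT_GENOME_LENGTH, cfg$n_pool)
  pool <- tibble(pos = pool_pos,
                 ref = reference_base(reference, pool_pos),
                 freq = f)
  pool$alt <- map_chr(pool$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1))
  pool_genes <- map_chr(assign_gene(pool$pos, gene_map), 1)
  causal <- pool_genes %in% cfg$causal_genes
  f_case <- if_else(causal,
                    pool$freq * cfg$causal_or /
                      (1 - pool$freq + pool$freq * cfg$causal_or),
                    pool$freq)

  carry <- function(fv, ids) {
    hits <- map(seq_along(fv), function(i) {
      ids[runif(length(ids)) < fv[i]]
    })
    tibble(site = rep(seq_along(fv), lengths(hits)), sample_id = unlist(hits))
  }
  case_ids <- samples$sample_id[samples$cohort == "case"]
  ctrl_ids <- samples$sample_id[samples$cohort == "control"]
  hits <- bind_rows(carry(f_case, case_ids), carry(pool$freq, ctrl_ids))
  obs <- bind_cols(pool[hits$site, c("pos", "ref", "alt")],
                   tibble(sample_id = hits$sample_id))

  # cohort-private singletons
  used <- unique(pool$pos)
  n_priv <- rpois(nrow(samples), cfg$private_rate)
  none <- !(samples$sample_id %in% obs$sample_id)
  n_priv[none] <- pmax(n_priv[none], 1L)   # every sample carries >= 1 allele
  if (sum(n_priv) > 0) {
    priv_pos <- sample(setdiff(seq_len(MT_GENOME_LENGTH), used), sum(n_priv))
    priv <- tibble(
      pos = priv_pos,
      ref = reference_base(reference, priv_pos),
      sample_id = rep(samples$sample_id, n_priv)
    )
    priv$alt <- map_chr(priv$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1))
    obs <- bind_rows(obs, priv[, c("pos", "ref", "alt", "sample_id")])
  }
  obs <- left_join(obs, samples, by = "sample_id")

  truth_planted <- NULL
  if (!is.null(cfg$planted_trna)) {
    st <- trna_structure(cfg$planted_trna, gene_map, reference)
    cand <- filter(st, !is.na(.data$partner_number),
                   .data$trna_number < .data$partner_number,
                   !(.data$pos %in% obs$pos))
    site <- cand[1, ]
    ref_g <- site$gene_strand_base
    # transition on the gene strand breaks the Watson-Crick pair
    alt_g <- c(A = "G", G = "A", C = "T", T = "C")[[ref_g]]
    ref_h <- if (site$strand == "L") complement_base(ref_g) else ref_g
    alt_h <- if (site$strand == "L") complement_base(alt_g) else alt_g
    carriers <- sample(case_ids, 2)
    obs <- bind_rows(obs, tibble(pos = site$pos, ref = ref_h, alt = alt_h,
                                 sample_id = carriers, cohort = "case"))
    truth_planted <- tibble(pos = site$pos, ref = ref_h, alt = alt_h,
                            gene = cfg$planted_trna, role = "planted_pathogenic")
  }

  # read depths and heteroplasmic fractions
  n_obs <- nrow(obs)
  depth <- round(rtruncnorm1(n_obs, cfg$depth_mean, cfg$depth_sd,
                             cfg$depth_range))
  hfv <- draw_hf(n_obs, cfg)
  if (!is.null(truth_planted)) {
    hfv[obs$pos == truth_planted$pos] <- 99
  }
  obs <- obs |>
    mutate(total_reads = as.integer(depth),
           mutant_reads = pmin(pmax(as.integer(round(depth * hfv / 100)), 1L),
                               .data$total_reads)) |>
    arrange(.data$sample_id, .data$pos) |>
    select("sample_id", "cohort", "pos", "ref", "alt",
           "mutant_reads", "total_reads") |>
    compute_hf()

  phenotypes <- generate_phenotypes(samples, obs, cfg, gene_map)

  # pathogenicity-tool ratings for nonsynonymous protein alleles
  prot <- obs |> distinct(.data$pos, .data$ref, .data$alt) |>
    add_gene(gene_map) |> filter(.data$gene_class == "protein")
  ratings <- NULL
  if (nrow(prot) > 0) {
    cons <- call_consequence(prot, reference, gene_map,
                             on_incomplete = "drop")
    nsyn <- filter(cons, .data$consequence == "nonsynonymous")
    if (nrow(nsyn) > 0) {
      pstar <- if_else(nsyn$gene %in% cfg$causal_genes, 0.25, 0.6)
      draw_star <- function(p1) {
        map_int(p1, function(p) sample(1:3, 1, prob = c(p, 0.8 - p, 0.2)))
      }
      ratings <- nsyn |>
        select("pos", "ref", "alt", "gene", "aa_change") |>
        mutate(polyphen = draw_star(pstar), sift = draw_star(pstar),
               pmut = draw_star(pstar))
    }
  }

  # reference-panel counts and conservation panels for tRNA alleles
  trna_alleles <- obs |> distinct(.data$pos, .data$ref, .data$alt) |>
    add_gene(gene_map) |> filter(.data$gene_class == "tRNA")
  panel_counts <- trna_alleles |>
    select("pos", "ref", "alt", "gene") |>
    mutate(panel_count = rpois(dplyr::n(), 3), panel_size = 2704L)
  if (!is.null(truth_planted)) {
    panel_counts$panel_count[panel_counts$pos == truth_planted$pos] <- 1L
  }
  trna_genes <- unique(trna_alleles$gene)
  panels <- list()
  for (g in trna_genes) {
    gm <- gene_map[gene_map$gene == g, ]
    k <- sample(12:17, gm$end - gm$start + 1, replace = TRUE)
    targets <- tibble(pos = gm$start:gm$end, k = k)
    if (!is.null(truth_planted) && truth_planted$gene == g) {
      targets$k[targets$pos == truth_planted$pos] <- 16L
    }
    panels[[g]] <- generate_conservation_panel(reference, gm$start, gm$end,
                                               ci_targets = targets)
  }

  structures <- trna_structures(gene_map, reference)
  truth <- bind_rows(
    if (length(cfg$causal_genes)) {
      tibble(pos = pool$pos[causal], ref = pool$ref[causal],
             alt = pool$alt[causal], gene = pool_genes[causal],
             role = "causal_pool")
    },
    truth_planted
  )
  structure(list(observations = obs, phenotypes = phenotypes,
                 ratings = ratings, panel_counts = panel_counts,
                 panels = panels, structures = structures, truth = truth,
                 reference = reference, config = cfg),
            class = "mito_cohort")
}

generate_phenotypes <- function(samples, obs, cfg, gene_map) {
  n <- nrow(samples)
  ph <- tibble(
    sample_id = samples$sample_id,
    age = round(rnorm(n, 51.6, 10.8), 1),
    uric_acid = round(pmax(rnorm(n, 7.0, 1.7), 1), 2),
    bmi = round(pmax(rnorm(n, 26.3, 3.7), 15), 1),
    diabetes = runif(n) < 0.08,
    fasting_glucose = round(pmax(rnorm(n, 99.8, 19.0), 50), 1),
    total_cholesterol = round(pmax(rnorm(n, 191.1, 40.4), 80), 1),
    hdl = round(pmax(rnorm(n, 47.2, 12.6), 10), 1),
    ldl = round(pmax(rnorm(n, 119.5, 38.5), 30), 1),
    triglycerides = round(pmax(rnorm(n, 157.5, 99.5), 30), 1)
  )
  if (length(cfg$causal_genes) > 0 && cfg$hdl_shift != 0) {
    flagged <- obs |> add_gene(gene_map) |>
      filter(.data$gene %in% cfg$causal_genes) |>
      distinct(.data$sample_id)
    ph$hdl <- ph$hdl + cfg$hdl_shift * (ph$sample_id %in% flagged$sample_id)
  }
  ph
}

#' Generate a synthetic conservation panel with prescribed conservation
#'
#' Builds a gapless 17-species alignment over a genomic window in which
#' each target position has exactly `k` rows (human included) carrying the
#' human wild-type base, so [conservation_index()] recovers `100 k / 17`
#' exactly.  Non-target columns are fully conserved.
#'
#' @param reference Reference sequence (human row source).
#' @param start,end Genomic window, 1-based inclusive.
#' @param ci_targets Tibble with `pos` and `k` (0-17; `k >= 1` since the
#'   human row always matches itself).
#' @param n_species Panel size (default 17).
#' @return A `conservation_panel` (see [read_alignment_panel()]).
#' @export
generate_conservation_panel <- function(reference, start, end,
                                        ci_targets = NULL, n_species = 17) {
  width <- end - start + 1L
  human <- strsplit(str_to_upper(substring(reference, start, end)), "")[[1]]
  aln <- matrix(rep(human, each = n_species), nrow = n_species)
  rownames(aln) <- c("human", paste0("species", seq_len(n_species - 1)))
  if (!is.null(ci_targets) && nrow(ci_targets) > 0) {
    stopifnot(all(ci_targets$k >= 1 & ci_targets$k <= n_species),
              all(ci_targets$pos >= start & ci_targets$pos <= end))
    for (i in seq_len(nrow(ci_targets))) {
      col <- ci_targets$pos[i] - start + 1L
      n_div <- n_species - ci_targets$k[i]
      if (n_div > 0) {
        rows <- 1 + seq_len(n_div)   # never the human row
        aln[rows, col] <- setdiff(c("A", "C", "G", "T"), human[col])[1]
      }
    }
  }
  structure(list(aln = aln, species = rownames(aln),
                 pos_to_col = setNames(seq_len(width), start:end)),
            class = "conservation_panel")
}

#' Write a conservation panel as aligned FASTA
#'
#' @param panel A `conservation_panel`.
#' @param path Output FASTA path.
#' @export
write_alignment_panel <- function(panel, path) {
  seqs <- apply(panel$aln, 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(panel)
}

#' Write every pipeline input of a synthetic cohort to a directory
#'
#' Emits the variant TSV, phenotype TSV, ratings TSV, panel-count TSV,
#' structure TSV, per-gene aligned FASTA panels, reference FASTA and a
#' truth JSON, i.e. one on-disk instance of every input format the
#' pipeline reads.
#'
#' @param cohort A `mito_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mito_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             structures = file.path(dir, "trna_structures.tsv"),
             panel_counts = file.path(dir, "panel_counts.tsv"),
             reference = file.path(dir, "reference.fa"),
             truth = file.path(dir, "truth.json"))
  write_variant_table(cohort$observations, paths["variants"])
  write_tsv(cohort$phenotypes, paths["phenotypes"], progress = FALSE)
  write_trna_structure(cohort$structures, paths["structures"])
  write_tsv(cohort$panel_counts, paths["panel_counts"], progress = FALSE)
  writeLines(c(">synthetic_chrM", cohort$reference), paths["reference"])
  if (!is.null(cohort$ratings)) {
    paths["ratings"] <- file.path(dir, "ratings.tsv")
    write_tsv(cohort$ratings, paths["ratings"], progress = FALSE)
  }
  for (g in names(cohort$panels)) {
    p <- file.path(dir, paste0("panel_", gsub("-", "_", g), ".fa"))
    write_alignment_panel(cohort$panels[[g]], p)
    paths[paste0("panel_", g)] <- p
  }
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         truth = cohort$truth %||% tibble()),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}
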