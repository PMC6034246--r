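#' Group alleles by cohort sharing
#'
#' Distinct alleles (keyed by position, reference and alternate base) are
#' partitioned into three groups: `shared` (carried by at least one case and
#' one control), `case_only` and `control_only`.
#'
#' @param obs Observation tibble with `sample_id`, `cohort`
#'   (`"case"`/`"control"`), `pos`, `ref`, `alt`.
#' @return A tibble with one row per distinct allele: `pos`, `ref`, `alt`,
#'   `case_carriers`, `control_carriers`, `group`.
#' @export
assign_groups <- function(obs) {
  stopifnot(all(c("sample_id", "cohort", "pos", "ref", "alt") %in% names(obs)))
  if (!all(obs$cohort %in% c("case", "control"))) {
    abort('cohort must be "case" or "control"')
  }
  obs |>
    distinct(.data$sample_id, .data$cohort, .data$pos, .data$ref, .data$alt) |>
    count(.data$pos, .data$ref, .data$alt, .data$cohort) |>
    pivot_wider(names_from = "cohort", values_from = "n", values_fill = 0L) |>
    (\(d) {
      if (!("case" %in% names(d))) d$case <- 0L
      if (!("control" %in% names(d))) d$control <- 0L
      d
    })() |>
    transmute(.data$pos, .data$ref, .data$alt,
              case_carriers = .data$case, control_carriers = .data$control,
              group = case_when(
                .data$case > 0 & .data$control > 0 ~ "shared",
                .data$case > 0 ~ "case_only",
                TRUE ~ "control_only"
              )) |>
    arrange(.data$pos, .data$alt)
}

#' Carrier enrichment test on a 2x2 cohort table
#'
#' Builds the table \[k_case, n_case - k_case; k_ctrl, n_ctrl - k_ctrl\] of
#' carriers versus non-carriers and tests whether carrier proportions differ
#' between cohorts.  With `rule = "auto"` the Pearson chi-square test
#' (1 df, no continuity correction) is used when all four expected cell
#' counts are at least `expected_min`, and the two-sided Fisher exact test
#' (sum of hypergeometric point probabilities no larger than the observed
#' table's) otherwise.
#'
#' @param k_case,n_case Carriers and cohort size among cases.
#' @param k_ctrl,n_ctrl Carriers and cohort size among controls.
#' @param rule `"auto"`, `"chi_square"` or `"fisher_exact"`.
#' @param expected_min Expected-count cutoff for the chi-square branch
#'   (default 5).
#' @return One-row tibble: `k_case`, `n_case`, `k_ctrl`, `n_ctrl`,
#'   `statistic` (chi-square statistic, `NA` for the exact test), `p_value`,
#'   `method`.
#' @examples
#' carrier_enrichment_test(10, 52, 0, 104)  # exact, p = 9.03e-6
#' carrier_enrichment_test(40, 52, 69, 104) # chi-square, p = 0.175
#' @export
carrier_enrichment_test <- function(k_case, n_case, k_ctrl, n_ctrl,
                                    rule = c("auto", "chi_square", "fisher_exact"),
                                    expected_min = 5) {
  rule <- match.arg(rule)
  if (n_case <= 0 || n_ctrl <= 0) abort("cohort sizes must be positive")
  if (k_case < 0 || k_case > n_case || k_ctrl < 0 || k_ctrl > n_ctrl) {
    abort("carrier counts must lie in [0, cohort size]")
  }
  tab <- matrix(c(k_case, n_case - k_case, k_ctrl, n_ctrl - k_ctrl),
                nrow = 2, byrow = TRUE)
  method <- if (rule == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= expected_min)) "chi_square" else "fisher_exact"
  } else rule
  if (method == "chi_square") {
    if (any(colSums(tab) == 0)) {
      statistic <- 0; p <- 1
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      statistic <- unname(ct$statistic); p <- ct$p.value
    }
  } else {
    statistic <- NA_real_
    p <- fisher.test(tab)$p.value
  }
  tibble(k_case = k_case, n_case = n_case, k_ctrl = k_ctrl, n_ctrl = n_ctrl,
         statistic = statistic, p_value = p, method = method)
}

#' Per-gene carrier enrichment table by allele group
#'
#' For each gene region and allele group, counts the individuals carrying at
#' least one allele of that gene/group and tests enrichment.  Shared alleles
#' compare case carriers against control carriers; case-only and
#' control-only alleles compare the carrying cohort against the structurally
#' zero other cohort.  tRNA genes are pooled into a single `MT-TRNA` row by
#' default.
#'
#' @param obs Observation tibble with `sample_id`, `cohort`, `pos`, `ref`,
#'   `alt`.
#' @param gene_map Gene map, by default [mt_genes()].
#' @param pool_trna Pool the 22 tRNA genes into one `MT-TRNA` region?
#' @param include_noncoding Keep a `noncoding` region row? Default `FALSE`.
#' @inheritParams carrier_enrichment_test
#' @return Tibble with one row per gene x group: carrier counts and
#'   percentages per cohort, `p_value` and `method`.  The underlying test
#'   result is of class `mito_enrichment` for plotting.
#' @export
enrichment_table <- function(obs, gene_map = mt_genes(), pool_trna = TRUE,
                             include_noncoding = FALSE,
                             rule = "auto", expected_min = 5) {
  groups <- assign_groups(obs)
  n_case <- n_distinct(obs$sample_id[obs$cohort == "case"])
  n_ctrl <- n_distinct(obs$sample_id[obs$cohort == "control"])
  keyed <- obs |>
    distinct(.data$sample_id, .data$cohort, .data$pos, .data$ref, .data$alt) |>
    inner_join(select(groups, "pos", "ref", "alt", "group"),
               by = c("pos", "ref", "alt")) |>
    add_gene(gene_map)
  if (pool_trna) {
    keyed <- mutate(keyed, gene = if_else(.data$gene_class == "tRNA",
                                          "MT-TRNA", .data$gene))
  }
  if (!include_noncoding) keyed <- filter(keyed, .data$gene != "noncoding")
  counts <- keyed |>
    distinct(.data$gene, .data$group, .data$cohort, .data$sample_id) |>
    count(.data$gene, .data$group, .data$cohort) |>
    pivot_wider(names_from = "cohort", values_from = "n", values_fill = 0L)
  if (!("case" %in% names(counts))) counts$case <- 0L
  if (!("control" %in% names(counts))) counts$control <- 0L
  res <- counts |>
    rowwise() |>
    mutate(test = list(switch(.data$group,
      shared = carrier_enrichment_test(.data$case, n_case, .data$control,
                                       n_ctrl, rule, expected_min),
      case_only = carrier_enrichment_test(.data$case, n_case, 0L, n_ctrl,
                                          rule, expected_min),
      control_only = carrier_enrichment_test(0L, n_case, .data$control,
                                             n_ctrl, rule, expected_min)
    ))) |>
    ungroup() |>
    unnest("test") |>
    transmute(.data$gene, .data$group,
              case_carriers = .data$case, control_carriers = .data$control,
              case_pct = round(100 * .data$case / n_case, 2),
              control_pct = round(100 * .data$control / n_ctrl, 2),
              .data$statistic, .data$p_value, .data$method) |>
    arrange(.data$gene, .data$group)
  class(res) <- c("mito_enrichment", class(res))
  res
}

#' Per-individual allele burden by gene region
#'
#' Counts distinct alleles per individual in each gene region (samples with
#' no allele in a region count zero) and compares case and control burdens
#' with a two-sample test (Mann-Whitney U by default, matching the
#' comparison rule used for clinical phenotypes).
#'
#' @inheritParams enrichment_table
#' @param method `"mann_whitney"` or `"t_test"`.
#' @return Tibble with one row per region: per-cohort mean and SD of the
#'   per-individual allele count, `p_value` and `method`.  Regions with no
#'   alleles at all report zero means and `NA` p-value.
#' @export
burden_per_individual <- function(obs, gene_map = mt_genes(), pool_trna = TRUE,
                                  method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  stopifnot(all(c("sample_id", "cohort", "pos", "ref", "alt") %in% names(obs)))
  roster <- distinct(obs, .data$sample_id, .data$cohort)
  keyed <- obs |>
    distinct(.data$sample_id, .data$cohort, .data$pos, .data$ref, .data$alt) |>
    add_gene(gene_map)
  if (pool_trna) {
    keyed <- mutate(keyed, gene = if_else(.data$gene_class == "tRNA",
                                          "MT-TRNA", .data$gene))
  }
  regions <- sort(unique(keyed$gene))
  out <- map(regions, function(g) {
    cnt <- keyed |>
      filter(.data$gene == g) |>
      count(.data$sample_id, name = "n_alleles") |>
      right_join(roster, by = "sample_id") |>
      mutate(n_alleles = replace_na(.data$n_alleles, 0L))
    x <- cnt$n_alleles[cnt$cohort == "case"]
    y <- cnt$n_alleles[cnt$cohort == "control"]
    p <- if (sum(x) + sum(y) == 0 || length(x) == 0 || length(y) == 0) {
      NA_real_
    } else if (method == "mann_whitney") {
      suppressWarnings(wilcox.test(x, y)$p.value)
    } else {
      stats::t.test(x, y)$p.value
    }
    tibble(region = g,
           mean_case = mean(x), sd_case = sd(x),
           mean_control = mean(y), sd_control = sd(y),
           p_value = p, method = method)
  })
  list_rbind(out)
}
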