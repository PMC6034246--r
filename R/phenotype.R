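#' Compare a phenotype between carriers and non-carriers
#'
#' Continuous phenotypes are compared with the Mann-Whitney U test by
#' default (exact distribution when the smaller group has at most 8 values
#' and there are no ties, normal approximation with tie correction
#' otherwise), or with Student's t test on request.  Categorical (binary)
#' phenotypes use the two-sided Fisher exact test on the 2x2 table of
#' trait by carrier status.
#'
#' @param values_plus,values_minus Phenotype values for carriers and
#'   non-carriers; numeric for `kind = "continuous"`, logical/0-1 for
#'   `kind = "categorical"`.  Missing values are dropped.
#' @param kind `"continuous"` or `"categorical"`.
#' @param method For continuous phenotypes, `"mann_whitney"` (default) or
#'   `"t_test"`.
#' @param exact_max Largest min-group size for which the exact
#'   Mann-Whitney distribution is used (default 8).
#' @return One-row tibble: group sizes, per-group mean and SD (or event
#'   counts for categorical), `statistic`, `p_value`, `method`.
#' @export
compare_phenotype <- function(values_plus, values_minus,
                              kind = c("continuous", "categorical"),
                              method = c("mann_whitney", "t_test"),
                              exact_max = 8) {
  kind <- match.arg(kind); method <- match.arg(method)
  x <- values_plus[!is.na(values_plus)]
  y <- values_minus[!is.na(values_minus)]
  if (length(x) == 0 || length(y) == 0) {
    abort("each group needs at least one non-missing value")
  }
  if (kind == "categorical") {
    tab <- matrix(c(sum(x == 1), sum(x == 0), sum(y == 1), sum(y == 0)),
                  nrow = 2, byrow = TRUE)
    p <- fisher.test(tab)$p.value
    return(tibble(n_plus = length(x), n_minus = length(y),
                  events_plus = sum(x == 1), events_minus = sum(y == 1),
                  statistic = NA_real_, p_value = p, method = "exact"))
  }
  if (method == "t_test") {
    tt <- stats::t.test(x, y)
    return(tibble(n_plus = length(x), n_minus = length(y),
                  mean_plus = mean(x), sd_plus = sd(x),
                  mean_minus = mean(y), sd_minus = sd(y),
                  statistic = unname(tt$statistic), p_value = tt$p.value,
                  method = "t_test"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- min(length(x), length(y)) <= exact_max && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact,
                                     correct = !use_exact))
  tibble(n_plus = length(x), n_minus = length(y),
         mean_plus = mean(x), sd_plus = sd(x),
         mean_minus = mean(y), sd_minus = sd(y),
         statistic = unname(wt$statistic), p_value = wt$p.value,
         method = "mann_whitney")
}

#' Two-sample t test from summary statistics
#'
#' @param n1,mean1,sd1 Size, mean and SD of the first group.
#' @param n2,mean2,sd2 Size, mean and SD of the second group.
#' @param variant `"pooled"` (equal-variance Student t) or `"welch"`.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `variant`.
#' @examples
#' ttest_from_summary(52, 51.60, 10.82, 104, 51.61, 10.78) # p = 0.996
#' @export
ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) abort("standard deviations must be positive")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df),
         variant = variant)
}

#' Phenotype comparison table for carriers of a flagged allele set
#'
#' Within the case cohort, splits samples into carriers and non-carriers
#' of any allele in `flagged` and compares each phenotype variable
#' (continuous variables by Mann-Whitney U, binary variables by Fisher
#' exact), producing a clinical-characteristics table.
#'
#' @param obs Observation tibble with `sample_id`, `cohort`, `pos`,
#'   `ref`, `alt`.
#' @param phenotypes Tibble with `sample_id` plus phenotype columns.
#' @param flagged Tibble of flagged alleles (`pos`, `ref`, `alt`).
#' @param variables Phenotype columns to compare; defaults to all numeric
#'   and logical columns.
#' @param cohort Which cohort to analyze (default `"case"`).
#' @return Tibble with one row per variable, carrying group summaries,
#'   `p_value` and `method`.
#' @export
phenotype_comparison_table <- function(obs, phenotypes, flagged,
                                       variables = NULL, cohort = "case") {
  stopifnot("sample_id" %in% names(phenotypes))
  roster <- obs |> filter(.data$cohort == !!cohort) |>
    distinct(.data$sample_id)
  key <- paste0(flagged$pos, "_", flagged$ref, ">", flagged$alt)
  carriers <- obs |>
    filter(.data$cohort == !!cohort,
           paste0(.data$pos, "_", .data$ref, ">", .data$alt) %in% key) |>
    distinct(.data$sample_id)
  ph <- phenotypes |>
    inner_join(roster, by = "sample_id") |>
    mutate(carrier = .data$sample_id %in% carriers$sample_id)
  if (is.null(variables)) {
    variables <- setdiff(names(ph)[vapply(ph, function(c)
      is.numeric(c) || is.logical(c), logical(1))], c("carrier"))
  }
  if (all(ph$carrier) || !any(ph$carrier)) {
    warn("all (or no) samples carry a flagged allele; comparison skipped")
    return(tibble(variable = variables, kind = NA_character_,
                  n_plus = sum(ph$carrier), n_minus = sum(!ph$carrier),
                  p_value = NA_real_, method = NA_character_))
  }
  out <- map(variables, function(v) {
    vals <- ph[[v]]
    kind <- if (is.logical(vals) || all(vals %in% c(0, 1, NA))) {
      "categorical"
    } else "continuous"
    res <- compare_phenotype(vals[ph$carrier], vals[!ph$carrier], kind)
    bind_cols(tibble(variable = v, kind = kind), res)
  })
  list_rbind(out)
}
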