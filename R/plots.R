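#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heteroplasmic-fraction distribution plot
#'
#' Histogram of per-observation heteroplasmic fractions, split by cohort
#' when a `cohort` column is present; useful for checking the bimodal
#' (near-homoplasmic plus intermediate) shape typical of mtDNA variant
#' calls.
#'
#' @param obs Observation tibble with an `hf` column (see
#'   [compute_hf()]).
#' @param binwidth Histogram bin width in percent.
#' @return A ggplot object.
#' @export
plot_hf_distribution <- function(obs, binwidth = 2.5) {
  stopifnot("hf" %in% names(obs))
  p <- ggplot(obs, aes(x = .data$hf)) +
    geom_histogram(binwidth = binwidth, boundary = 0, fill = "steelblue",
                   colour = "white") +
    labs(x = "heteroplasmic fraction (%)", y = "observations") +
    theme_minimal()
  if ("cohort" %in% names(obs)) p <- p + facet_wrap(~cohort, ncol = 1)
  p
}

#' Enrichment table plot
#'
#' Dot plot of -log10 p-values per gene, faceted by allele group, with the
#' significance threshold drawn as a dashed line.
#'
#' @param x A `mito_enrichment` table from [enrichment_table()].
#' @param alpha Significance level (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mito_enrichment <- function(x, alpha = 0.05, ...) {
  ggplot(x, aes(x = -log10(.data$p_value),
                y = stats::reorder(.data$gene, -.data$p_value),
                shape = .data$method)) +
    geom_vline(xintercept = -log10(alpha), linetype = "dashed",
               colour = "grey40") +
    geom_point(size = 2, colour = "firebrick") +
    facet_wrap(~group, nrow = 1) +
    labs(x = expression(-log[10](p)), y = NULL, shape = "test") +
    theme_minimal()
}

#' SKAT result plot
#'
#' For permutation results, the permutation null distribution of Q with
#' the observed statistic marked; otherwise the eigenvalue spectrum of the
#' projected kernel.
#'
#' @param x A `mito_skat` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mito_skat <- function(x, ...) {
  if (!is.null(x$perm_Q)) {
    ggplot(tibble(Q = x$perm_Q), aes(x = .data$Q)) +
      geom_histogram(bins = 40, fill = "grey70", colour = "white") +
      geom_vline(xintercept = x$Q, colour = "firebrick") +
      labs(x = "permutation Q", y = "count",
           title = sprintf("observed Q = %.3g, p = %.3g", x$Q, x$p_value)) +
      theme_minimal()
  } else {
    ggplot(tibble(i = seq_along(x$lambda), lambda = x$lambda),
           aes(x = .data$i, y = .data$lambda)) +
      geom_col(fill = "steelblue") +
      labs(x = "component", y = "eigenvalue",
           title = sprintf("Q = %.3g, p = %.3g (%s)", x$Q, x$p_value,
                           x$method)) +
      theme_minimal()
  }
}
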