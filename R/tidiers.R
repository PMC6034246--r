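#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a SKAT result
#'
#' @param x A `mito_skat` object.
#' @param ... Unused.
#' @return One-row tibble with `Q`, `p.value`, `method`, `n.alleles`.
#' @export
tidy.mito_skat <- function(x, ...) {
  tibble(Q = x$Q, p.value = x$p_value, method = x$method,
         n.alleles = x$n_alleles)
}

#' Glance at a SKAT result
#'
#' @inheritParams tidy.mito_skat
#' @return One-row tibble with model-level summaries.
#' @export
glance.mito_skat <- function(x, ...) {
  tibble(n = x$n, n.alleles = x$n_alleles, Q = x$Q, p.value = x$p_value,
         method = x$method, B = x$B)
}

#' Tidy an interaction test result
#'
#' @param x A `mito_interaction` object.
#' @param ... Unused.
#' @export
tidy.mito_interaction <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method)
}
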