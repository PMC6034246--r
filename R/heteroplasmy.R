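#' Heteroplasmic fraction from read counts
#'
#' The heteroplasmic fraction (HF) of a substitution in a sample is the
#' percentage of reads at that position that carry the mutant base:
#' `100 * mutant_reads / total_reads`.
#'
#' @param mutant_reads,total_reads Non-negative integer vectors;
#'   `total_reads` must be positive.
#' @return Numeric vector of percentages in \[0, 100\].
#' @examples
#' hf(9935, 10000) # 99.35
#' @export
hf <- function(mutant_reads, total_reads) {
  if (any(total_reads <= 0)) abort("total_reads must be positive")
  if (any(mutant_reads < 0 | mutant_reads > total_reads)) {
    abort("mutant_reads must lie in [0, total_reads]")
  }
  100 * mutant_reads / total_reads
}

#' Add a heteroplasmic-fraction column to an observation table
#'
#' @param obs Tibble with `mutant_reads` and `total_reads` columns.
#' @return `obs` with an `hf` column (percent).
#' @export
compute_hf <- function(obs) {
  mutate(obs, hf = hf(.data$mutant_reads, .data$total_reads))
}

#' Flag heteroplasmic fractions above the metabolic threshold
#'
#' Mitochondrial mutations are generally thought to produce a biochemical
#' phenotype only once the mutant load exceeds a threshold; 40% is used as
#' the default.  The comparison is strict (`hf > threshold`).
#'
#' @param hf Numeric vector of percentages.
#' @param threshold Threshold percentage (default 40).
#' @return Logical vector.
#' @examples
#' hf_threshold_flag(c(42.05, 40, 99.71))
#' @export
hf_threshold_flag <- function(hf, threshold = 40) {
  stopifnot(is.numeric(hf), all(hf >= 0 & hf <= 100))
  hf > threshold
}

#' Band alleles as common or low-frequency by cohort carrier frequency
#'
#' An allele is `common` when more than `threshold` percent of the cohort
#' carries it and `low_frequency` otherwise; a frequency of exactly the
#' threshold is banded low-frequency (both bands are defined by strict
#' inequalities).
#'
#' @param carriers Integer vector of carrier counts.
#' @param cohort_n Cohort size (scalar or vector), positive.
#' @param threshold Percent threshold, default 5.
#' @return Character vector over `{"common", "low_frequency"}`.
#' @examples
#' frequency_band(c(3, 2, 8), c(52, 52, 104))
#' @export
frequency_band <- function(carriers, cohort_n, threshold = 5) {
  if (any(cohort_n <= 0)) abort("cohort_n must be positive")
  if (any(carriers < 0 | carriers > cohort_n)) {
    abort("carriers must lie in [0, cohort_n]")
  }
  if_else(100 * carriers / cohort_n > threshold, "common", "low_frequency")
}
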