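# Small in-code fixtures shared across test files.

# An observation table built directly from (sample, cohort, pos, ref, alt)
# rows with constant read counts unless given.
make_obs <- function(df, mutant_reads = 90L, total_reads = 100L) {
  df <- tibble::as_tibble(df)
  if (!("mutant_reads" %in% names(df))) df$mutant_reads <- mutant_reads
  if (!("total_reads" %in% names(df))) df$total_reads <- total_reads
  df
}

# Cohort in which carriage is specified per allele as two vectors of sample
# indices (cases 1..n_case -> "case#", controls -> "ctrl#").
make_cohort_obs <- function(alleles, n_case = 4, n_ctrl = 6) {
  rows <- list()
  for (i in seq_len(nrow(alleles))) {
    a <- alleles[i, ]
    for (s in a$case_ids[[1]]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sprintf("case%02d", s), cohort = "case",
        pos = a$pos, ref = a$ref, alt = a$alt)
    }
    for (s in a$ctrl_ids[[1]]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sprintf("ctrl%02d", s), cohort = "control",
        pos = a$pos, ref = a$ref, alt = a$alt)
    }
  }
  make_obs(dplyr::bind_rows(rows))
}

# Complete-enumeration two-sided Fisher oracle: sum of hypergeometric point
# probabilities not exceeding the observed table's.
fisher_enumeration_oracle <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  xs <- max(0, m - n2):min(n1, m)
  logp <- lchoose(n1, xs) + lchoose(n2, m - xs) - lchoose(n1 + n2, m)
  p_obs <- logp[xs == k1]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# A tiny single-record-per-line VCF with AD genotype fields.
write_test_vcf <- function(path, records) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(unique(records$sample), collapse = "\t")))
  samples <- unique(records$sample)
  lines <- vapply(split(records, records$pos), function(r) {
    gt <- vapply(samples, function(s) {
      row <- r[r$sample == s, ]
      if (nrow(row) == 0) "./.:.," else paste0("0/1:", row$ad)
    }, character(1))
    paste(c("chrM", r$pos[1], ".", r$ref[1], r$alt[1], ".", "PASS", ".",
            "GT:AD", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
}
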