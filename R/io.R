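#' Read a per-sample mtDNA variant table
#'
#' Two dialects are supported.  The TSV dialect is a delimited text file
#' (tab or comma) with header columns `sample,pos,ref,alt,mutant_reads,
#' total_reads` (an optional `cohort` column is passed through).  The VCF
#' dialect is a VCF 4.x file, single- or multi-sample, whose genotype fields
#' carry either allelic depths (`AD`) or total depth plus allele fraction
#' (`DP` + `AF`); multi-allelic records are split into one observation per
#' alternate allele and `total_reads` is the sum of the AD fields.
#'
#' Only single-nucleotide substitutions are analyzed downstream; indel
#' records are parsed and flagged `variant_type = "indel"` rather than
#' rejected.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A tibble with columns `sample_id`, `pos`, `ref`, `alt`,
#'   `mutant_reads`, `total_reads`, `variant_type` (plus `cohort` when
#'   present in the input).
#' @export
read_variant_table <- function(path, dialect = c("auto", "tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  obs <- switch(dialect,
    tsv = read_variant_tsv(path),
    vcf = read_variant_vcf(path)
  )
  validate_observations(obs, context = path)
  obs$.line <- NULL
  obs
}

empty_observations <- function() {
  tibble(
    sample_id = character(), pos = integer(), ref = character(),
    alt = character(), mutant_reads = integer(), total_reads = integer(),
    variant_type = character()
  )
}

read_variant_tsv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) {
    warn(paste0("empty variant table: ", path))
    return(empty_observations())
  }
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  need <- c("sample", "pos", "ref", "alt", "mutant_reads", "total_reads")
  if (!all(need %in% names(raw))) {
    abort(paste0("variant TSV must have columns ", paste(need, collapse = ",")))
  }
  if (nrow(raw) == 0) {
    warn(paste0("variant table has a header but no records: ", path))
    return(empty_observations())
  }
  # one observation per alt, should a record list several
  raw <- mutate(raw, .line = dplyr::row_number() + 1L)
  raw <- unnest(mutate(raw, alt = str_split(.data$alt, ",")), "alt")
  bad <- which(is.na(raw$pos) | is.na(raw$mutant_reads) | is.na(raw$total_reads) |
                 !nzchar(raw$ref) | !nzchar(raw$alt))
  if (length(bad)) {
    abort(paste0("malformed variant record at line ", raw$.line[bad[1]],
                 " of ", path))
  }
  out <- tibble(
    sample_id = as.character(raw$sample),
    pos = as.integer(raw$pos),
    ref = str_to_upper(raw$ref),
    alt = str_to_upper(raw$alt),
    mutant_reads = as.integer(raw$mutant_reads),
    total_reads = as.integer(raw$total_reads),
    variant_type = if_else(nchar(raw$ref) == 1L & nchar(raw$alt) == 1L,
                           "snv", "indel"),
    .line = raw$.line
  )
  if ("cohort" %in% names(raw)) out$cohort <- as.character(raw$cohort)
  out
}

read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  n_rec <- nrow(fx)
  if (n_rec == 0) {
    warn(paste0("VCF has no records: ", path))
    return(empty_observations())
  }
  samples <- colnames(v@gt)[-1]
  ad <- tryCatch(vcfR::extract.gt(v, "AD"), error = function(e) NULL)
  dp <- tryCatch(vcfR::extract.gt(v, "DP", as.numeric = TRUE), error = function(e) NULL)
  af <- tryCatch(vcfR::extract.gt(v, "AF", as.numeric = TRUE), error = function(e) NULL)
  rows <- list()
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fx[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      ad_i <- if (!is.null(ad)) ad[i, s] else NA_character_
      if (!is.na(ad_i)) {
        depths <- suppressWarnings(as.numeric(strsplit(ad_i, ",", fixed = TRUE)[[1]]))
        if (anyNA(depths) || length(depths) != length(alts) + 1L) {
          abort(paste0("malformed AD field in record ", i, " of ", path))
        }
        tot <- sum(depths)
        if (tot == 0) next
        for (j in seq_along(alts)) {
          if (depths[j + 1L] == 0) next
          rows[[length(rows) + 1L]] <- tibble(
            sample_id = s, pos = as.integer(fx[i, "POS"]),
            ref = fx[i, "REF"], alt = alts[j],
            mutant_reads = as.integer(depths[j + 1L]),
            total_reads = as.integer(tot)
          )
        }
      } else if (!is.null(dp) && !is.null(af) && !is.na(dp[i, s]) && !is.na(af[i, s])) {
        tot <- as.integer(dp[i, s])
        mut <- as.integer(round(tot * af[i, s]))
        if (mut == 0) next
        for (j in seq_along(alts)) {
          rows[[length(rows) + 1L]] <- tibble(
            sample_id = s, pos = as.integer(fx[i, "POS"]),
            ref = fx[i, "REF"], alt = alts[j],
            mutant_reads = mut, total_reads = tot
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    warn(paste0("no usable genotype depth fields in ", path))
    return(empty_observations())
  }
  out <- list_rbind(rows)
  out$variant_type <- if_else(nchar(out$ref) == 1L & nchar(out$alt) == 1L,
                              "snv", "indel")
  out
}

validate_observations <- function(obs, context = "variant table") {
  if (nrow(obs) == 0) return(invisible(obs))
  if (any(obs$pos < 1 | obs$pos > MT_GENOME_LENGTH)) {
    abort(paste0(context, ": positions outside 1..16569"))
  }
  if (any(obs$total_reads <= 0)) {
    abort(paste0(context, ": total_reads must be positive"))
  }
  bad <- which(obs$mutant_reads > obs$total_reads | obs$mutant_reads < 0)
  if (length(bad)) {
    where <- if (".line" %in% names(obs)) paste0(" at line ", obs$.line[bad[1]]) else ""
    abort(paste0(context, ": mutant_reads exceeds total_reads", where))
  }
  same <- which(obs$ref == obs$alt)
  if (length(same)) abort(paste0(context, ": ref equals alt"))
  invisible(obs)
}

#' Write a variant table in the TSV dialect
#'
#' The written file round-trips losslessly through [read_variant_table()].
#'
#' @param obs Observation tibble as returned by [read_variant_table()].
#' @param path Output path.
#' @return `obs`, invisibly.
#' @export
write_variant_table <- function(obs, path) {
  out <- tibble(
    sample = obs$sample_id, pos = obs$pos, ref = obs$ref, alt = obs$alt,
    mutant_reads = obs$mutant_reads, total_reads = obs$total_reads
  )
  if ("cohort" %in% names(obs)) out$cohort <- obs$cohort
  write_tsv(out, path, progress = FALSE)
  invisible(obs)
}

#' Read a reference mitochondrial sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return A single upper-case character string.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort("reference FASTA has no sequences")
  as.character(seqs[[1]])
}
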