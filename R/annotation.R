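#' Combine three pathogenicity-tool star ratings
#'
#' Each of the three protein-impact tools rates an allele on a 3-stage
#' scale (1 = neutral, 2 = moderate evidence of pathogenicity, 3 = strong
#' evidence).  The combined rating is the arithmetic mean of the three,
#' rounded to the nearest integer; exact halves round up by default
#' (the published worked example, mean 2.333 -> 2, does not involve a
#' half, so the half rule is configurable).
#'
#' @param polyphen,sift,pmut Integer vectors with values in `{1, 2, 3}`.
#' @param rounding `"half_up"` (default) or `"half_even"`.
#' @return Integer vector of combined star ratings in `{1, 2, 3}`.
#' @examples
#' combine_ratings(2, 2, 3) # 2
#' @export
combine_ratings <- function(polyphen, sift, pmut,
                            rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  vals <- c(polyphen, sift, pmut)
  if (any(is.na(vals)) || !all(vals %in% 1:3)) {
    abort("ratings must be integers in {1, 2, 3}")
  }
  m <- (polyphen + sift + pmut) / 3
  if (rounding == "half_up") as.integer(floor(m + 0.5)) else as.integer(round(m))
}

#' Build a conservation panel from an aligned orthologue FASTA
#'
#' The alignment holds the human sequence first, followed by the other
#' species (17 rows in the reference design).  The mapping from human
#' genomic position to alignment column is derived from the ungapped human
#' row starting at `human_start`.
#'
#' @param path Aligned FASTA (equal-width rows, human first), or a
#'   character vector of aligned sequences.
#' @param human_start Genomic position of the first human base in the
#'   alignment.
#' @return A list of class `conservation_panel`: `aln` (character matrix,
#'   species x columns), `species`, `pos_to_col` (named integer vector).
#' @export
read_alignment_panel <- function(path, human_start = 1L) {
  seqs <- if (length(path) == 1 && file.exists(path)) {
    s <- Biostrings::readDNAStringSet(path)
    setNames(as.character(s), names(s))
  } else {
    path
  }
  if (length(unique(nchar(seqs))) != 1) {
    abort("alignment rows must have equal width")
  }
  aln <- do.call(rbind, strsplit(str_to_upper(unname(seqs)), ""))
  rownames(aln) <- names(seqs) %||% paste0("seq", seq_len(nrow(aln)))
  human <- aln[1, ]
  ungapped <- which(human != "-")
  pos_to_col <- setNames(ungapped, human_start + seq_along(ungapped) - 1L)
  structure(list(aln = aln, species = rownames(aln), pos_to_col = pos_to_col),
            class = "conservation_panel")
}

#' Conservation index of a position across the orthologue panel
#'
#' CI is the percentage of panel species (human included) carrying the
#' human wild-type nucleotide at the alignment column of the given genomic
#' position, reported to two decimals.  With the 17-species reference panel
#' every CI is a multiple of 100/17.
#'
#' @param panel A `conservation_panel` from [read_alignment_panel()] or
#'   [generate_conservation_panel()].
#' @param pos Genomic position(s).
#' @param wild_type Wild-type base(s); defaults to the human row's base.
#' @return Numeric vector of CI percentages.
#' @export
conservation_index <- function(panel, pos, wild_type = NULL) {
  stopifnot(inherits(panel, "conservation_panel"))
  col <- panel$pos_to_col[as.character(pos)]
  if (anyNA(col)) abort("position not covered by the conservation panel")
  n_sp <- nrow(panel$aln)
  ci <- vapply(seq_along(col), function(i) {
    column <- panel$aln[, col[i]]
    if (column[1] == "-") abort("human row is gapped at this column")
    wt <- if (is.null(wild_type)) column[1] else str_to_upper(wild_type[min(i, length(wild_type))])
    100 * sum(column == wt) / n_sp
  }, numeric(1))
  round(ci, 2)
}

#' Reference-panel population-frequency criterion
#'
#' An allele passes when its frequency in the reference panel of
#' mitochondrial genomes is strictly below the threshold (1% of 2704
#' genomes in the reference design).
#'
#' @param count Allele count in the panel.
#' @param panel_size Panel size (default 2704).
#' @param threshold Percent threshold (default 1, strict).
#' @return Logical vector.
#' @examples
#' panel_frequency_check(4, 2704)   # 0.15% -> TRUE
#' panel_frequency_check(31, 2704)  # 1.15% -> FALSE
#' @export
panel_frequency_check <- function(count, panel_size = 2704, threshold = 1) {
  if (any(panel_size <= 0)) abort("panel_size must be positive")
  if (any(count < 0 | count > panel_size)) abort("count must lie in [0, panel_size]")
  100 * count / panel_size < threshold
}

is_watson_crick <- function(b1, b2) {
  p <- paste0(b1, b2)
  p %in% c("AT", "TA", "GC", "CG")
}

#' Structural assessment of tRNA alleles on the cloverleaf
#'
#' Locates each allele on its tRNA's cloverleaf (conventional numbering)
#' and decides whether the substitution is a structural alteration: the
#' position sits in a stem and the change converts a Watson-Crick pair
#' (A-U or G-C on the gene strand) into a non-Watson-Crick pair (G·U
#' wobble counts as non-Watson-Crick).  Anticodon-loop positions are
#' additionally flagged as functionally sensitive, without by themselves
#' counting as a structural alteration.
#'
#' @param alleles Tibble with `pos`, `ref`, `alt` (genomic orientation)
#'   and optionally `gene`.
#' @param structure tRNA structure table ([trna_structure()]) covering the
#'   alleles' genes, with `gene_strand_base` filled in.
#' @return `alleles` with `gene`, `trna_number`, `region`, `alteration`
#'   and `anticodon_loop` columns.
#' @export
structural_assessment <- function(alleles, structure) {
  stopifnot(all(c("pos", "ref", "alt") %in% names(alleles)),
            all(c("pos", "gene", "trna_number", "region", "partner_pos",
                  "strand", "gene_strand_base") %in% names(structure)))
  idx <- match(alleles$pos, structure$pos)
  if (anyNA(idx)) {
    abort(paste0("position m.", alleles$pos[which(is.na(idx))[1]],
                 " absent from the tRNA structure table"))
  }
  st <- structure[idx, ]
  n <- nrow(alleles)
  alteration <- logical(n); acl <- logical(n)
  for (i in seq_len(n)) {
    strand <- st$strand[i]
    ref_g <- if (strand == "L") complement_base(alleles$ref[i]) else alleles$ref[i]
    alt_g <- if (strand == "L") complement_base(alleles$alt[i]) else alleles$alt[i]
    if (!is.na(st$gene_strand_base[i]) && st$gene_strand_base[i] != ref_g) {
      abort(paste0("wild-type base mismatch at m.", alleles$pos[i]))
    }
    acl[i] <- st$region[i] == "anticodon loop"
    if (!is.na(st$partner_pos[i])) {
      partner <- structure$gene_strand_base[match(st$partner_pos[i], structure$pos)]
      alteration[i] <- is_watson_crick(ref_g, partner) &&
        !is_watson_crick(alt_g, partner)
    }
  }
  bind_cols(as_tibble(alleles)[setdiff(names(alleles), c("gene"))],
            tibble(gene = st$gene, trna_number = st$trna_number,
                   region = st$region, alteration = alteration,
                   anticodon_loop = acl))
}

#' Classify tRNA alleles as potentially pathogenic
#'
#' An allele is potentially pathogenic when all three criteria hold:
#' (1) it is absent from the analyzed control cohort and rare
#' (strictly below 1%) in the reference panel of mitochondrial genomes,
#' (2) its position is evolutionarily conserved (CI strictly above 75%),
#' and (3) it produces a potential structural/functional alteration of the
#' cloverleaf.
#'
#' @param verdicts Tibble with logical `absent_in_controls` and
#'   `alteration` columns, numeric `ci` (percent) and either logical
#'   `panel_ok` or `panel_count` (+ optional `panel_size`).
#' @param ci_threshold CI threshold in percent (default 75, strict).
#' @param panel_threshold Panel-frequency threshold in percent (default 1).
#' @param panel_size Panel size when `panel_count` is supplied.
#' @return `verdicts` with `panel_ok`, `ci_ok` and `pathogenic` columns.
#' @export
classify_trna <- function(verdicts, ci_threshold = 75, panel_threshold = 1,
                          panel_size = 2704) {
  need <- c("absent_in_controls", "alteration")
  if (!all(need %in% names(verdicts))) {
    abort(paste0("missing criterion column(s): ",
                 paste(setdiff(need, names(verdicts)), collapse = ", ")))
  }
  if (!("panel_ok" %in% names(verdicts))) {
    if (!("panel_count" %in% names(verdicts))) {
      abort("missing criterion: panel_ok or panel_count (population frequency)")
    }
    sz <- if ("panel_size" %in% names(verdicts)) verdicts$panel_size else panel_size
    verdicts$panel_ok <- panel_frequency_check(verdicts$panel_count, sz,
                                               panel_threshold)
  }
  if (!("ci" %in% names(verdicts)) || anyNA(verdicts$ci)) {
    abort("missing criterion: ci (conservation index)")
  }
  verdicts |>
    mutate(ci_ok = .data$ci > ci_threshold,
           pathogenic = .data$absent_in_controls & .data$panel_ok &
             .data$ci_ok & .data$alteration)
}

#' Shortlist protein alleles by combined rating and heteroplasmic fraction
#'
#' Retains alleles with at least moderate combined evidence of
#' pathogenicity (stars >= 2) whose heteroplasmic fraction exceeds the
#' metabolic threshold.
#'
#' @param alleles Tibble with `stars` and `hf` columns.
#' @param min_stars Minimum combined rating (default 2).
#' @param hf_threshold HF threshold in percent (default 40, strict).
#' @return The flagged subset of `alleles`.
#' @export
protein_shortlist <- function(alleles, min_stars = 2, hf_threshold = 40) {
  stopifnot(all(c("stars", "hf") %in% names(alleles)))
  filter(alleles, .data$stars >= min_stars,
         hf_threshold_flag(.data$hf, hf_threshold))
}
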