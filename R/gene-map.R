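#' Length of the human mitochondrial reference (rCRS / GRCh38 chrM)
#'
#' @export
MT_GENOME_LENGTH <- 16569L

#' The 37-gene human mitochondrial gene map
#'
#' Standard annotation of the revised Cambridge Reference Sequence (rCRS,
#' identical to GRCh38 chrM): 13 protein-coding genes, 22 tRNA genes and the
#' two rRNA genes, with 1-based inclusive coordinates and the strand the gene
#' is encoded on (H = heavy, L = light).  The two well-known overlaps
#' (MT-ATP8/MT-ATP6 and MT-ND4L/MT-ND4) are retained; positions outside every
#' gene (chiefly the D-loop control region) are treated as noncoding.
#'
#' @return A tibble with columns `gene`, `start`, `end`, `strand`
#'   (`"H"`/`"L"`) and `class` (`"protein"`, `"tRNA"`, `"rRNA"`).
#' @examples
#' mt_genes()
#' @export
mt_genes <- function() {
  tibble::tribble(
    ~gene,      ~start, ~end,   ~strand, ~class,
    "MT-TF",    577L,   647L,   "H",     "tRNA",
    "MT-RNR1",  648L,   1601L,  "H",     "rRNA",
    "MT-TV",    1602L,  1670L,  "H",     "tRNA",
    "MT-RNR2",  1671L,  3229L,  "H",     "rRNA",
    "MT-TL1",   3230L,  3304L,  "H",     "tRNA",
    "MT-ND1",   3307L,  4262L,  "H",     "protein",
    "MT-TI",    4263L,  4331L,  "H",     "tRNA",
    "MT-TQ",    4329L,  4400L,  "L",     "tRNA",
    "MT-TM",    4402L,  4469L,  "H",     "tRNA",
    "MT-ND2",   4470L,  5511L,  "H",     "protein",
    "MT-TW",    5512L,  5579L,  "H",     "tRNA",
    "MT-TA",    5587L,  5655L,  "L",     "tRNA",
    "MT-TN",    5657L,  5729L,  "L",     "tRNA",
    "MT-TC",    5761L,  5826L,  "L",     "tRNA",
    "MT-TY",    5826L,  5891L,  "L",     "tRNA",
    "MT-CO1",   5904L,  7445L,  "H",     "protein",
    "MT-TS1",   7446L,  7514L,  "L",     "tRNA",
    "MT-TD",    7518L,  7585L,  "H",     "tRNA",
    "MT-CO2",   7586L,  8269L,  "H",     "protein",
    "MT-TK",    8295L,  8364L,  "H",     "tRNA",
    "MT-ATP8",  8366L,  8572L,  "H",     "protein",
    "MT-ATP6",  8527L,  9207L,  "H",     "protein",
    "MT-CO3",   9207L,  9990L,  "H",     "protein",
    "MT-TG",    9991L,  10058L, "H",     "tRNA",
    "MT-ND3",   10059L, 10404L, "H",     "protein",
    "MT-TR",    10405L, 10469L, "H",     "tRNA",
    "MT-ND4L",  10470L, 10766L, "H",     "protein",
    "MT-ND4",   10760L, 12137L, "H",     "protein",
    "MT-TH",    12138L, 12206L, "H",     "tRNA",
    "MT-TS2",   12207L, 12265L, "H",     "tRNA",
    "MT-TL2",   12266L, 12336L, "H",     "tRNA",
    "MT-ND5",   12337L, 14148L, "H",     "protein",
    "MT-ND6",   14149L, 14673L, "L",     "protein",
    "MT-TE",    14674L, 14742L, "L",     "tRNA",
    "MT-CYB",   14747L, 15887L, "H",     "protein",
    "MT-TT",    15888L, 15953L, "H",     "tRNA",
    "MT-TP",    15956L, 16023L, "L",     "tRNA"
  )
}

validate_gene_map <- function(gene_map) {
  stopifnot(is.data.frame(gene_map))
  need <- c("gene", "start", "end", "strand", "class")
  if (!all(need %in% names(gene_map))) {
    abort(paste0("gene map must have columns ", paste(need, collapse = ", ")))
  }
  if (any(gene_map$start > gene_map$end)) abort("gene map has start > end")
  invisible(gene_map)
}

#' Map genomic positions to mitochondrial genes
#'
#' Positions falling in two genes (the MT-ATP8/MT-ATP6 and MT-ND4L/MT-ND4
#' overlaps) return both symbols, ordered by gene start; positions outside
#' every annotated gene return `"noncoding"`.
#'
#' @param pos Integer vector of 1-based positions on rCRS / GRCh38 chrM.
#' @param gene_map Gene map tibble, by default [mt_genes()].
#' @return A list (one element per position) of character vectors of gene
#'   symbols.
#' @examples
#' assign_gene(c(9957, 8530, 200))
#' @export
assign_gene <- function(pos, gene_map = mt_genes()) {
  validate_gene_map(gene_map)
  if (any(pos < 1 | pos > MT_GENOME_LENGTH)) {
    abort("positions must lie in 1..16569")
  }
  gm <- arrange(gene_map, .data$start)
  lapply(as.integer(pos), function(p) {
    hit <- gm$gene[gm$start <= p & p <= gm$end]
    if (length(hit) == 0) "noncoding" else hit
  })
}

#' Add gene and gene-class columns to a variant table
#'
#' One row is emitted per (observation, gene) pair, so alleles in an
#' overlapping region appear once per gene, mirroring how per-gene allele
#' counts treat overlaps.
#'
#' @param x A data frame with a `pos` column.
#' @param gene_map Gene map tibble, by default [mt_genes()].
#' @return `x` with `gene` and `gene_class` columns added (class
#'   `"noncoding"` for intergenic positions).
#' @export
add_gene <- function(x, gene_map = mt_genes()) {
  stopifnot(is.data.frame(x), "pos" %in% names(x))
  hits <- assign_gene(x$pos, gene_map)
  out <- x[rep(seq_len(nrow(x)), lengths(hits)), , drop = FALSE]
  out$gene <- unlist(hits)
  cls <- setNames(gene_map$class, gene_map$gene)
  out$gene_class <- unname(cls[out$gene])
  out$gene_class[is.na(out$gene_class)] <- "noncoding"
  as_tibble(out)
}

#' Functional class of an allele from its gene class and consequence
#'
#' @param gene_class `"protein"`, `"tRNA"`, `"rRNA"` or `"noncoding"`.
#' @param consequence For protein genes, `"synonymous"` or `"nonsynonymous"`
#'   (ignored otherwise).
#' @return Character vector over
#'   `{synonymous, nonsynonymous, tRNA, rRNA, noncoding}`.
#' @export
functional_class <- function(gene_class, consequence = NA_character_) {
  out <- gene_class
  prot <- gene_class == "protein"
  out[prot] <- consequence[if (length(consequence) == 1) rep(1, sum(prot)) else prot]
  out
}

complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}
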