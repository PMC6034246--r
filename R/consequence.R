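#' Vertebrate mitochondrial genetic code
#'
#' NCBI translation table 2, as used for the 13 mitochondrially encoded
#' proteins (AUA = Met, UGA = Trp, AGA/AGG = stop).
#'
#' @return Named character vector mapping DNA codons to one-letter amino
#'   acids (`"*"` for stop).
#' @export
mt_genetic_code <- function() {
  Biostrings::getGeneticCode("2")
}

reference_base <- function(reference, pos) {
  stopifnot(is.character(reference), length(reference) == 1)
  str_to_upper(substring(reference, pos, pos))
}

#' Call the coding consequence of a substitution in a protein gene
#'
#' Translates the reference and mutant codon under the vertebrate
#' mitochondrial genetic code.  For genes on the light (L) strand the codon
#' is read on the gene strand, i.e. the genomic allele is complemented
#' before translation; the reported amino-acid change uses the gene-strand
#' codon index (1-based from the gene start).
#'
#' @param alleles Tibble with columns `pos`, `ref`, `alt` and optionally
#'   `gene` (assigned from `gene_map` when absent; alleles outside protein
#'   genes error).
#' @param reference Reference sequence as a single character string (see
#'   [read_reference()] or [synthetic_reference()]).
#' @param gene_map Gene map tibble, by default [mt_genes()].
#' @param on_incomplete `"error"` (default) to reject alleles whose codon
#'   runs past the gene end (incomplete terminal codons, e.g. the final
#'   base of MT-CO3), or `"drop"` to silently remove them.
#' @return `alleles` with columns `gene`, `strand`, `codon_index`,
#'   `codon_position` (1-3 within the codon), `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `consequence` (`"synonymous"`/`"nonsynonymous"`)
#'   and `aa_change` (e.g. `"F251L"`, `NA` for synonymous changes).
#' @export
call_consequence <- function(alleles, reference, gene_map = mt_genes(),
                             on_incomplete = c("error", "drop")) {
  on_incomplete <- match.arg(on_incomplete)
  stopifnot(is.data.frame(alleles),
            all(c("pos", "ref", "alt") %in% names(alleles)))
  validate_gene_map(gene_map)
  code <- mt_genetic_code()
  if (!("gene" %in% names(alleles))) {
    alleles <- add_gene(alleles, gene_map)
    alleles <- filter(alleles, .data$gene_class == "protein")
  }
  gm <- gene_map[match(alleles$gene, gene_map$gene), ]
  if (anyNA(gm$gene)) abort("allele gene not found in gene map")
  if (any(gm$class != "protein")) abort("call_consequence requires protein genes")
  if (any(alleles$pos < gm$start | alleles$pos > gm$end)) {
    abort("allele position outside its gene")
  }

  n <- nrow(alleles)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- alleles$pos[i]; ref <- alleles$ref[i]; alt <- alleles$alt[i]
    strand <- gm$strand[i]
    # offset of the position along the gene strand, 0-based
    offset <- if (strand == "H") pos - gm$start[i] else gm$end[i] - pos
    codon_index <- offset %/% 3L + 1L
    within <- offset %% 3L + 1L
    codon_start_offset <- (codon_index - 1L) * 3L
    gpos <- if (strand == "H") {
      gm$start[i] + codon_start_offset + 0:2
    } else {
      gm$end[i] - codon_start_offset - 0:2
    }
    if (max(gpos) > gm$end[i] || min(gpos) < gm$start[i]) {
      if (on_incomplete == "drop") next
      abort(paste0("position ", pos, " falls in an incomplete terminal codon"))
    }
    bases <- reference_base(reference, gpos)
    if (strand == "L") bases <- complement_base(bases)
    ref_gene <- if (strand == "H") ref else complement_base(ref)
    alt_gene <- if (strand == "H") alt else complement_base(alt)
    if (bases[within] != ref_gene) {
      abort(paste0("reference base at m.", pos, " is ", bases[within],
                   " (gene strand), not ", ref_gene))
    }
    alt_codon <- ref_codon <- paste(bases, collapse = "")
    substring(alt_codon, within, within) <- alt_gene
    ref_aa <- unname(code[[ref_codon]])
    alt_aa <- unname(code[[alt_codon]])
    cons <- if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
    out[[i]] <- tibble(
      strand = strand, codon_index = codon_index, codon_position = within,
      ref_codon = ref_codon, alt_codon = alt_codon,
      ref_aa = ref_aa, alt_aa = alt_aa, consequence = cons,
      aa_change = if (cons == "nonsynonymous") {
        paste0(ref_aa, codon_index, alt_aa)
      } else NA_character_
    )
  }
  kept <- !vapply(out, is.null, logical(1))
  bind_cols(as_tibble(alleles)[kept, ], list_rbind(out[kept]))
}
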