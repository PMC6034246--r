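#' Generate a cloverleaf structure table for a mitochondrial tRNA gene
#'
#' Builds a synthetic but internally consistent cloverleaf for one of the
#' 22 mt-tRNA genes, mapping each genomic position to a conventional tRNA
#' number, a cloverleaf region and (for stem positions) its pairing
#' partner.  The canonical layout is used: acceptor stem 1-7/66-72, D-stem
#' 10-13/22-25, D-loop 14-21, anticodon stem 27-31/39-43, anticodon loop
#' 32-38, variable region 44-48, T-stem 49-53/61-65, T-loop 54-60
#' (positions 8, 9 and 26 are single-strand linkers).  Genes shorter than
#' 72 nt lose positions from the D-loop first and then the variable
#' region, mimicking the truncated D-arms and variable arms of real
#' mt-tRNAs; longer genes gain extra unpaired variable-region positions
#' (numbered 48.1, 48.2, ...).  Real curated structures can be substituted
#' through the same table schema.
#'
#' @param gene A tRNA gene symbol (e.g. `"MT-TA"`).
#' @param gene_map Gene map, by default [mt_genes()].
#' @param reference Optional reference sequence; fills `gene_strand_base`.
#' @return A tibble with columns `gene`, `pos` (genomic), `strand`,
#'   `trna_number`, `region`, `partner_number`, `partner_pos`,
#'   `gene_strand_base`.
#' @export
trna_structure <- function(gene, gene_map = mt_genes(), reference = NULL) {
  gm <- gene_map[gene_map$gene == gene, ]
  if (nrow(gm) != 1 || gm$class != "tRNA") {
    abort(paste0(gene, " is not a tRNA gene in the gene map"))
  }
  len <- gm$end - gm$start + 1L

  base_layout <- tibble(
    trna_number = as.numeric(1:72),
    region = c(rep("acceptor stem", 7), rep("linker", 2),
               rep("D-stem", 4), rep("D-loop", 8), rep("D-stem", 4),
               "linker", rep("anticodon stem", 5), rep("anticodon loop", 7),
               rep("anticodon stem", 5), rep("variable region", 5),
               rep("T-stem", 5), rep("T-loop", 7), rep("T-stem", 5),
               rep("acceptor stem", 7)),
    partner_number = c(72:66, NA, NA, 25:22, rep(NA, 8), 13:10, NA,
                       43:39, rep(NA, 7), 31:27, rep(NA, 5),
                       65:61, rep(NA, 7), 53:49, 7:1)
  )
  d <- 72L - len
  if (d > 0) {
    drop_dloop <- 21 - seq_len(min(d, 8L)) + 1      # 21, 20, ...
    drop_var <- if (d > 8) 48 - seq_len(d - 8L) + 1 else numeric(0)
    if (d > 13) abort("gene too short for the canonical cloverleaf layout")
    layout <- filter(base_layout,
                     !(.data$trna_number %in% c(drop_dloop, drop_var)))
  } else if (d < 0) {
    extra <- tibble(trna_number = 48 + seq_len(-d) / 10,
                    region = "variable region", partner_number = NA_real_)
    layout <- bind_rows(filter(base_layout, .data$trna_number <= 48), extra,
                        filter(base_layout, .data$trna_number > 48))
  } else {
    layout <- base_layout
  }

  ord <- seq_len(nrow(layout))
  pos <- if (gm$strand == "H") gm$start + ord - 1L else gm$end - ord + 1L
  st <- layout |>
    mutate(gene = gene, pos = pos, strand = gm$strand,
           partner_pos = pos[match(.data$partner_number, .data$trna_number)],
           gene_strand_base = NA_character_) |>
    select("gene", "pos", "strand", "trna_number", "region",
           "partner_number", "partner_pos", "gene_strand_base")
  if (!is.null(reference)) {
    b <- reference_base(reference, st$pos)
    st$gene_strand_base <- if (gm$strand == "L") complement_base(b) else b
  }
  st
}

#' Structure tables for all 22 mitochondrial tRNA genes
#'
#' @inheritParams trna_structure
#' @return Row-bound [trna_structure()] tables.
#' @export
trna_structures <- function(gene_map = mt_genes(), reference = NULL) {
  genes <- gene_map$gene[gene_map$class == "tRNA"]
  list_rbind(map(genes, trna_structure, gene_map = gene_map,
                 reference = reference))
}

#' Validate internal consistency of a tRNA structure table
#'
#' Checks that stem partners are mutual, that loop and linker positions
#' have no partner, and that partner numbers resolve within the gene.
#'
#' @param structure A structure table from [trna_structure()].
#' @return `TRUE` invisibly; errors describe the first inconsistency.
#' @export
validate_trna_structure <- function(structure) {
  for (g in unique(structure$gene)) {
    st <- structure[structure$gene == g, ]
    stems <- st[!is.na(st$partner_number), ]
    back <- st$partner_number[match(stems$partner_number, st$trna_number)]
    if (anyNA(back) || any(back != stems$trna_number)) {
      abort(paste0("non-mutual stem pairing in ", g))
    }
    loops <- st[st$region %in% c("D-loop", "anticodon loop", "T-loop",
                                 "variable region", "linker"), ]
    if (any(!is.na(loops$partner_number))) {
      abort(paste0("loop position with a pairing partner in ", g))
    }
  }
  invisible(TRUE)
}

#' Write tRNA structure tables as TSV
#'
#' @param structure Structure table.
#' @param path Output path.
#' @export
write_trna_structure <- function(structure, path) {
  write_tsv(structure, path, progress = FALSE)
  invisible(structure)
}

#' Read tRNA structure tables from TSV
#'
#' @param path TSV written by [write_trna_structure()] (or curated tables
#'   in the same schema).
#' @return Structure tibble.
#' @export
read_trna_structure <- function(path) {
  read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
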