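#' Map introns onto protein coordinates and type the domain introns
#'
#' For each intron of a gene model, computes its coding phase (cumulative CDS
#' length before the junction, mod 3) and the protein residue it interrupts
#' (`cumlen %/% 3 + 1`; for phase-0 introns this is the residue immediately
#' after the junction).  Introns falling inside a complete WRKY domain are
#' typed:
#'
#' * **R-type** — the splice point sits at an arginine about five residues
#'   before the domain's first finger cysteine (window `offset_r` +/-
#'   `tolerance`);
#' * **V-type** — the splice point sits at a valine about six residues after
#'   the second finger cysteine (window `offset_v` +/- `tolerance`);
#' * otherwise **untyped**.
#'
#' @param gene One row of a gene-model tibble (from [read_gff3()]), with the
#'   `cds` list-column in transcription order.
#' @param protein_seq The translated protein (stop excluded).
#' @param domains Domain tibble for this protein (from [scan_protein()]);
#'   only complete domains are used for typing.
#' @param offset_r,offset_v,tolerance Residue offsets relative to the first
#'   and second finger cysteines, and the +/- window around them.
#' @return Tibble: `gene_id`, `intron_index`, `phase`, `protein_position`,
#'   `splice_type`.
#' @export
annotate_introns <- function(gene, protein_seq, domains,
                             offset_r = 5L, offset_v = 6L, tolerance = 2L) {
  segs <- gene$cds[[1]]
  seg_len <- segs$end - segs$start + 1L
  cds_len <- sum(seg_len)
  plen <- nchar(protein_seq)
  if (!cds_len %in% c(3L * plen, 3L * plen + 3L)) {
    wrky_abort(paste0(
      "CDS length (", cds_len, ") does not match protein length (", plen,
      " aa) for gene '", gene$gene_id, "'"
    ))
  }
  n_introns <- nrow(segs) - 1L
  if (n_introns <= 0) {
    return(tibble(
      gene_id = character(), intron_index = integer(), phase = integer(),
      protein_position = integer(), splice_type = character()
    ))
  }
  chars <- strsplit(protein_seq, "")[[1]]
  complete <- domains[domains$complete, , drop = FALSE]
  cum <- cumsum(seg_len)[seq_len(n_introns)]
  phase <- as.integer(cum %% 3L)
  pos <- as.integer(cum %/% 3L + 1L)

  type_one <- function(p) {
    if (p > plen) return("untyped")
    for (j in seq_len(nrow(complete))) {
      c1 <- complete$c1[j]; c2 <- complete$c2[j]
      if (chars[p] == "R" && abs((c1 - p) - offset_r) <= tolerance) return("R-type")
      if (chars[p] == "V" && abs((p - c2) - offset_v) <= tolerance) return("V-type")
    }
    "untyped"
  }
  tibble(
    gene_id = gene$gene_id,
    intron_index = seq_len(n_introns),
    phase = phase,
    protein_position = pos,
    splice_type = if (nrow(complete) == 0) "untyped" else map_chr(pos, type_one)
  )
}

#' Annotate introns for all genes of a genome
#'
#' @param gene_models Gene-model tibble from [read_gff3()].
#' @param proteins Tibble with `id`, `sequence`; ids must match `gene_id`.
#' @param domains Domain tibble from [scan_proteins()].
#' @param ... Passed to [annotate_introns()].
#' @return Combined intron annotation tibble.
#' @export
annotate_introns_all <- function(gene_models, proteins, domains, ...) {
  rows <- map(seq_len(nrow(gene_models)), function(i) {
    g <- gene_models[i, ]
    seq <- proteins$sequence[match(g$gene_id, proteins$id)]
    if (is.na(seq)) return(NULL)
    dd <- domains[domains$protein_id == g$gene_id, , drop = FALSE]
    annotate_introns(g, seq, dd, ...)
  })
  bind_rows(rows)
}
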