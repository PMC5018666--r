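#' Read gene models from a GFF3 file
#'
#' Imports `gene`/`mRNA`/`CDS` features via [rtracklayer::import()] and
#' collapses them to one model per gene.  When a gene carries several mRNAs
#' the transcript with the longest total CDS is kept (ties go to the first in
#' file order).  CDS segments are returned in transcription order (reversed
#' for minus-strand genes) with their coding phases, so downstream intron
#' mapping can walk codons directly.
#'
#' Coordinates are 1-based inclusive genomic bp, as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per gene: `gene_id`, `chromosome`, `strand`,
#'   `start`, `end`, `exon_count`, `introns` and a list-column `cds` of
#'   tibbles (`start`, `end`, `phase`) in transcription order.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) wrky_abort(paste0("GFF3 file not found: ", path))
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  first_parent <- function(p) if (length(p) == 0) NA_character_ else p[[1]]
  df$parent <- vapply(df$Parent, first_parent, character(1))

  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  cds <- df[df$type == "CDS", ]
  if (nrow(cds) == 0) wrky_abort(paste0("no CDS features in '", path, "'"))

  # resolve each CDS to its gene: via mRNA parent, or directly under a gene
  mrna_gene <- setNames(mrnas$parent, mrnas$ID)
  cds$tx <- cds$parent
  cds$gene <- ifelse(cds$tx %in% names(mrna_gene), unname(mrna_gene[cds$tx]),
    ifelse(cds$tx %in% genes$ID, cds$tx, NA_character_)
  )
  if (anyNA(cds$gene) || anyNA(cds$tx)) {
    orphan <- cds[is.na(cds$gene) | is.na(cds$tx), ]
    wrky_abort(paste0(
      "CDS feature without a parent gene in '", path, "' (",
      orphan$seqnames[1], ":", orphan$start[1], "-", orphan$end[1], ")"
    ))
  }

  per_tx <- cds |>
    group_by(.data$gene, .data$tx) |>
    summarise(
      chromosome = .data$seqnames[1],
      strand = .data$strand[1],
      segs = list(tibble(start = start, end = end)),
      cds_len = sum(.data$end - .data$start + 1L),
      .groups = "drop"
    )
  # longest CDS per gene, first transcript on ties (file order preserved)
  per_gene <- per_tx |>
    group_by(.data$gene) |>
    filter(row_number() == which.max(.data$cds_len)) |>
    ungroup()

  models <- pmap(per_gene, function(gene, tx, chromosome, strand, segs, cds_len) {
    segs <- arrange(segs, .data$start)
    if (nrow(segs) > 1 && any(segs$start[-1] <= segs$end[-nrow(segs)])) {
      wrky_abort(paste0("overlapping CDS segments in gene '", gene, "'"))
    }
    if (identical(strand, "-")) segs <- segs[rev(seq_len(nrow(segs))), ]
    seg_len <- segs$end - segs$start + 1L
    cum_before <- cumsum(c(0L, head(seg_len, -1L)))
    segs$phase <- as.integer((3L - cum_before %% 3L) %% 3L)
    tibble(
      gene_id = gene,
      chromosome = chromosome,
      strand = strand,
      start = min(segs$start),
      end = max(segs$end),
      exon_count = nrow(segs),
      introns = nrow(segs) - 1L,
      cds = list(segs)
    )
  })
  arrange(bind_rows(models), .data$chromosome, .data$start)
}

#' Load a packaged WRKY family characterization table
#'
#' Reads a per-gene characterization table (gene name, sequence ID,
#' chromosome, group, orthologs in two reference species, protein length,
#' isoelectric point, molecular weight, intron count).  The default is the
#' packaged willow (*Salix suchowensis*) table of 85 SsWRKY genes, transcribed
#' verbatim from the published family survey.
#'
#' Ortholog cells use an en-dash for "not detected" (parsed to an empty
#' vector) and list multiple orthologs separated by `,` or `/`.  The
#' chromosome sentinel `N/A` (gene not placed on any chromosome) is parsed
#' to `NA`.
#'
#' @param path Path to a TSV table; `NULL` (default) loads the packaged
#'   willow fixture.
#' @return Tibble with columns `gene`, `sequence_id`, `chromosome`, `group`,
#'   `at_orthologs` (list), `pt_orthologs` (list), `length_aa`, `pi`,
#'   `mw_kda`, `introns`.
#' @export
#' @examples
#' fam <- load_family_table()
#' nrow(fam) # 85
load_family_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sswrky_family_table.tsv", package = "wrkyscan")
  }
  expected <- c(
    "gene", "sequence_id", "chromosome", "group", "at_orthologs",
    "pt_orthologs", "length_aa", "pi", "mw_kda", "introns"
  )
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!identical(names(tab), expected)) {
    wrky_abort(paste0(
      "family table must have ", length(expected), " columns (",
      paste(expected, collapse = ", "), "); got ", ncol(tab)
    ))
  }
  groups <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III")
  if (!all(tab$group %in% groups)) {
    wrky_abort(paste0(
      "unknown group label(s): ",
      paste(unique(setdiff(tab$group, groups)), collapse = ", ")
    ))
  }
  parse_orthologs <- function(x) {
    map(x, function(cell) {
      if (is.na(cell) || cell %in% c("–", "-", "")) character(0)
      else stringr::str_split_1(cell, "[,/]")
    })
  }
  mutate(tab,
    chromosome = ifelse(.data$chromosome == "N/A", NA_character_, .data$chromosome),
    at_orthologs = parse_orthologs(.data$at_orthologs),
    pt_orthologs = parse_orthologs(.data$pt_orthologs),
    length_aa = as.integer(.data$length_aa),
    pi = as.numeric(.data$pi),
    mw_kda = as.numeric(.data$mw_kda),
    introns = as.integer(.data$introns)
  )
}
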