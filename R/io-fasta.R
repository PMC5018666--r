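#' Read a FASTA file into a tibble
#'
#' Thin tidy wrapper around [Biostrings::readBStringSet()] with strict
#' alphabet validation.  Protein sequences are uppercased, a single terminal
#' stop (`*`) is stripped, and any residue outside the 20-letter amino-acid
#' alphabet plus `X` raises a parse error naming the offending file line.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` (default) or `"dna"`.  DNA sequences are validated
#'   against `A`, `C`, `G`, `T`, `N`.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `sequence` and `source_gene_id` (the full header line).
#'   Records keep file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "MKV"), f)
#' read_fasta(f)
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    wrky_abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) wrky_abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(set) == 0) wrky_abort(paste0("no records in FASTA '", path, "'"))
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)

  alphabet <- if (type == "protein") "ACDEFGHIKLMNPQRSTVWYX" else "ACGTN"
  bad_re <- paste0("[^", alphabet, "]")
  bad <- stringr::str_detect(seqs, bad_re) | !nzchar(seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    what <- if (!nzchar(seqs[i])) "empty sequence" else {
      paste0("illegal character '", stringr::str_extract(seqs[i], bad_re), "'")
    }
    wrky_abort(paste0(
      "FASTA parse error in '", path, "', record '", headers[i],
      "' (line ", fasta_record_line(path, i), "): ", what
    ))
  }
  tibble(
    id = stringr::str_extract(headers, "^\\S+"),
    sequence = unname(seqs),
    source_gene_id = unname(headers)
  )
}

# line number of the i-th header in a FASTA file (for error messages)
fasta_record_line <- function(path, i) {
  which(startsWith(readLines(path, warn = FALSE), ">"))[i]
}

#' Write a tibble of sequences to FASTA
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (residues per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
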