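#' Scan configuration for WRKY domain detection
#'
#' @param variants Character vector of heptapeptide variants accepted as
#'   exact matches.  The default covers the canonical WRKYGQK plus the
#'   variants recurrently reported in plant WRKY surveys.
#' @param max_mismatch Maximum Hamming distance (0 or 1) from `WRKYGQK` for a
#'   7-mer outside `variants` to still be reported (as `other-1-mismatch`).
#' @param finger_window Number of residues downstream of a heptapeptide in
#'   which the first Cys of the zinc finger may start.  The spacing between
#'   heptapeptide and finger is not fixed in nature; 80 is a permissive
#'   default for ~60-residue domains.
#' @param leucine_zipper_min Minimum number of leucines spaced exactly 7
#'   apart (heptad repeat) to call a leucine zipper.
#' @return A list of class `wrky_scan_config`.
#' @export
scan_config <- function(variants = c("WRKYGQK", "WRKYGRK", "WKKYGQK", "WRKYGKK", "WRKYGEK"),
                        max_mismatch = 1L,
                        finger_window = 80L,
                        leucine_zipper_min = 4L) {
  if (!max_mismatch %in% c(0L, 1L)) wrky_abort("max_mismatch must be 0 or 1")
  structure(
    list(
      variants = variants, max_mismatch = as.integer(max_mismatch),
      finger_window = as.integer(finger_window),
      leucine_zipper_min = as.integer(leucine_zipper_min)
    ),
    class = "wrky_scan_config"
  )
}

#' Find WRKY heptapeptides in a protein sequence
#'
#' Reports every 7-mer that is either an exact member of the allowed variant
#' set or within `max_mismatch` substitutions of the canonical `WRKYGQK`
#' (labelled `other-1-mismatch`).  Matches are reported left to right;
#' positions are 1-based.
#'
#' @param sequence Amino-acid string.
#' @param variants,max_mismatch See [scan_config()].
#' @return Tibble with columns `position`, `hepta_seq`, `variant`
#'   (empty when nothing matches).
#' @export
find_heptapeptides <- function(sequence,
                               variants = scan_config()$variants,
                               max_mismatch = 1L) {
  if (!max_mismatch %in% c(0L, 1L)) wrky_abort("max_mismatch must be 0 or 1")
  n <- nchar(sequence)
  empty <- tibble(position = integer(), hepta_seq = character(), variant = character())
  if (n < 7) return(empty)
  starts <- seq_len(n - 6L)
  kmers <- stringr::str_sub(sequence, starts, starts + 6L)
  canonical <- "WRKYGQK"
  mism <- vapply(kmers, function(k) {
    sum(utf8ToInt(k) != utf8ToInt(canonical))
  }, integer(1), USE.NAMES = FALSE)
  exact <- kmers %in% variants
  near <- !exact & mism <= max_mismatch
  keep <- exact | near
  if (!any(keep)) return(empty)
  lab <- ifelse(kmers == canonical, "canonical",
    ifelse(exact, kmers, "other-1-mismatch")
  )
  tibble(position = starts[keep], hepta_seq = kmers[keep], variant = lab[keep])
}

# concrete zinc-finger spacings, in priority order: canonical C2H2, the
# group-III C2HC, then the shortened variant C2H2 forms
zinc_finger_patterns <- function() {
  tibble(
    finger_type = c("C2H2", "C2H2", "C2H2", "C2H2", "C2HC",
                    "variant-C2H2", "variant-C2H2"),
    x1 = c(4L, 4L, 5L, 5L, 7L, 4L, 5L),
    x2 = c(22L, 23L, 22L, 23L, 23L, 21L, 19L),
    last = c("H", "H", "H", "H", "C", "H", "H")
  )
}

#' Find a spaced zinc-finger motif downstream of a heptapeptide
#'
#' Searches for the first match of the WRKY zinc-finger patterns
#' `C-X(4,5)-C-X(22,23)-H-X-H` (C2H2), `C-X7-C-X23-H-X-C` (C2HC, group III)
#' or the shortened variants `C-X4-C-X21-H-X-H` / `C-X5-C-X19-H-X-H`.
#' Among candidate matches the leftmost first Cys wins, then the shortest
#' spacing, then the pattern order above.
#'
#' @param sequence Amino-acid string.
#' @param search_start 1-based position at which the first Cys may start
#'   (typically one past the heptapeptide).
#' @param window Number of positions from `search_start` within which the
#'   first Cys must lie (the motif itself may extend past the window).
#' @return One-row tibble `finger_type`, `c1`, `c2`, `h3`, `h4`
#'   (positions of the four coordinating residues), or a zero-row tibble
#'   when no pattern fits.
#' @export
find_zinc_finger <- function(sequence, search_start, window = 80L) {
  n <- nchar(sequence)
  if (search_start < 1 || search_start > n) {
    wrky_abort(paste0("search_start ", search_start, " out of range [1, ", n, "]"))
  }
  pat <- zinc_finger_patterns()
  chars <- strsplit(sequence, "")[[1]]
  c_pos <- which(chars == "C")
  c_pos <- c_pos[c_pos >= search_start & c_pos < search_start + window]
  hits <- list()
  for (p in c_pos) {
    for (j in seq_len(nrow(pat))) {
      c2 <- p + pat$x1[j] + 1L
      h3 <- c2 + pat$x2[j] + 1L
      h4 <- h3 + 2L
      if (h4 > n) next
      if (chars[c2] == "C" && chars[h3] == "H" && chars[h4] == pat$last[j]) {
        hits[[length(hits) + 1L]] <- tibble(
          finger_type = pat$finger_type[j],
          c1 = p, c2 = c2, h3 = h3, h4 = h4, priority = j
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(
      finger_type = character(), c1 = integer(), c2 = integer(),
      h3 = integer(), h4 = integer()
    ))
  }
  best <- bind_rows(hits) |>
    arrange(.data$c1, .data$h4 - .data$c1, .data$priority) |>
    head(1)
  select(best, -"priority")
}

#' Detect WRKY domains in a single protein
#'
#' One domain is emitted per heptapeptide hit; the zinc finger is searched
#' within `finger_window` residues downstream.  Domains whose finger is
#' missing are retained with `complete = FALSE` (`domain_end` then falls at
#' the heptapeptide's last residue).  Consecutive additional finger motifs
#' after the first (before any next heptapeptide) are tallied in
#' `n_fingers`, so a one-domain/two-finger architecture is visible to the
#' classifier.
#'
#' @param sequence Amino-acid string.
#' @param protein_id Identifier carried into the output.
#' @param config A [scan_config()].
#' @return Tibble with one row per domain: `protein_id`, `hepta_start`,
#'   `hepta_seq`, `hepta_variant`, `finger_type` (`"none"` when incomplete),
#'   `c1`, `c2`, `h3`, `h4`, `domain_start`, `domain_end`, `complete`,
#'   `n_fingers`.
#' @export
scan_protein <- function(sequence, protein_id = "protein", config = scan_config()) {
  hep <- find_heptapeptides(sequence, config$variants, config$max_mismatch)
  empty <- tibble(
    protein_id = character(), hepta_start = integer(), hepta_seq = character(),
    hepta_variant = character(), finger_type = character(),
    c1 = integer(), c2 = integer(), h3 = integer(), h4 = integer(),
    domain_start = integer(), domain_end = integer(),
    complete = logical(), n_fingers = integer()
  )
  if (nrow(hep) == 0) return(empty)
  n <- nchar(sequence)
  out <- vector("list", nrow(hep))
  for (i in seq_len(nrow(hep))) {
    h_start <- hep$position[i]
    h_end <- h_start + 6L
    # extra fingers must not leak into the next heptapeptide's domain
    region_end <- if (i < nrow(hep)) hep$position[i + 1L] - 1L else n
    fingers <- list()
    from <- h_end + 1L
    while (from <= min(n, region_end)) {
      win <- min(config$finger_window, region_end - from + 1L)
      if (win <= 0) break
      zf <- find_zinc_finger(sequence, from, window = win)
      if (nrow(zf) == 0 || zf$h4 > region_end) break
      fingers[[length(fingers) + 1L]] <- zf
      from <- zf$h4 + 1L
    }
    if (length(fingers) == 0) {
      out[[i]] <- tibble(
        protein_id = protein_id, hepta_start = h_start,
        hepta_seq = hep$hepta_seq[i], hepta_variant = hep$variant[i],
        finger_type = "none", c1 = NA_integer_, c2 = NA_integer_,
        h3 = NA_integer_, h4 = NA_integer_,
        domain_start = h_start, domain_end = h_end,
        complete = FALSE, n_fingers = 0L
      )
    } else {
      zf <- fingers[[1]]
      out[[i]] <- tibble(
        protein_id = protein_id, hepta_start = h_start,
        hepta_seq = hep$hepta_seq[i], hepta_variant = hep$variant[i],
        finger_type = zf$finger_type, c1 = zf$c1, c2 = zf$c2,
        h3 = zf$h3, h4 = zf$h4,
        domain_start = h_start, domain_end = zf$h4,
        complete = TRUE, n_fingers = length(fingers)
      )
    }
  }
  bind_rows(out)
}

#' Detect WRKY domains across a proteome
#'
#' Tibble-first wrapper over [scan_protein()].
#'
#' @param proteins Tibble with columns `id` and `sequence`
#'   (as from [read_fasta()]).
#' @param config A [scan_config()].
#' @return Tibble of domains (see [scan_protein()]), all proteins combined.
#' @export
scan_proteins <- function(proteins, config = scan_config()) {
  bind_rows(map2(
    proteins$sequence, proteins$id,
    function(s, id) scan_protein(s, id, config)
  ))
}

#' Search the hand-curated accessory motifs
#'
#' Scans for the HARF motif (`RTGHARFRR[A/G]P`), the co-activator motif
#' LXXLL, the repressor motif LXLXLX (L = leucine, X = any residue) and a
#' heptad-repeat leucine zipper (`leucine_zipper_min` leucines spaced
#' exactly 7 apart).  Overlapping matches are all reported; a zipper is
#' reported once per maximal heptad run.
#'
#' @param sequence Amino-acid string.
#' @param protein_id Identifier carried into the output.
#' @param leucine_zipper_min Minimum heptad leucine count.
#' @return Tibble `protein_id`, `motif_name`, `start`, `matched_seq`.
#' @export
search_accessory_motifs <- function(sequence, protein_id = "protein",
                                    leucine_zipper_min = 4L) {
  hits <- list()
  add <- function(name, start, match) {
    hits[[length(hits) + 1L]] <<- tibble(
      protein_id = protein_id, motif_name = name,
      start = as.integer(start), matched_seq = match
    )
  }
  overlap_scan <- function(pattern, name) {
    m <- gregexpr(paste0("(?=(", pattern, "))"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1) return()
    len <- attr(m, "capture.length")[, 1]
    for (k in seq_along(m)) {
      add(name, m[k], stringr::str_sub(sequence, m[k], m[k] + len[k] - 1L))
    }
  }
  overlap_scan("RTGHARFRR[AG]P", "HARF")
  overlap_scan("L..LL", "LXXLL")
  overlap_scan("L.L.L.", "LXLXLX")
  # heptad leucine repeat: maximal runs of L at exact 7-residue spacing
  chars <- strsplit(sequence, "")[[1]]
  is_l <- chars == "L"
  n <- length(chars)
  counted <- rep(FALSE, n)
  for (p in seq_len(n)) {
    if (!is_l[p] || counted[p]) next
    run <- p
    while (run[length(run)] + 7L <= n && is_l[run[length(run)] + 7L]) {
      run <- c(run, run[length(run)] + 7L)
    }
    counted[run] <- TRUE
    if (length(run) >= leucine_zipper_min) {
      add("LeuZipper", p, stringr::str_sub(sequence, p, run[length(run)]))
    }
  }
  if (length(hits) == 0) {
    return(tibble(
      protein_id = character(), motif_name = character(),
      start = integer(), matched_seq = character()
    ))
  }
  bind_rows(hits)
}

#' Search accessory motifs across a proteome
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param leucine_zipper_min Minimum heptad leucine count.
#' @return Combined motif-hit tibble (see [search_accessory_motifs()]).
#' @export
search_motifs <- function(proteins, leucine_zipper_min = 4L) {
  bind_rows(map2(
    proteins$sequence, proteins$id,
    function(s, id) search_accessory_motifs(s, id, leucine_zipper_min)
  ))
}
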