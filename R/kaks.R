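# codon -> amino acid (standard code; "*" = stop)
codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

# per-codon synonymous site count under the 1/3-per-position convention:
# for each position, the fraction of the three single-nucleotide mutations
# that preserve the amino acid (mutations to stop codons count as
# nonsynonymous), so synonymous + nonsynonymous sites = 3 exactly
syn_sites <- local({
  cache <- new.env(parent = emptyenv())
  function(codon) {
    if (!is.null(cache[[codon]])) return(cache[[codon]])
    cache[[codon]] <- syn_sites_compute(codon)
    cache[[codon]]
  }
})

syn_sites_compute <- function(codon) {
  aa <- codon_aa(codon)
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substring(codon, pos, pos))) {
      mut <- codon
      substring(mut, pos, pos) <- b
      if (identical(codon_aa(mut), aa)) s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons; pathways passing through a stop codon are excluded unless every
# pathway does
codon_differences <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- list(
    list(1L), list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )[[k]]
  walk <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0; stopped <- FALSE
    for (idx in order) {
      pos <- diff_pos[idx]
      nxt <- cur
      substring(nxt, pos, pos) <- substring(c2, pos, pos)
      aa1 <- codon_aa(cur); aa2 <- codon_aa(nxt)
      if (identical(aa1, aa2)) sd <- sd + 1 else nd <- nd + 1
      if (aa2 == "*") stopped <- TRUE
      cur <- nxt
    }
    c(sd = sd, nd = nd, stopped = as.numeric(stopped))
  }
  res <- vapply(perms, walk, numeric(3))
  ok <- res["stopped", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(sd = mean(res["sd", ok]), nd = mean(res["nd", ok]))
}

jukes_cantor <- function(p) {
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

#' Ka/Ks by the Nei-Gojobori counting method
#'
#' Back-translates a protein alignment to a codon alignment, counts
#' synonymous and nonsynonymous sites per codon (1/3-per-position
#' convention over single-nucleotide mutations; sites sum to 3 per codon)
#' and pathway-averaged synonymous/nonsynonymous differences, then applies
#' the Jukes-Cantor correction to each proportion.  Site totals are the
#' average of the two sequences over the compared codons.  Codon pairs with
#' ambiguous bases (`N`) or a gap in either row are skipped.
#'
#' @param cds_a,cds_b Coding sequences (lengths divisible by 3; a trailing
#'   stop codon is stripped; internal stops are an error).
#' @param protein_alignment Optional two-element character vector of aligned
#'   (gapped) protein rows; when `NULL` the translations are aligned
#'   globally with [align_pair()].  Degapped rows must equal the
#'   translations.
#' @return One-row tibble: `ka`, `ks`, `ka_ks` (`NA` when `ks` is 0;
#'   saturated proportions, p >= 3/4, give `Inf` distances).
#' @export
#' @examples
#' kaks_nei_gojobori("TTTGGG", "TTCGGG") # synonymous-only divergence
kaks_nei_gojobori <- function(cds_a, cds_b, protein_alignment = NULL) {
  prep <- function(cds, which) {
    if (nchar(cds) %% 3 != 0) {
      wrky_abort(paste0("CDS ", which, " length not divisible by 3"))
    }
    codons <- split_codons(toupper(cds))
    aa <- ifelse(grepl("N", codons), "X", codon_aa(codons))
    if (length(aa) > 0 && !is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(aa == "*", na.rm = TRUE)) {
      wrky_abort(paste0("internal stop codon in CDS ", which))
    }
    list(codons = codons, protein = paste(aa, collapse = ""))
  }
  a <- prep(cds_a, "a")
  b <- prep(cds_b, "b")
  if (is.null(protein_alignment)) {
    al <- align_pair(a$protein, b$protein, mode = "global-affine")
    protein_alignment <- c(al$aligned_a, al$aligned_b)
  }
  rows <- strsplit(protein_alignment, "")
  if (gsub("-", "", protein_alignment[1]) != a$protein ||
      gsub("-", "", protein_alignment[2]) != b$protein) {
    wrky_abort("protein_alignment rows do not match the CDS translations")
  }
  ia <- 0L; ib <- 0L
  s_tot <- 0; n_tot <- 0; sd_tot <- 0; nd_tot <- 0
  for (col in seq_along(rows[[1]])) {
    ga <- rows[[1]][col] == "-"; gb <- rows[[2]][col] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) next
    ca <- a$codons[ia]; cb <- b$codons[ib]
    if (grepl("N", ca) || grepl("N", cb)) next
    s_tot <- s_tot + (syn_sites(ca) + syn_sites(cb)) / 2
    n_tot <- n_tot + 3 - (syn_sites(ca) + syn_sites(cb)) / 2
    d <- codon_differences(ca, cb)
    sd_tot <- sd_tot + d["sd"]
    nd_tot <- nd_tot + d["nd"]
  }
  if (s_tot == 0 && n_tot == 0) wrky_abort("no comparable codons between sequences")
  ks <- unname(jukes_cantor(sd_tot / s_tot))
  ka <- unname(jukes_cantor(nd_tot / n_tot))
  tibble(
    ka = ka, ks = ks,
    ka_ks = if (ks == 0) NA_real_ else unname(ka / ks)
  )
}

#' All-pairs Ka/Ks for a gene set
#'
#' Runs [kaks_nei_gojobori()] over every unordered pair, e.g. the all-pairs
#' analysis of a family's group III members (k genes give k(k-1)/2 pairs).
#'
#' @param cds Tibble with `id` and `sequence` (coding sequences).
#' @param purifying_threshold Pairs with `ka_ks` below this are flagged as
#'   evolving under purifying selection.
#' @return Tibble: `gene_a`, `gene_b`, `ka`, `ks`, `ka_ks`, `purifying`.
#' @export
kaks_all_pairs <- function(cds, purifying_threshold = 0.5) {
  n <- nrow(cds)
  rows <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        kk <- kaks_nei_gojobori(cds$sequence[i], cds$sequence[j])
        rows[[length(rows) + 1L]] <- mutate(kk,
          gene_a = cds$id[i], gene_b = cds$id[j], .before = 1
        )
      }
    }
  }
  out <- if (length(rows) == 0) {
    tibble(
      gene_a = character(), gene_b = character(),
      ka = numeric(), ks = numeric(), ka_ks = numeric()
    )
  } else {
    bind_rows(rows)
  }
  mutate(out, purifying = !is.na(.data$ka_ks) & .data$ka_ks < purifying_threshold)
}
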