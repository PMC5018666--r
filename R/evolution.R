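#' Screen all protein pairs for homology
#'
#' Aligns every unordered pair (local affine alignment, BLOSUM62) and keeps
#' pairs passing both screening thresholds: aligned coverage of the longer
#' protein and percent identity over alignment columns.  The defaults are
#' the duplicate-gene screen used for plant gene-family surveys (coverage
#' >= 80% of the longer gene, identity >= 65%).
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param min_coverage,min_identity Thresholds in percent.
#' @return Tibble: `gene_a`, `gene_b`, `identity_pct`, `coverage_pct`,
#'   `score`.
#' @export
find_homolog_pairs <- function(proteins, min_coverage = 80, min_identity = 65) {
  n <- nrow(proteins)
  empty <- tibble(
    gene_a = character(), gene_b = character(),
    identity_pct = numeric(), coverage_pct = numeric(), score = numeric()
  )
  if (n < 2) return(empty)
  rows <- list()
  for (j in 2:n) {
    idx <- seq_len(j - 1)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins$sequence[idx]),
      Biostrings::AAString(proteins$sequence[j]),
      substitutionMatrix = "BLOSUM62", type = "local",
      gapOpening = 10, gapExtension = 0.5
    )
    len_a <- nchar(proteins$sequence[idx])
    len_b <- nchar(proteins$sequence[j])
    span_a <- al@pattern@range@width
    span_b <- al@subject@range@width
    longer <- pmax(len_a, len_b)
    span <- ifelse(len_a >= len_b, span_a, span_b)
    coverage <- 100 * span / longer
    cand <- which(coverage >= min_coverage)
    if (length(cand) == 0) next
    pa <- as.character(Biostrings::alignedPattern(al[cand]))
    pb <- as.character(Biostrings::alignedSubject(al[cand]))
    for (k in seq_along(cand)) {
      ac <- strsplit(pa[k], "")[[1]]
      bc <- strsplit(pb[k], "")[[1]]
      identity <- 100 * sum(ac == bc & ac != "-") / length(ac)
      if (identity >= min_identity) {
        i <- idx[cand[k]]
        rows[[length(rows) + 1L]] <- tibble(
          gene_a = proteins$id[i], gene_b = proteins$id[j],
          identity_pct = identity, coverage_pct = coverage[cand[k]],
          score = BiocGenerics::score(al)[cand[k]]
        )
      }
    }
  }
  if (length(rows) == 0) empty else bind_rows(rows)
}

#' Classify a homologous pair as tandem or segmental duplication
#'
#' Tandem duplication: both genes on the same chromosome, no other family
#' gene between them, and start-to-start distance at most `window_bp`.
#' Segmental duplication: genes on different chromosomes.  Same-chromosome
#' pairs that are not adjacent (or too far apart) are `"unclassified"` by
#' default, or `"segmental"` with `distant_as_segmental = TRUE`.  Pairs with
#' an unplaced member are always `"unclassified"`.
#'
#' @param pair One-row tibble (or list) with `gene_a`, `gene_b`.
#' @param gene_models Gene-model tibble (`gene_id`, `chromosome`, `start`).
#' @param family_gene_ids Character vector of all family gene ids (used for
#'   the adjacency test).
#' @param window_bp Maximum start-to-start distance for a tandem call.
#' @param distant_as_segmental Treat non-adjacent same-chromosome pairs as
#'   segmental.
#' @return `"tandem"`, `"segmental"` or `"unclassified"`.
#' @export
classify_duplication <- function(pair, gene_models, family_gene_ids,
                                 window_bp = 200000,
                                 distant_as_segmental = FALSE) {
  a <- gene_models[match(pair$gene_a, gene_models$gene_id), ]
  b <- gene_models[match(pair$gene_b, gene_models$gene_id), ]
  if (nrow(a) == 0 || nrow(b) == 0 || is.na(a$chromosome) || is.na(b$chromosome)) {
    return("unclassified")
  }
  if (!identical(a$chromosome, b$chromosome)) return("segmental")
  lo <- min(a$start, b$start); hi <- max(a$start, b$start)
  between <- gene_models |>
    filter(
      .data$gene_id %in% family_gene_ids,
      .data$chromosome == a$chromosome,
      .data$start > lo, .data$start < hi,
      !.data$gene_id %in% c(pair$gene_a, pair$gene_b)
    )
  adjacent <- nrow(between) == 0
  if (adjacent && (hi - lo) <= window_bp) return("tandem")
  if (distant_as_segmental) "segmental" else "unclassified"
}

#' Find duplicate gene pairs and classify them
#'
#' Convenience wrapper: [find_homolog_pairs()] then [classify_duplication()]
#' per pair.
#'
#' @inheritParams find_homolog_pairs
#' @inheritParams classify_duplication
#' @return Homolog-pair tibble with a `dup_class` column.
#' @export
find_duplications <- function(proteins, gene_models,
                              min_coverage = 80, min_identity = 65,
                              window_bp = 200000,
                              distant_as_segmental = FALSE) {
  pairs <- find_homolog_pairs(proteins, min_coverage, min_identity)
  if (nrow(pairs) == 0) return(mutate(pairs, dup_class = character(0)))
  pairs$dup_class <- map_chr(seq_len(nrow(pairs)), function(i) {
    classify_duplication(pairs[i, ], gene_models, proteins$id,
                         window_bp, distant_as_segmental)
  })
  pairs
}

#' Reciprocal-best-hit orthologs between two proteomes
#'
#' Scores every cross-genome pair by local affine alignment (BLOSUM62) and
#' keeps pair (a, b) when b is a's best hit, a is b's best hit, and the
#' score reaches `min_score` (an absolute score floor standing in for a
#' database E-value cutoff; the default is far above what unrelated random
#' proteins attain).  Ties in best-hit selection go to the first protein in
#' input order.
#'
#' For group I proteins (two WRKY domains) an extra concordance rule is
#' applied when domain tables are supplied: the N-terminal domains of a and
#' b must be mutual nearest partners among group I N-domains, and likewise
#' the C-terminal domains, mirroring the requirement that the two domain
#' phylogenies tell the same story.  Pairs failing concordance are dropped
#' and reported with `concordant_domains = FALSE` in the attribute
#' `"rejected"`.
#'
#' @param proteome_a,proteome_b Tibbles with `id`, `sequence`.
#' @param min_score Minimum alignment score.
#' @param domains_a,domains_b Optional domain tibbles (from
#'   [scan_proteins()]) to enable the group I concordance rule.
#' @return Tibble: `gene_a`, `gene_b`, `score`, `concordant_domains`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, min_score = 100,
                                 domains_a = NULL, domains_b = NULL) {
  if (nrow(proteome_a) == 0 || nrow(proteome_b) == 0) {
    wrky_abort("both proteomes must be non-empty")
  }
  # score matrix: rows = proteome_a, cols = proteome_b
  scores <- vapply(
    proteome_b$sequence,
    function(s) alignment_scores(proteome_a$sequence, s),
    numeric(nrow(proteome_a))
  )
  scores <- matrix(scores, nrow = nrow(proteome_a))
  best_b <- apply(scores, 1, which.max)
  best_a <- apply(scores, 2, which.max)
  keep <- which(best_a[best_b] == seq_len(nrow(proteome_a)))
  out <- tibble(
    gene_a = proteome_a$id[keep],
    gene_b = proteome_b$id[best_b[keep]],
    score = scores[cbind(keep, best_b[keep])]
  )
  out <- filter(out, .data$score >= min_score)
  out$concordant_domains <- TRUE

  if (!is.null(domains_a) && !is.null(domains_b) && nrow(out) > 0) {
    two_dom <- function(domains) {
      tab <- table(domains$protein_id)
      names(tab)[tab >= 2]
    }
    gi_a <- two_dom(domains_a); gi_b <- two_dom(domains_b)
    dom_seq <- function(proteome, domains, id, which_dom) {
      dd <- domains[domains$protein_id == id, ]
      dd <- dd[order(dd$hepta_start), ][which_dom, ]
      seq <- proteome$sequence[match(id, proteome$id)]
      stringr::str_sub(seq, dd$domain_start, dd$domain_end)
    }
    concord <- map_lgl(seq_len(nrow(out)), function(k) {
      a <- out$gene_a[k]; b <- out$gene_b[k]
      if (!(a %in% gi_a && b %in% gi_b)) return(TRUE)
      ok <- map_lgl(1:2, function(w) {
        qa <- dom_seq(proteome_a, domains_a, a, w)
        d <- map_dbl(gi_b, function(cand) {
          pairwise_p_distance(qa, dom_seq(proteome_b, domains_b, cand, w))
        })
        # b must be a nearest partner (ties, e.g. identical duplicated
        # domains, do not break concordance)
        d[match(b, gi_b)] <= min(d) + 1e-12
      })
      all(ok)
    })
    rejected <- mutate(out[!concord, ], concordant_domains = FALSE)
    out <- out[concord, ]
    attr(out, "rejected") <- rejected
  }
  out
}
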