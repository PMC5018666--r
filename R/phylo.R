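# alignment objects are named character vectors of equal-length gapped rows;
# helpers convert to/from a character matrix (rows = sequences)
alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (length(unique(nchar(alignment))) != 1) {
    wrky_abort("alignment rows differ in length")
  }
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  m
}

alignment_strings <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

# BLOSUM62 restricted to the 20 amino acids, loaded once
blosum20 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      data("BLOSUM62", package = "Biostrings", envir = environment())
      aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
      cache <<- get("BLOSUM62", envir = environment())[aa, aa]
    }
    cache
  }
})

# column frequency profile (21 x L: 20 residues + gap)
profile_freq <- function(m) {
  aa <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")
  apply(m, 2, function(col) {
    col[!col %in% aa] <- "-" # X and friends score as gaps (0)
    tabulate(match(col, aa), nbins = 21) / length(col)
  })
}

# global profile-profile alignment (sum-of-pairs column score, linear gap)
align_profiles <- function(ma, mb, gap = -8) {
  fa <- profile_freq(ma)[1:20, , drop = FALSE]
  fb <- profile_freq(mb)[1:20, , drop = FALSE]
  S <- t(fa) %*% blosum20() %*% fb
  la <- ncol(ma); lb <- ncol(mb)
  M <- matrix(0, la + 1, lb + 1)
  M[1, ] <- gap * (0:lb)
  M[, 1] <- gap * (0:la)
  ptr <- matrix(0L, la + 1, lb + 1) # 1 diag, 2 up (gap in b), 3 left (gap in a)
  ptr[1, -1] <- 3L; ptr[-1, 1] <- 2L
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cand <- c(M[i, j] + S[i, j], M[i, j + 1] + gap, M[i + 1, j] + gap)
      k <- which.max(cand)
      M[i + 1, j + 1] <- cand[k]
      ptr[i + 1, j + 1] <- k
    }
  }
  # traceback
  i <- la; j <- lb
  cols_a <- integer(0); cols_b <- integer(0)
  while (i > 0 || j > 0) {
    k <- ptr[i + 1, j + 1]
    if (k == 1L) {
      cols_a <- c(i, cols_a); cols_b <- c(j, cols_b); i <- i - 1; j <- j - 1
    } else if (k == 2L) {
      cols_a <- c(i, cols_a); cols_b <- c(0L, cols_b); i <- i - 1
    } else {
      cols_a <- c(0L, cols_a); cols_b <- c(j, cols_b); j <- j - 1
    }
  }
  take <- function(m, cols) {
    out <- matrix("-", nrow(m), length(cols))
    out[, cols > 0] <- m[, cols[cols > 0], drop = FALSE]
    rownames(out) <- rownames(m)
    out
  }
  rbind(take(ma, cols_a), take(mb, cols_b))
}

#' Progressive multiple sequence alignment
#'
#' A guide-tree progressive aligner for short, domain-scale sequences:
#' pairwise global-alignment identities give a distance matrix, a
#' neighbor-joining guide tree (midpoint-rooted) fixes the merge order, and
#' profiles are merged by global profile-profile dynamic programming with
#' sum-of-pairs BLOSUM62 column scores and a linear gap penalty.  Degapping
#' any output row recovers the corresponding input exactly.
#'
#' @param sequences Character vector of at least two amino-acid sequences.
#' @param labels Optional names (default `seq1..seqN` or existing names).
#' @param gap Linear gap penalty per inserted column.
#' @return Named character vector of gapped rows, input
#'   order preserved.
#' @export
progressive_msa <- function(sequences, labels = NULL, gap = -8) {
  n <- length(sequences)
  if (n < 2) wrky_abort("progressive_msa needs at least 2 sequences")
  if (is.null(labels)) {
    labels <- if (!is.null(names(sequences))) names(sequences) else paste0("seq", seq_len(n))
  }
  sequences <- unname(sequences)
  if (n == 2) {
    al <- align_pair(sequences[1], sequences[2], mode = "global-affine")
    out <- setNames(c(al$aligned_a, al$aligned_b), labels)
    return(out)
  }
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (j in 2:n) {
    idx <- seq_len(j - 1)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(sequences[idx]), Biostrings::AAString(sequences[j]),
      substitutionMatrix = "BLOSUM62", type = "global",
      gapOpening = 10, gapExtension = 0.5
    )
    pa <- as.character(Biostrings::alignedPattern(al))
    pb <- as.character(Biostrings::alignedSubject(al))
    ident <- map_dbl(seq_along(idx), function(i) {
      ac <- strsplit(pa[i], "")[[1]]; bc <- strsplit(pb[i], "")[[1]]
      sum(ac == bc & ac != "-") / length(ac)
    })
    d[idx, j] <- d[j, idx] <- 1 - ident
  }
  guide <- phangorn::midpoint(neighbor_joining(d))
  merge_node <- function(node) {
    ntip <- length(guide$tip.label)
    if (node <= ntip) {
      m <- matrix(strsplit(sequences[match(guide$tip.label[node], labels)], "")[[1]], nrow = 1)
      rownames(m) <- guide$tip.label[node]
      return(m)
    }
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    Reduce(function(a, b) align_profiles(a, b, gap = gap), lapply(kids, merge_node))
  }
  m <- merge_node(length(guide$tip.label) + 1L)
  m <- m[match(labels, rownames(m)), , drop = FALSE]
  alignment_strings(m)
}

#' p-distance matrix with pairwise gap deletion
#'
#' For each sequence pair, columns gapped in either row are excluded and the
#' distance is the proportion of mismatches over the compared columns.
#'
#' @param alignment Named character vector of gapped rows, or a character
#'   matrix (rows = sequences).
#' @return Symmetric numeric matrix with zero diagonal, labelled by row
#'   names.
#' @export
p_distance <- function(alignment) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2) wrky_abort("p_distance needs at least 2 rows")
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  gapped <- m == "-"
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      keep <- !gapped[i, ] & !gapped[j, ]
      if (!any(keep)) {
        wrky_abort(paste0("no shared ungapped columns between '",
                          labs[i], "' and '", labs[j], "'"))
      }
      d[i, j] <- d[j, i] <- sum(m[i, keep] != m[j, keep]) / sum(keep)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration.  Ties in the Q-criterion are broken by
#' the lowest index pair, so the result is deterministic; negative branch
#' lengths are clamped to zero with a warning.  On an additive distance
#' matrix the generating topology and branch lengths are recovered exactly.
#'
#' @param dm Symmetric distance matrix with labelled rows (or a `dist`).
#' @return An unrooted [ape] `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) wrky_abort("distance matrix is not symmetric")
  n <- nrow(dm)
  if (n < 3) wrky_abort("neighbor_joining needs at least 3 taxa")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  clamped <- 0L
  clamp <- function(x) {
    bad <- x < 0
    clamped <<- clamped + sum(bad)
    ifelse(bad, 0, x)
  }
  fmt <- function(x) sprintf("%.17g", x)
  nodes <- labs # newick fragment per active node
  D <- unname(dm)
  while (length(nodes) > 3) {
    r <- length(nodes)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest-index pair among minima
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    newick <- paste0("(", nodes[i], ":", fmt(li), ",", nodes[j], ":", fmt(lj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    nodes <- c(nodes[keep], newick)
  }
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  if (clamped > 0) {
    warning(clamped, " negative branch length(s) clamped to 0", call. = FALSE)
  }
  newick <- paste0(
    "(", nodes[1], ":", fmt(l1), ",", nodes[2], ":", fmt(l2), ",",
    nodes[3], ":", fmt(l3), ");"
  )
  ape::read.tree(text = newick)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the reference tree from the full alignment (p-distance, pairwise
#' gap deletion, then [neighbor_joining()]), resamples alignment columns
#' with replacement `n_reps` times via [ape::boot.phylo()], and annotates
#' each internal node with the percentage of replicate trees containing its
#' bipartition.  Deterministic for a fixed `seed`.
#'
#' @param alignment Alignment (named character vector or matrix).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return The reference `phylo` tree with `node.label` set to support
#'   percentages in `[0, 100]`.
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1) {
  if (n_reps < 1) wrky_abort("n_reps must be >= 1")
  m <- alignment_matrix(alignment)
  build <- function(x) neighbor_joining(p_distance(x))
  ref <- build(m)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  counts <- suppressWarnings(
    ape::boot.phylo(ref, m, build, B = n_reps, rooted = FALSE, quiet = TRUE)
  )
  ref$node.label <- 100 * counts / n_reps
  ref
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
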