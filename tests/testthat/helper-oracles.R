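# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results by brute force or exhaustive search
# and never call the code paths they verify.

# Gotoh affine-gap global alignment score (gap of length L costs
# open + ext * L, matching the aligner's convention), BLOSUM62
oracle_global_score <- function(a, b, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  M <- get("BLOSUM62", envir = environment())
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  S <- matrix(NEG, n + 1, m + 1) # end in match
  P <- matrix(NEG, n + 1, m + 1) # end in gap in b (up)
  Q <- matrix(NEG, n + 1, m + 1) # end in gap in a (left)
  S[1, 1] <- 0
  for (i in 2:(n + 1)) P[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Q[1, j] <- -(open + ext * (j - 1))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- max(S[i, j], P[i, j], Q[i, j])
      S[i + 1, j + 1] <- best + M[ac[i], bc[j]]
      P[i + 1, j + 1] <- max(S[i, j + 1] - open - ext,
                             P[i, j + 1] - ext,
                             Q[i, j + 1] - open - ext)
      Q[i + 1, j + 1] <- max(S[i + 1, j] - open - ext,
                             Q[i + 1, j] - ext,
                             P[i + 1, j] - open - ext)
    }
  }
  max(S[n + 1, m + 1], P[n + 1, m + 1], Q[n + 1, m + 1])
}

# dense grid-scan pI: argmin |net charge| over a pH grid
oracle_pi_grid <- function(sequence, step = 5e-4) {
  chars <- strsplit(sequence, "")[[1]]
  pka <- c(Nterm = 7.50, Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00,
           Y = 10.00, H = 5.98, K = 10.00, R = 12.00)
  counts <- vapply(c("D", "E", "C", "Y", "H", "K", "R"),
                   function(a) sum(chars == a), numeric(1))
  grid <- seq(0, 14, by = step)
  charge <- vapply(grid, function(ph) {
    pos <- sum(c(1, counts[c("K", "R", "H")]) /
                 (1 + 10^(ph - pka[c("Nterm", "K", "R", "H")])))
    neg <- sum(c(1, counts[c("D", "E", "C", "Y")]) /
                 (1 + 10^(pka[c("Cterm", "D", "E", "C", "Y")] - ph)))
    pos - neg
  }, numeric(1))
  grid[which.min(abs(charge))]
}

# exhaustive search over the three unrooted 4-taxon topologies: returns the
# topology (as a split of taxon 1's partner) with zero least-squares
# residual against an additive matrix, plus the residual
oracle_quartet <- function(D) {
  stopifnot(nrow(D) == 4)
  taxa <- rownames(D)
  splits <- list(c(2, 3, 4), c(3, 2, 4), c(4, 2, 3)) # partner of taxon 1
  best <- NULL
  for (s in splits) {
    # topology ((1,s1),(s2,s3)); solve the 5 branch lengths from 6 distances
    a <- s[1]; b <- s[2]; c <- s[3]
    internal <- (D[1, b] + D[a, c] - D[1, a] - D[b, c]) / 2
    x1 <- (D[1, a] + D[1, b] - D[a, b]) / 2
    xa <- D[1, a] - x1
    xb <- D[1, b] - x1 - internal
    xc <- D[1, c] - x1 - internal
    pred <- D
    pred[1, a] <- pred[a, 1] <- x1 + xa
    pred[1, b] <- pred[b, 1] <- x1 + internal + xb
    pred[1, c] <- pred[c, 1] <- x1 + internal + xc
    pred[a, b] <- pred[b, a] <- xa + internal + xb
    pred[a, c] <- pred[c, a] <- xa + internal + xc
    pred[b, c] <- pred[c, b] <- xb + xc
    resid <- sum((pred - D)^2)
    if (is.null(best) || resid < best$resid) {
      best <- list(partner = taxa[a], resid = resid, internal = internal)
    }
  }
  best
}

# brute-force leucine heptad check: is there any start with >= k leucines
# spaced exactly 7 apart?
oracle_heptad <- function(sequence, k = 4) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  for (p in seq_len(n)) {
    run <- 0
    q <- p
    while (q <= n && chars[q] == "L") {
      run <- run + 1
      q <- q + 7
    }
    if (run >= k) return(TRUE)
  }
  FALSE
}

# sum-of-pairs score of an alignment under BLOSUM62 with a flat gap-column
# cost, used to sanity-check the progressive aligner
oracle_sp_score <- function(rows, gap = -8) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  M <- get("BLOSUM62", envir = environment())
  m <- do.call(rbind, strsplit(rows, ""))
  total <- 0
  for (i in seq_len(nrow(m) - 1)) {
    for (j in seq((i + 1), nrow(m))) {
      for (col in seq_len(ncol(m))) {
        a <- m[i, col]; b <- m[j, col]
        if (a == "-" && b == "-") next
        total <- total + if (a == "-" || b == "-") gap else M[a, b]
      }
    }
  }
  total
}

# small synthetic genome used by several suites (kept modest for speed)
tiny_synth_config <- function(seed = 1L) {
  synth_config(
    seed = seed,
    subgroup_counts = c(I = 2, IIa = 1, IIb = 1, IIc = 2, IId = 1, IIe = 1, III = 2),
    n_tandem = 1L, n_segmental = 1L, cluster_sizes = c(2L)
  )
}
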