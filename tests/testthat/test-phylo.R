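test_that("p-distance applies pairwise gap deletion", {
  expect_equal(p_distance(c(a = "ACGT", b = "ACGA"))["a", "b"], 0.25)
  # the gapped column is excluded: 3 compared columns, 0 mismatches
  expect_equal(p_distance(c(a = "AC-T", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_error(p_distance(c(a = "--AA", b = "TT--")), "no shared ungapped")
  expect_error(p_distance(c(a = "ACGT")), "at least 2")
})

test_that("p-distance stays in [0,1] and grows with added mismatch columns", {
  set.seed(71)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    d0 <- p_distance(c(a = a, b = b))["a", "b"]
    expect_gte(d0, 0); expect_lte(d0, 1)
    d1 <- p_distance(c(a = paste0(a, "A"), b = paste0(b, "T")))["a", "b"]
    expect_gte(d1, d0)
  }
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("additive matrices are recovered exactly, matching exhaustive search", {
  tr0 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):1);")
  D <- ape::cophenetic.phylo(tr0)
  tr <- neighbor_joining(D)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
  # brute force over the three unrooted quartet topologies agrees
  q <- oracle_quartet(D[c("A", "B", "C", "D"), c("A", "B", "C", "D")])
  expect_equal(q$partner, "B")
  expect_equal(q$resid, 0, tolerance = 1e-18)

  # 5-taxon additive case
  tr5 <- ape::read.tree(text = "(((A:1,B:1):0.5,C:2):0.7,(D:1,E:0.3):0.4);")
  D5 <- ape::cophenetic.phylo(tr5)
  out5 <- neighbor_joining(D5)
  expect_equal(ape::cophenetic.phylo(out5)[rownames(D5), colnames(D5)], D5,
               tolerance = 1e-12)
})

test_that("NJ is deterministic under ties and validates its input", {
  dm <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  t1 <- ape::write.tree(neighbor_joining(dm))
  t2 <- ape::write.tree(neighbor_joining(dm))
  expect_identical(t1, t2)
  bad <- dm; bad[1, 2] <- 5
  expect_error(neighbor_joining(bad), "not symmetric")
  expect_error(neighbor_joining(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ topology agrees with an independent implementation", {
  set.seed(73)
  for (rep in 1:4) {
    X <- matrix(runif(49, 0.1, 1), 7, 7)
    D <- (X + t(X)) / 2; diag(D) <- 0
    rownames(D) <- colnames(D) <- paste0("t", 1:7)
    expect_equal(
      ape::dist.topo(ape::unroot(neighbor_joining(D)), ape::unroot(ape::nj(D))),
      structure(0, names = "PH85"),
      ignore_attr = TRUE
    )
  }
})

test_that("progressive MSA preserves inputs and reduces to pairwise for n = 2", {
  seqs <- c("WRKYGQKDET", "WRKYGQKDET", "WRKYGQKDET")
  msa <- progressive_msa(seqs)
  expect_false(any(grepl("-", msa)))
  expect_equal(unname(gsub("-", "", msa)), seqs)

  two <- c("ACDEFGHIKL", "ACDEGHIKL")
  m2 <- progressive_msa(two)
  al <- align_pair(two[1], two[2], mode = "global-affine")
  expect_equal(unname(m2), c(al$aligned_a, al$aligned_b))

  set.seed(75)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rnd <- vapply(1:4, function(i) {
    paste(sample(aas, sample(18:24, 1), replace = TRUE), collapse = "")
  }, character(1))
  m <- progressive_msa(rnd)
  expect_equal(unname(gsub("-", "", m)), rnd)
  expect_equal(length(unique(nchar(m))), 1L)

  expect_error(progressive_msa("ACDE"), "at least 2")
})

test_that("MSA sum-of-pairs score is locally optimal against gap moves", {
  set.seed(77)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- paste(sample(aas, 20, replace = TRUE), collapse = "")
  mut <- function(s) {
    chars <- strsplit(s, "")[[1]]
    drop <- sample(length(chars), 2)
    paste(chars[-drop], collapse = "")
  }
  seqs <- c(base, mut(base), mut(base))
  msa <- progressive_msa(seqs)
  sp0 <- oracle_sp_score(unname(msa))
  rows <- strsplit(unname(msa), "")
  # move each gap to every other position within its row: no variant scores higher
  for (r in seq_along(rows)) {
    gaps <- which(rows[[r]] == "-")
    for (gpos in gaps) {
      for (newpos in seq_along(rows[[r]])[-gpos]) {
        v <- rows
        row <- v[[r]][-gpos]
        v[[r]] <- append(row, "-", after = newpos - 1)
        variant <- vapply(v, paste, character(1), collapse = "")
        expect_lte(oracle_sp_score(variant), sp0 + 1e-9)
      }
    }
  }
})

test_that("bootstrap supports separate planted clades and respect the seed", {
  seqs <- c(
    a1 = "AAAAAAAAAAAAAAAAAAGG", a2 = "AAAAAAAAAAAAAAAAAAGC",
    a3 = "AAAAAAAAAAAAAAAACAGG",
    b1 = "TTTTTTTTTTTTTTTTTTGG", b2 = "TTTTTTTTTTTTTTTTTCGG"
  )
  tr <- bootstrap_support(seqs, n_reps = 100, seed = 5)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_gte(max(sup), 95) # the a/b split is essentially certain

  tr2 <- bootstrap_support(seqs, n_reps = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)

  one <- bootstrap_support(seqs, n_reps = 1, seed = 2)
  expect_true(all(one$node.label[!is.na(one$node.label)] %in% c(0, 100)))

  # permuting input rows leaves bipartition supports unchanged
  perm <- seqs[c(3, 1, 5, 2, 4)]
  tr3 <- bootstrap_support(perm, n_reps = 100, seed = 5)
  split_support <- function(tree) {
    parts <- ape::prop.part(tree)
    labs <- attr(parts, "labels")
    keys <- vapply(seq_along(parts), function(i) {
      paste(sort(labs[parts[[i]]]), collapse = "+")
    }, character(1))
    setNames(tree$node.label, keys)
  }
  s1 <- split_support(tr); s3 <- split_support(tr3)
  common <- intersect(names(s1), names(s3))
  expect_gte(length(common), 2L)
  expect_equal(s1[common], s3[common])
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  seqs <- c(a = "AAAAAAAAGG", b = "AAAAAAAAGC", c = "TTTTTTTTGG", d = "TTTTTTTCGG")
  tr <- bootstrap_support(seqs, n_reps = 50, seed = 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_setequal(na.omit(as.numeric(back$node.label)),
                  na.omit(as.numeric(tr$node.label)))
})
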