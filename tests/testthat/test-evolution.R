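random_protein <- function(n, seed = NULL) {
  aas <- strsplit("ADEFGIKLMNPQSTVWY", "")[[1]]
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

mutate_at <- function(s, k) {
  chars <- strsplit(s, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(LETTERS[LETTERS %in% strsplit("ADEFGIKLMNPQSTVWY", "")[[1]]], chars[p]), 1)
  paste(chars, collapse = "")
}

test_that("homolog screening applies both identity and coverage thresholds", {
  set.seed(51)
  base <- random_protein(200)
  near <- mutate_at(base, 20)   # ~90% identity, full coverage -> kept
  far <- mutate_at(base, 80)    # ~60% identity -> dropped
  half <- substr(base, 1, 100)  # identical but ~50% coverage -> dropped
  prot <- tibble::tibble(
    id = c("base", "near", "far", "half"),
    sequence = c(base, near, far, half)
  )
  pairs <- find_homolog_pairs(prot)
  key <- paste(pairs$gene_a, pairs$gene_b)
  expect_true("base near" %in% key)
  expect_false(any(grepl("far", key)))
  expect_false(any(grepl("half", key)))
  expect_true(all(pairs$identity_pct >= 65 & pairs$coverage_pct >= 80))
})

test_that("duplication classes follow chromosome and adjacency rules", {
  gm <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    chromosome = c("Chr1", "Chr1", "Chr5", "Chr1", NA),
    start = c(100000L, 150000L, 100000L, 5e6L, 1L)
  )
  fam <- gm$gene_id
  pair <- function(x, y) tibble::tibble(gene_a = x, gene_b = y)
  expect_equal(classify_duplication(pair("a", "b"), gm, fam), "tandem")
  expect_equal(classify_duplication(pair("a", "c"), gm, fam), "segmental")
  # same chromosome, far apart, another family gene between
  expect_equal(classify_duplication(pair("a", "d"), gm, fam), "unclassified")
  expect_equal(classify_duplication(pair("a", "d"), gm, fam,
                                    distant_as_segmental = TRUE), "segmental")
  expect_equal(classify_duplication(pair("a", "e"), gm, fam), "unclassified")
})

test_that("tandem is never called across chromosomes", {
  set.seed(53)
  gm <- tibble::tibble(
    gene_id = paste0("g", 1:20),
    chromosome = sample(paste0("Chr", 1:4), 20, replace = TRUE),
    start = sample.int(1e6, 20)
  )
  for (i in 1:19) {
    for (j in (i + 1):20) {
      cls <- classify_duplication(
        tibble::tibble(gene_a = paste0("g", i), gene_b = paste0("g", j)),
        gm, gm$gene_id
      )
      if (gm$chromosome[i] != gm$chromosome[j]) expect_equal(cls, "segmental")
      if (cls == "tandem") expect_equal(gm$chromosome[i], gm$chromosome[j])
    }
  }
})

test_that("reciprocal best hits require mutual bests and a score floor", {
  set.seed(55)
  prot <- tibble::tibble(
    id = paste0("p", 1:5),
    sequence = vapply(1:5, function(i) random_protein(150), character(1))
  )
  # two identical proteomes: every gene pairs with its copy
  other <- dplyr::mutate(prot, id = paste0("q", 1:5))
  rbh <- reciprocal_best_hits(prot, other)
  expect_equal(nrow(rbh), 5L)
  expect_equal(sub("q", "p", rbh$gene_b), rbh$gene_a)

  # reciprocity: a's best hit b whose best hit is a different gene -> no pair
  a1 <- random_protein(150)
  pa <- tibble::tibble(id = c("a1", "a2"), sequence = c(a1, mutate_at(a1, 60)))
  pb <- tibble::tibble(id = "b", sequence = mutate_at(a1, 8))
  rbh2 <- reciprocal_best_hits(pa, pb)
  expect_equal(rbh2$gene_a, "a1") # only the mutual pair survives
  expect_equal(nrow(rbh2), 1L)

  # unrelated random proteins never reach the default score floor
  ra <- tibble::tibble(id = paste0("r", 1:6),
                       sequence = vapply(1:6, function(i) random_protein(300), character(1)))
  rb <- tibble::tibble(id = paste0("s", 1:6),
                       sequence = vapply(1:6, function(i) random_protein(300), character(1)))
  expect_equal(nrow(reciprocal_best_hits(ra, rb)), 0L)

  expect_error(reciprocal_best_hits(prot[0, ], other), "non-empty")
})

test_that("manifest orthologs are recovered at >= 95% on a synthetic pair of genomes", {
  g <- generate_genome(tiny_synth_config(seed = 13))
  orth <- generate_ortholog_proteome(g)
  rbh <- reciprocal_best_hits(
    g$proteins, orth$proteins,
    domains_a = scan_proteins(g$proteins),
    domains_b = scan_proteins(orth$proteins)
  )
  truth <- paste(orth$ortholog_map$gene_a, orth$ortholog_map$gene_b)
  expect_gte(mean(truth %in% paste(rbh$gene_a, rbh$gene_b)), 0.95)
})
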