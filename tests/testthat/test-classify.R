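mk_domain <- function(id = "p", finger_type = "C2H2", complete = TRUE,
                      n_fingers = 1L, hepta_start = 10L) {
  tibble::tibble(
    protein_id = id, hepta_start = hepta_start, hepta_seq = "WRKYGQK",
    hepta_variant = "canonical", finger_type = finger_type,
    c1 = hepta_start + 15L, c2 = hepta_start + 20L,
    h3 = hepta_start + 43L, h4 = hepta_start + 45L,
    domain_start = hepta_start, domain_end = hepta_start + 45L,
    complete = complete, n_fingers = n_fingers
  )
}

test_that("structural group rules follow domain count and finger type", {
  two <- dplyr::bind_rows(mk_domain(), mk_domain(hepta_start = 100L))
  g <- assign_group(two)
  expect_equal(g$group, "I")
  expect_equal(g$domain_labels[[1]], c("p-N", "p-C"))

  expect_equal(assign_group(mk_domain(finger_type = "C2HC"))$group, "III")
  expect_equal(assign_group(mk_domain())$group, "II")
  expect_true(assign_group(mk_domain())$subgroup_pending)

  # one domain with two finger motifs: the SsWRKY78 rule puts it in group I
  expect_equal(assign_group(mk_domain(n_fingers = 2L))$group, "I")

  # incomplete finger: provisionally group II, flagged
  inc <- mk_domain(finger_type = "none", complete = FALSE, n_fingers = 0L)
  expect_equal(assign_group(inc)$evidence, "incomplete_finger")

  expect_error(assign_group(mk_domain()[0, ]), "not a family member")
})

test_that("subgroup placement: exact reference match, ties, planted recovery", {
  panel <- generate_reference_panel()
  iia <- panel$sequence[panel$label == "IIa"]

  # query identical to the IIa exemplar: distance 0
  expect_equal(assign_subgroup(iia, panel, method = "nearest")$subgroup, "IIa")

  # constructed tie: two references at equal Hamming distance from the query
  ref_a <- "WRKYGQKAAAAAAAAAA"
  ref_b <- "WRKYGQKAAAAAAAAGG"
  query <- "WRKYGQKAAAAAAAAAG" # one mismatch from each
  tie_panel <- tibble::tibble(
    label = c("IIa", "IIb", "IIc", "IId", "IIe"),
    sequence = c(ref_a, ref_b, "WRKYGQKTTTTTTTTTT", "WRKYGQKSSSSSSSSSS",
                 "WRKYGQKQQQQQQQQQQ")
  )
  res <- assign_subgroup(query, tie_panel, method = "nearest")
  expect_equal(res$subgroup, "IIa") # first in panel order wins
  expect_true(res$tie)

  # planted IId domain (template + noise) is recovered by both methods
  set.seed(21)
  tpl <- strsplit(panel$sequence[panel$label == "IId"], "")[[1]]
  free <- setdiff(seq_along(tpl), c(1:7, 15, 20, 25, 31, 48, 50))
  tpl[sample(free, 3)] <- "A"
  noisy <- paste(tpl, collapse = "")
  expect_equal(assign_subgroup(noisy, panel, method = "nearest")$subgroup, "IId")
  expect_equal(assign_subgroup(noisy, panel, method = "tree")$subgroup, "IId")

  expect_error(assign_subgroup(iia, panel[0, ]), "empty reference panel")
  expect_error(assign_subgroup(iia, panel[panel$label == "IIa", ]), "lacks subgroup")
})

test_that("every scanned protein receives exactly one group label", {
  g <- generate_genome(tiny_synth_config(seed = 3))
  doms <- scan_proteins(g$proteins)
  cls <- suppressWarnings(
    classify_proteins(doms, g$proteins, generate_reference_panel(), method = "nearest")
  )
  expect_setequal(cls$protein_id, unique(doms$protein_id))
  expect_equal(anyDuplicated(cls$protein_id), 0L)
  expect_true(all(cls$group %in% c("I", paste0("II", letters[1:5]), "III", "unclassified")))
})

test_that("group-level counts on the willow table give 19 / 59 / 7", {
  s <- summarize_family(load_family_table())
  expect_equal(unname(s$group_counts["I"]), 19L)
  expect_equal(unname(s$group_counts["II"]), 59L)
  expect_equal(unname(s$group_counts["III"]), 7L)
})
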