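pad <- function(core, left = 10, right = 10) {
  paste0(strrep("A", left), core, strrep("A", right))
}

test_that("heptapeptide variants are found and labelled", {
  hits <- find_heptapeptides(pad("WRKYGQK"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 11L)
  expect_equal(hits$variant, "canonical")

  # the WRKYGRK variant (as carried by SsWRKY78-like proteins)
  expect_equal(find_heptapeptides(pad("WRKYGRK"))$variant, "WRKYGRK")
  expect_equal(find_heptapeptides(pad("WKKYGQK"))$variant, "WKKYGQK")

  # three mismatches from WRKYGQK: no hit even with max_mismatch = 1
  expect_equal(nrow(find_heptapeptides(pad("WRKYAAA"), max_mismatch = 1)), 0L)

  # an unlisted single mismatch is reported as other-1-mismatch,
  # but not under max_mismatch = 0
  expect_equal(find_heptapeptides(pad("WRKYGQR"))$variant, "other-1-mismatch")
  expect_equal(nrow(find_heptapeptides(pad("WRKYGQR"), max_mismatch = 0)), 0L)
  expect_error(find_heptapeptides(pad("WRKYGQK"), max_mismatch = 2), "0 or 1")
})

finger <- function(x1, x2, last) {
  paste0("C", strrep("A", x1), "C", strrep("A", x2), "H", "A", last)
}

test_that("zinc finger patterns match with their spacings and positions", {
  s <- pad(finger(4, 22, "H"), left = 5)
  zf <- find_zinc_finger(s, 1)
  expect_equal(zf$finger_type, "C2H2")
  expect_equal(zf$c1, 6L)
  expect_equal(zf$c2, 6L + 5L)
  chars <- strsplit(s, "")[[1]]
  expect_equal(chars[c(zf$c1, zf$c2)], c("C", "C"))
  expect_equal(chars[zf$h3], "H")

  zf2 <- find_zinc_finger(pad(finger(7, 23, "C"), left = 5), 1)
  expect_equal(zf2$finger_type, "C2HC")

  # the shortened forms reported in willow (C-X4-C-X21 and C-X5-C-X19)
  expect_equal(find_zinc_finger(pad(finger(4, 21, "H"), left = 5), 1)$finger_type,
               "variant-C2H2")
  expect_equal(find_zinc_finger(pad(finger(5, 19, "H"), left = 5), 1)$finger_type,
               "variant-C2H2")

  expect_equal(nrow(find_zinc_finger(strrep("A", 120), 1)), 0L)
  expect_error(find_zinc_finger("ACDEF", 99), "out of range")
})

test_that("scan_protein emits one domain per heptapeptide and keeps incomplete ones", {
  unit <- paste0("WRKYGQK", strrep("A", 10), finger(4, 22, "H"))
  two <- pad(paste0(unit, strrep("A", 20), unit))
  doms <- scan_protein(two, "gI")
  expect_equal(nrow(doms), 2L)
  expect_true(all(doms$complete))
  expect_equal(doms$finger_type, c("C2H2", "C2H2"))

  # heptapeptide with a scrambled finger region: retained, incomplete
  lone <- pad(paste0("WRKYGQK", strrep("A", 60)))
  d1 <- scan_protein(lone, "x")
  expect_equal(nrow(d1), 1L)
  expect_false(d1$complete)
  expect_equal(d1$finger_type, "none")
  expect_equal(d1$domain_end, d1$hepta_start + 6L)

  # one heptapeptide followed by two consecutive fingers (SsWRKY78-like)
  s78 <- pad(paste0("WRKYGRK", strrep("A", 10), finger(4, 22, "H"),
                    strrep("A", 5), finger(4, 22, "H")))
  d78 <- scan_protein(s78, "w78")
  expect_equal(nrow(d78), 1L)
  expect_equal(d78$n_fingers, 2L)
})

test_that("scan positions shift exactly with a non-matching prefix", {
  base <- pad(paste0("WRKYGQK", strrep("A", 10), finger(4, 22, "H")))
  d0 <- scan_protein(base, "p")
  for (k in c(1, 7, 23)) {
    dk <- scan_protein(paste0(strrep("G", k), base), "p")
    expect_equal(dk$hepta_start, d0$hepta_start + k)
    expect_equal(dk$c1, d0$c1 + k)
    expect_equal(dk$domain_end, d0$domain_end + k)
  }
})

test_that("accessory motifs are detected, with a brute-force heptad oracle", {
  harf <- search_accessory_motifs(pad("RTGHARFRRAP"), "m")
  expect_true("HARF" %in% harf$motif_name)
  expect_equal(harf$matched_seq[harf$motif_name == "HARF"], "RTGHARFRRAP")
  expect_true("HARF" %in% search_accessory_motifs(pad("RTGHARFRRGP"))$motif_name)
  expect_false("HARF" %in% search_accessory_motifs(pad("RTGHARFRRTP"))$motif_name)

  lx <- search_accessory_motifs(pad("LKDLL"), "m")
  expect_true("LXXLL" %in% lx$motif_name)
  expect_true("LXLXLX" %in% search_accessory_motifs(pad("LALALA"))$motif_name)

  zip <- "LAAAAAALAAAAAALAAAAAAL"
  hits <- search_accessory_motifs(zip, "z")
  expect_true("LeuZipper" %in% hits$motif_name)
  expect_true(oracle_heptad(zip, 4))
  # three heptad leucines only: below the default threshold, and the oracle agrees
  zip3 <- "LAAAAAALAAAAAAL"
  expect_false("LeuZipper" %in% search_accessory_motifs(zip3)$motif_name)
  expect_false(oracle_heptad(zip3, 4))

  # every reported match equals the protein substring at its start
  all_hits <- search_accessory_motifs(pad("RTGHARFRRAPLKDLLXLALALA"), "m")
  s <- pad("RTGHARFRRAPLKDLLXLALALA")
  for (i in seq_len(nrow(all_hits))) {
    expect_equal(
      substr(s, all_hits$start[i], all_hits$start[i] + nchar(all_hits$matched_seq[i]) - 1L),
      all_hits$matched_seq[i]
    )
  }
})

test_that("the scanner recovers every planted domain with exact variant labels", {
  g <- generate_genome(tiny_synth_config(seed = 7))
  doms <- scan_proteins(g$proteins)
  man <- g$manifest$genes
  for (i in seq_len(nrow(man))) {
    d <- doms[doms$protein_id == man$gene_id[i], ]
    want <- man$domains[[i]]
    expect_equal(nrow(d), nrow(want))
    expect_equal(d$hepta_start, want$start)
    expect_equal(d$c1, want$c1)
    expect_true(all(d$complete))
  }
  # variant labels match the manifest (canonical or the planted variant string)
  single <- man[man$n_domains == 1, ]
  d1 <- doms[match(single$gene_id, doms$protein_id), ]
  expect_equal(
    ifelse(d1$hepta_variant == "canonical", "canonical", d1$hepta_variant),
    single$variant
  )
})
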