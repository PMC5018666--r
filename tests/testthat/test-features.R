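test_that("molecular weight matches hand-summed average masses", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-3)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 1e-3)
  # one water per chain regardless of length
  expect_equal(
    molecular_weight("GGG") - molecular_weight("GG"),
    molecular_weight("GG") - molecular_weight("G"),
    tolerance = 1e-9
  )
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("GZ"), "unknown residue")
  expect_equal(molecular_weight("X"), 110 + 18.01524, tolerance = 1e-6)
})

test_that("isoelectric point behaves for charged peptides and matches a grid scan", {
  expect_lt(isoelectric_point("DDDD"), 4.5)
  expect_gt(isoelectric_point("KKKK"), 9)
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:5) {
    s <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    expect_equal(isoelectric_point(s), oracle_pi_grid(s), tolerance = 0.011)
  }
})

test_that("protein_properties reports table-style rounding", {
  p <- tibble::tibble(id = "x", sequence = strrep("G", 100))
  props <- protein_properties(p)
  expect_equal(props$length_aa, 100L)
  expect_equal(props$mw_kda, round((100 * 57.0519 + 18.01524) / 1000, 1))
  expect_equal(props$pi, round(isoelectric_point(p$sequence), 2))
})

# a minimal one-gene model with introns at chosen protein positions/phases
toy_gene <- function(protein, introns_at, phases, intron_len = 100L) {
  plen <- nchar(protein)
  cds_len <- 3L * plen + 3L
  junctions <- 3L * (introns_at - 1L) + phases
  bounds <- c(0L, junctions, cds_len)
  seg_len <- diff(bounds)
  starts <- integer(length(seg_len)); ends <- integer(length(seg_len))
  pos <- 1000L
  for (i in seq_along(seg_len)) {
    starts[i] <- pos; ends[i] <- pos + seg_len[i] - 1L
    pos <- ends[i] + 1L + intron_len
  }
  tibble::tibble(
    gene_id = "toy", chromosome = "Chr1", strand = "+",
    start = min(starts), end = max(ends),
    exon_count = length(seg_len), introns = length(seg_len) - 1L,
    cds = list(tibble::tibble(start = starts, end = ends, phase = 0L))
  )
}

test_that("domain introns are typed R/V by position and residue", {
  tpl <- synth_template("IIc") # C2H2 layout, R at 15, V at 31, C1 20, C2 25
  protein <- paste0(strrep("A", 20), tpl, strrep("A", 20))
  doms <- scan_protein(protein, "toy")
  r_pos <- 20L + 15L # global position of the R five residues before C1

  ann <- annotate_introns(toy_gene(protein, r_pos, 2L), protein, doms)
  expect_equal(ann$splice_type, "R-type")
  expect_equal(ann$protein_position, r_pos)
  expect_equal(ann$phase, 2L)

  v_pos <- 20L + 31L
  annv <- annotate_introns(toy_gene(protein, v_pos, 0L), protein, doms)
  expect_equal(annv$splice_type, "V-type")

  # an intron far downstream of the domain is untyped
  far <- nchar(protein) - 5L
  expect_equal(annotate_introns(toy_gene(protein, far, 0L), protein, doms)$splice_type,
               "untyped")

  # no typing without a complete domain
  ann0 <- annotate_introns(toy_gene(protein, r_pos, 2L), protein, doms[0, ])
  expect_equal(ann0$splice_type, "untyped")

  bad <- toy_gene(protein, r_pos, 2L)
  expect_error(annotate_introns(bad, paste0(protein, "AAAA"), doms), "does not match")
})

test_that("intron phases agree with cumulative CDS length on synthetic genes", {
  g <- generate_genome(tiny_synth_config(seed = 5))
  doms <- scan_proteins(g$proteins)
  ann <- annotate_introns_all(g$gene_models, g$proteins, doms)
  man <- g$manifest$genes
  for (i in seq_len(nrow(man))) {
    a <- ann[ann$gene_id == man$gene_id[i], ]
    expect_equal(a$protein_position, man$intron_positions[[i]])
    expect_equal(a$phase, as.integer(man$intron_phases[[i]]))
    expect_equal(a$splice_type, man$intron_types[[i]])
    # exon lengths sum to the CDS length
    segs <- g$gene_models$cds[[match(man$gene_id[i], g$gene_models$gene_id)]]
    expect_equal(sum(segs$end - segs$start + 1L),
                 nchar(g$cds$sequence[g$cds$id == man$gene_id[i]]))
  }
})
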