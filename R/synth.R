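# ---- fixed domain templates ------------------------------------------------
# One 60-residue template per subgroup, built deterministically (no RNG).
# Layout (1-based, C2H2 form):      Layout (C2HC form, group III):
#   1-7   WRKYGQK                     1-7   WRKYGQK
#   8-19  filler, R at 15             8-19  filler, R at 15
#   20    C  (first finger Cys)       20    C
#   21-24 filler                      21-27 filler
#   25    C  (second finger Cys)      28    C
#   26-47 filler, V at 31 (= C2+6)    29-51 filler
#   48    H                           52    H
#   49    filler                      53    filler
#   50    H                           54    C
#   51-60 filler tail                 55-60 filler tail
# The filler alphabet avoids C/H/R/V/W so the only finger-pattern and
# intron-anchor residues are the planted ones.

SYNTH_FILLERS <- c(
  "I-N" = "QAG", "I-C" = "EKT",
  IIa = "AEK", IIb = "GDS", IIc = "STQ", IId = "TPE", IIe = "NQA",
  III = "DLS"
)
SYNTH_BG_ALPHABET <- strsplit("ADEFGIKLMNPQSTY", "")[[1]]

synth_template <- function(label) {
  filler <- strsplit(SYNTH_FILLERS[[label]], "")[[1]]
  fill <- function(k, offset = 0) {
    paste(filler[((offset + seq_len(k) - 1) %% 3) + 1], collapse = "")
  }
  c2hc <- identical(label, "III")
  s1 <- strsplit(fill(12), "")[[1]]
  s1[8] <- "R" # template position 15 = C1 - 5
  s1 <- paste(s1, collapse = "")
  if (!c2hc) {
    s3 <- strsplit(fill(22, 3), "")[[1]]
    s3[6] <- "V" # template position 31 = C2 + 6
    s3 <- paste(s3, collapse = "")
    paste0("WRKYGQK", s1, "C", fill(4, 1), "C", s3, "H", fill(1, 2), "H", fill(10, 0))
  } else {
    paste0("WRKYGQK", s1, "C", fill(7, 1), "C", fill(23, 2), "H", fill(1, 0), "C", fill(6, 1))
  }
}

# template positions that must never be mutated (hepta, R/V anchors, finger)
synth_constrained_idx <- function(label) {
  if (identical(label, "III")) c(1:7, 15, 20, 28, 52, 54) else c(1:7, 15, 20, 25, 31, 48, 50)
}

# within-domain positions of the key residues, for manifest bookkeeping
synth_domain_layout <- function(label) {
  if (identical(label, "III")) {
    list(len = 60L, c1 = 20L, c2 = 28L, r_pos = 15L, v_pos = NA_integer_,
         finger_type = "C2HC")
  } else {
    list(len = 60L, c1 = 20L, c2 = 25L, r_pos = 15L, v_pos = 31L,
         finger_type = "C2H2")
  }
}

# one fixed codon per amino acid (reverse translation); stop = TAA
SYNTH_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", E = "GAA",
  Q = "CAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

reverse_translate <- function(protein) {
  paste(SYNTH_CODON[strsplit(protein, "")[[1]]], collapse = "")
}

#' Configuration for the synthetic WRKY genome generator
#'
#' The defaults emulate, at desk scale, the architecture of a plant WRKY
#' family survey: group counts proportional to a real family (a few dozen
#' genes rather than 85), group-specific zinc-finger types, R-type introns
#' in groups I(C)/IIc/IId/IIe/III and V-type introns in IIa/IIb, group III
#' genes with exactly two introns, planted 200-kb gene clusters, tandem and
#' segmental duplicate pairs at controlled protein identity, and
#' negative-binomial expression counts over five tissues.
#'
#' @param seed RNG seed; all outputs are deterministic given the seed.
#' @param n_chromosomes Number of chromosomes.  The last chromosome is
#'   reserved for segmental duplicates so they always land on a different
#'   chromosome than their source.
#' @param chromosome_length Length of every chromosome in bp.
#' @param subgroup_counts Named vector of planted gene counts per subgroup
#'   (`I`, `IIa`..`IIe`, `III`).
#' @param variant_rate Probability that a single-domain gene carries a
#'   non-canonical heptapeptide variant.
#' @param hepta_variants Variant pool for non-canonical heptapeptides.
#' @param noise_rate Per-position mutation rate applied to unconstrained
#'   template positions of each planted domain.
#' @param n_tandem,n_segmental Number of tandem / segmental duplicate pairs.
#' @param duplicate_identity Target protein percent identity of duplicate
#'   pairs (must be in (65, 100]).
#' @param cluster_sizes Sizes of planted gene clusters.
#' @param intra_cluster_gap,tandem_gap,inter_unit_gap Start-to-start
#'   distances (bp) within clusters, within tandem pairs, and between
#'   placement units (the latter must exceed the 200-kb cluster window).
#' @param ortholog_mutation_rate Per-position substitution rate (outside
#'   domains) used to derive the orthologous proteome.
#' @param tissues Tissue names for the expression model.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of per-gene mean
#'   expression.
#' @param expr_dispersion Negative-binomial size parameter.
#' @param min_template_divergence Minimum pairwise divergence required
#'   between subgroup templates (guards against an unlearnable panel).
#' @return A list of class `wrky_synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_chromosomes = 5L,
                         chromosome_length = 5e6,
                         subgroup_counts = c(I = 6, IIa = 2, IIb = 3, IIc = 7,
                                             IId = 4, IIe = 3, III = 3),
                         variant_rate = 0.1,
                         hepta_variants = c("WRKYGRK", "WKKYGQK", "WRKYGKK"),
                         noise_rate = 0.03,
                         n_tandem = 2L,
                         n_segmental = 4L,
                         duplicate_identity = 90,
                         cluster_sizes = c(3L, 2L),
                         intra_cluster_gap = 50000,
                         tandem_gap = 40000,
                         inter_unit_gap = 400000,
                         ortholog_mutation_rate = 0.05,
                         tissues = c("root", "stem", "bark", "bud", "leaf"),
                         expr_meanlog = 2.5, expr_sdlog = 1.2,
                         expr_dispersion = 5,
                         min_template_divergence = 0.2) {
  if (duplicate_identity <= 65 || duplicate_identity > 100) {
    wrky_abort("duplicate_identity must be in (65, 100]")
  }
  if (any(subgroup_counts < 0)) wrky_abort("subgroup counts must be >= 0")
  structure(as.list(environment()), class = "wrky_synth_config")
}

# mutate a protein at `n_mut` positions drawn from `allowed` (1-based)
mutate_protein <- function(protein, n_mut, allowed) {
  if (n_mut == 0 || length(allowed) == 0) return(protein)
  chars <- strsplit(protein, "")[[1]]
  pos <- sample(allowed, min(n_mut, length(allowed)))
  for (p in pos) {
    chars[p] <- sample(setdiff(SYNTH_BG_ALPHABET, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# build one gene's protein, domain table and intron plan
synth_build_gene <- function(group, subgroup, variant, cfg) {
  n_flank <- sample(40:80, 1)
  c_flank <- sample(40:80, 1)
  bg <- function(k) paste(sample(SYNTH_BG_ALPHABET, k, replace = TRUE), collapse = "")

  one_domain <- function(label, variant) {
    tpl <- strsplit(synth_template(label), "")[[1]]
    if (variant != "canonical") tpl[1:7] <- strsplit(variant, "")[[1]]
    free <- setdiff(seq_along(tpl), synth_constrained_idx(label))
    n_mut <- rbinom(1, length(free), cfg$noise_rate)
    for (p in sample(free, n_mut)) {
      tpl[p] <- sample(setdiff(SYNTH_BG_ALPHABET, tpl[p]), 1)
    }
    paste(tpl, collapse = "")
  }

  if (group == "I") {
    linker <- sample(25:40, 1)
    dn <- one_domain("I-N", "canonical")
    dc <- one_domain("I-C", variant)
    protein <- paste0(bg(n_flank), dn, bg(linker), dc, bg(c_flank))
    d1 <- n_flank + 1L
    d2 <- n_flank + 60L + linker + 1L
    lay <- synth_domain_layout("I-C")
    doms <- tibble(
      domain = c("N", "C"),
      start = c(d1, d2), end = c(d1, d2) + 59L,
      c1 = c(d1, d2) + lay$c1 - 1L, c2 = c(d1, d2) + lay$c2 - 1L,
      r_pos = c(d1, d2) + lay$r_pos - 1L, v_pos = c(d1, d2) + lay$v_pos - 1L
    )
    anchor <- doms[2, ] # conserved intron lives in the C-terminal domain
  } else {
    lab <- if (group == "III") "III" else subgroup
    dom <- one_domain(lab, variant)
    protein <- paste0(bg(n_flank), dom, bg(c_flank))
    d1 <- n_flank + 1L
    lay <- synth_domain_layout(lab)
    doms <- tibble(
      domain = "single",
      start = d1, end = d1 + lay$len - 1L,
      c1 = d1 + lay$c1 - 1L, c2 = d1 + lay$c2 - 1L,
      r_pos = d1 + lay$r_pos - 1L,
      v_pos = if (is.na(lay$v_pos)) NA_integer_ else d1 + lay$v_pos - 1L
    )
    anchor <- doms[1, ]
  }
  plen <- nchar(protein)

  # conserved domain intron: V-type (phase 0) for IIa/IIb, R-type (phase 2)
  # elsewhere; plus group-specific numbers of flank introns
  if (subgroup %in% c("IIa", "IIb")) {
    dom_intron <- tibble(protein_position = anchor$v_pos, phase = 0L, splice_type = "V-type")
  } else {
    dom_intron <- tibble(protein_position = anchor$r_pos, phase = 2L, splice_type = "R-type")
  }
  n_extra <- switch(group, I = 2L, III = 1L, II = switch(subgroup,
    IIa = 2L, IIb = 2L, 1L
  ))
  flank_pos <- c(seq(5, n_flank - 5), seq(plen - c_flank + 5, plen - 5))
  flank_pos <- setdiff(flank_pos, dom_intron$protein_position)
  extra <- sort(sample(flank_pos, n_extra))
  extras <- tibble(
    protein_position = extra,
    phase = sample(0:2, n_extra, replace = TRUE),
    splice_type = "untyped"
  )
  introns <- arrange(bind_rows(dom_intron, extras), .data$protein_position)
  introns$junction <- 3L * (introns$protein_position - 1L) + introns$phase

  list(protein = protein, domains = doms, introns = introns)
}

# genomic CDS segments for a gene, given junctions and intron lengths
synth_segments <- function(cds_len, junctions, intron_lengths, start, strand) {
  bounds <- c(0L, junctions, cds_len)
  seg_len <- diff(bounds)
  seg_start <- integer(length(seg_len))
  seg_end <- integer(length(seg_len))
  pos <- start
  for (i in seq_along(seg_len)) {
    seg_start[i] <- pos
    seg_end[i] <- pos + seg_len[i] - 1L
    pos <- seg_end[i] + 1L + if (i < length(seg_len)) intron_lengths[i] else 0L
  }
  segs <- tibble(start = seg_start, end = seg_end)
  if (strand == "-") { # mirror so transcription runs downhill in genome coords
    total_end <- max(segs$end)
    new_start <- start + (total_end - segs$end)
    new_end <- start + (total_end - segs$start)
    segs <- tibble(start = new_start, end = new_end)
  }
  segs
}

#' Generate a synthetic genome with planted WRKY-family structure
#'
#' Emits a proteome, matching CDS set, GFF3 gene models and a per-tissue
#' count table, together with a ground-truth manifest covering every planted
#' feature: group/subgroup, heptapeptide variant, domain coordinates, intron
#' positions and R/V types, cluster memberships and duplicate pairs with
#' their tandem/segmental class.  Deterministic for a fixed config seed; at
#' generation time every CDS is checked to translate back to its protein and
#' every planted domain is re-detected by the scanner.
#'
#' @param config A [synth_config()].
#' @param dir Optional directory: when given, writes `proteins.fa`,
#'   `cds.fa`, `genes.gff3`, `counts.tsv` and flattened manifest TSVs.
#' @return List of class `wrky_synth_genome`: `proteins`, `cds` (tibbles
#'   `id`/`sequence`), `gene_models` (as [read_gff3()] would return),
#'   `counts`, `gene_lengths`, and `manifest` (list of tibbles `genes`,
#'   `clusters`, `duplications`).
#' @export
generate_genome <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "wrky_synth_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  # ---- gene roster ---------------------------------------------------------
  roster <- list()
  for (sg in names(config$subgroup_counts)) {
    k <- config$subgroup_counts[[sg]]
    if (k == 0) next
    grp <- if (sg %in% c("I", "III")) sg else "II"
    for (i in seq_len(k)) {
      variant <- if (grp == "II" && runif(1) < config$variant_rate) {
        sample(config$hepta_variants, 1)
      } else "canonical"
      roster[[length(roster) + 1L]] <- list(group = grp, subgroup = sg, variant = variant)
    }
  }
  n_base <- length(roster)
  n_dup <- config$n_tandem + config$n_segmental
  if (n_base < max(sum(config$cluster_sizes), n_dup) + 2) {
    wrky_abort("infeasible plan: not enough base genes for the cluster/duplication plan")
  }

  built <- map(roster, function(r) synth_build_gene(r$group, r$subgroup, r$variant, config))

  # ---- duplicates ----------------------------------------------------------
  dup_sources <- sample(n_base, n_dup)
  tandem_src <- dup_sources[seq_len(config$n_tandem)]
  seg_src <- setdiff(dup_sources, tandem_src)
  make_dup <- function(src_idx) {
    src <- built[[src_idx]]
    plen <- nchar(src$protein)
    constrained <- unlist(map(seq_len(nrow(src$domains)), function(j) {
      seq(src$domains$start[j], src$domains$end[j])
    }))
    allowed <- setdiff(seq_len(plen), constrained)
    n_mut <- round((1 - config$duplicate_identity / 100) * plen)
    dup <- src
    dup$protein <- mutate_protein(src$protein, n_mut, allowed)
    dup
  }
  dup_built <- map(dup_sources, make_dup)
  dup_roster <- map(dup_sources, function(i) roster[[i]])

  # ---- placement -----------------------------------------------------------
  # units: clusters (of base singletons), tandem pairs, remaining singletons;
  # segmental duplicates are reserved for the last chromosome
  cluster_pool <- setdiff(seq_len(n_base), dup_sources)
  unit_list <- list()
  ci <- 1L
  cluster_assign <- integer(0)
  for (k in seq_along(config$cluster_sizes)) {
    sz <- config$cluster_sizes[k]
    members <- cluster_pool[seq(ci, ci + sz - 1L)]
    ci <- ci + sz
    unit_list[[length(unit_list) + 1L]] <- list(
      type = "cluster", members = members, gap = config$intra_cluster_gap
    )
  }
  for (k in seq_along(tandem_src)) {
    unit_list[[length(unit_list) + 1L]] <- list(
      type = "tandem", members = c(tandem_src[k], n_base + which(dup_sources == tandem_src[k])),
      gap = config$tandem_gap
    )
  }
  singles <- setdiff(seq_len(n_base), c(unlist(map(unit_list, "members"))))
  for (s in singles) {
    unit_list[[length(unit_list) + 1L]] <- list(type = "single", members = s, gap = 0)
  }

  all_built <- c(built, dup_built)
  all_roster <- c(roster, dup_roster)
  n_total <- length(all_built)
  chr_of <- character(n_total); start_of <- numeric(n_total)
  strand_of <- rep_len(c("+", "-"), n_total)
  main_chr <- seq_len(config$n_chromosomes - 1L)
  cursor <- setNames(rep(100001, config$n_chromosomes), paste0("Chr", seq_len(config$n_chromosomes)))
  cluster_rows <- list()
  for (u in seq_along(unit_list)) {
    unit <- unit_list[[u]]
    chr <- paste0("Chr", main_chr[(u - 1L) %% length(main_chr) + 1L])
    pos <- cursor[chr]
    starts <- pos + (seq_along(unit$members) - 1L) * unit$gap
    chr_of[unit$members] <- chr
    start_of[unit$members] <- starts
    cursor[chr] <- max(starts) + config$inter_unit_gap
    if (unit$type %in% c("cluster", "tandem")) {
      cluster_rows[[length(cluster_rows) + 1L]] <- tibble(
        chromosome = chr, member_idx = list(unit$members)
      )
    }
  }
  seg_dup_idx <- n_base + which(dup_sources %in% seg_src)
  seg_chr <- paste0("Chr", config$n_chromosomes)
  for (k in seq_along(seg_dup_idx)) {
    chr_of[seg_dup_idx[k]] <- seg_chr
    start_of[seg_dup_idx[k]] <- cursor[seg_chr]
    cursor[seg_chr] <- cursor[seg_chr] + config$inter_unit_gap
  }
  if (any(cursor > config$chromosome_length)) {
    wrky_abort("infeasible plan: genes do not fit on the configured chromosomes")
  }

  # ---- materialise genes ---------------------------------------------------
  ids <- sprintf("swk%03d", seq_len(n_total))
  genes <- list(); gff <- list(); proteins <- list(); cds_tbl <- list()
  for (i in seq_len(n_total)) {
    b <- all_built[[i]]
    r <- all_roster[[i]]
    plen <- nchar(b$protein)
    cds <- paste0(reverse_translate(b$protein), "TAA")
    cds_len <- nchar(cds)
    intron_lengths <- sample(100:250, nrow(b$introns), replace = TRUE)
    segs <- synth_segments(cds_len, b$introns$junction, intron_lengths,
                           as.integer(start_of[i]), strand_of[i])
    genes[[i]] <- tibble(
      gene_id = ids[i], chromosome = chr_of[i], strand = strand_of[i],
      start = min(segs$start), end = max(segs$end),
      group = r$group, subgroup = r$subgroup, variant = r$variant,
      length_aa = plen, n_domains = nrow(b$domains),
      domain_start = b$domains$start[1], domain_end = b$domains$end[1],
      domains = list(b$domains),
      n_introns = nrow(b$introns),
      intron_positions = list(b$introns$protein_position),
      intron_phases = list(b$introns$phase),
      intron_types = list(b$introns$splice_type)
    )
    proteins[[i]] <- tibble(id = ids[i], sequence = b$protein)
    cds_tbl[[i]] <- tibble(id = ids[i], sequence = cds)
    gff[[i]] <- tibble(
      gene_id = ids[i], chromosome = chr_of[i], strand = strand_of[i],
      segs = list(segs)
    )
  }
  genes <- bind_rows(genes)
  proteins <- bind_rows(proteins)
  cds_tbl <- bind_rows(cds_tbl)

  clusters <- if (length(cluster_rows) == 0) {
    tibble(cluster_id = character(), chromosome = character(), members = list())
  } else {
    bind_rows(imap(cluster_rows, function(row, k) {
      tibble(
        cluster_id = paste0("planted", k), chromosome = row$chromosome,
        members = list(ids[row$member_idx[[1]]])
      )
    }))
  }
  duplications <- tibble(
    gene_a = ids[dup_sources],
    gene_b = ids[n_base + seq_len(n_dup)],
    dup_class = ifelse(dup_sources %in% tandem_src, "tandem", "segmental"),
    target_identity = config$duplicate_identity
  )

  # ---- expression counts ---------------------------------------------------
  mu_gene <- exp(rnorm(n_total, config$expr_meanlog, config$expr_sdlog))
  counts <- matrix(0L, n_total, length(config$tissues),
                   dimnames = list(ids, config$tissues))
  for (t in seq_along(config$tissues)) {
    eff <- exp(rnorm(n_total, 0, 0.5))
    counts[, t] <- rnbinom(n_total, mu = mu_gene * eff, size = config$expr_dispersion)
  }
  counts_tbl <- as_tibble(counts, rownames = "gene_id")

  manifest <- list(genes = genes, clusters = clusters, duplications = duplications)

  # ---- generation-time consistency checks ----------------------------------
  translated <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(setNames(cds_tbl$sequence, cds_tbl$id))
  ))
  translated <- sub("\\*$", "", translated)
  if (!identical(unname(translated), proteins$sequence)) {
    wrky_abort("internal generator error: CDS does not translate to protein")
  }
  for (i in seq_len(n_total)) {
    sc <- scan_protein(proteins$sequence[i], ids[i])
    want <- genes$domains[[i]]
    if (nrow(sc) != nrow(want) || !all(sc$hepta_start == want$start) ||
        !all(sc$c1 == want$c1, na.rm = TRUE)) {
      wrky_abort(paste0("internal generator error: domain scan mismatch for ", ids[i]))
    }
  }

  genome <- structure(
    list(
      proteins = proteins, cds = cds_tbl,
      gene_models = mutate(
        select(genes, "gene_id", "chromosome", "strand", "start", "end"),
        cds = map(gff, function(g) g$segs[[1]]),
        exon_count = map_int(.data$cds, nrow),
        introns = .data$exon_count - 1L
      ),
      counts = counts_tbl,
      gene_lengths = tibble(gene_id = ids, length_bp = nchar(cds_tbl$sequence)),
      manifest = manifest,
      config = config
    ),
    class = "wrky_synth_genome"
  )
  if (!is.null(dir)) write_synth_genome(genome, dir)
  genome
}

#' @export
print.wrky_synth_genome <- function(x, ...) {
  cat("<wrky_synth_genome> ", nrow(x$proteins), " genes on ",
      length(unique(x$gene_models$chromosome)), " chromosomes\n", sep = "")
  invisible(x)
}

# write genome files (FASTA/GFF3/TSV + flattened manifest)
write_synth_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(genome$proteins, file.path(dir, "proteins.fa"))
  write_fasta(genome$cds, file.path(dir, "cds.fa"))
  write_gff3(genome$gene_models, file.path(dir, "genes.gff3"))
  readr::write_tsv(genome$counts, file.path(dir, "counts.tsv"))
  flat <- genome$manifest$genes |>
    select(-"domains") |>
    mutate(across(
      c("intron_positions", "intron_phases", "intron_types"),
      function(col) map_chr(col, paste, collapse = ";")
    ))
  readr::write_tsv(flat, file.path(dir, "manifest_genes.tsv"))
  readr::write_tsv(
    mutate(genome$manifest$clusters,
           members = map_chr(.data$members, paste, collapse = ";")),
    file.path(dir, "manifest_clusters.tsv")
  )
  readr::write_tsv(genome$manifest$duplications, file.path(dir, "manifest_duplications.tsv"))
  invisible(dir)
}

#' Write gene models to GFF3
#'
#' @param gene_models Tibble with `gene_id`, `chromosome`, `strand` and the
#'   `cds` list-column (transcription-order segments).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gene_models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    segs <- arrange(g$cds[[1]], .data$start)
    tx_segs <- g$cds[[1]] # transcription order for phase computation
    seg_len <- tx_segs$end - tx_segs$start + 1L
    phase <- (3L - cumsum(c(0L, head(seg_len, -1L))) %% 3L) %% 3L
    phase_by_start <- phase[match(segs$start, tx_segs$start)]
    gstart <- min(segs$start); gend <- max(segs$end)
    mk <- function(type, s, e, ph, attrs) {
      paste(g$chromosome, "wrkyscan", type, s, e, ".", g$strand, ph, attrs, sep = "\t")
    }
    lines <- c(
      lines,
      mk("gene", gstart, gend, ".", paste0("ID=", g$gene_id)),
      mk("mRNA", gstart, gend, ".", paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id)),
      vapply(seq_len(nrow(segs)), function(k) {
        mk("CDS", segs$start[k], segs$end[k], phase_by_start[k],
           paste0("ID=", g$gene_id, ".cds;Parent=", g$gene_id, ".t1"))
      }, character(1))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Labelled WRKY domain reference panel
#'
#' Returns the fixed subgroup templates (IIa-IIe, group I N- and C-terminal
#' domains, group III) as a labelled panel for reference-guided subgroup
#' assignment, standing in for a curated set of labelled domains from a
#' reference species.  Errors when any two group II templates diverge less
#' than `min_divergence` (an unlearnable panel).
#'
#' @param config A [synth_config()] (only `min_template_divergence` is used,
#'   override with `min_divergence`).
#' @param min_divergence Minimum pairwise divergence between group II
#'   templates.
#' @return Tibble: `label`, `sequence`.
#' @export
generate_reference_panel <- function(config = synth_config(),
                                     min_divergence = config$min_template_divergence) {
  labels <- names(SYNTH_FILLERS)
  panel <- tibble(
    label = c("I-N", "I-C", paste0("II", letters[1:5]), "III"),
    sequence = map_chr(c("I-N", "I-C", paste0("II", letters[1:5]), "III"), synth_template)
  )
  ii <- filter(panel, stringr::str_detect(.data$label, "^II[a-e]$"))
  for (i in seq_len(nrow(ii) - 1)) {
    for (j in seq((i + 1), nrow(ii))) {
      a <- strsplit(ii$sequence[i], "")[[1]]
      b <- strsplit(ii$sequence[j], "")[[1]]
      div <- mean(a != b)
      if (div < min_divergence) {
        wrky_abort(paste0(
          "unlearnable reference panel: templates ", ii$label[i], " and ",
          ii$label[j], " diverge only ", round(100 * div, 1), "%"
        ))
      }
    }
  }
  panel
}

#' Simulate a codon-sequence pair evolving under purifying selection
#'
#' Draws a random sense-codon sequence and evolves a copy by proposing
#' `n_events` single-nucleotide mutations: synonymous changes are always
#' accepted, nonsynonymous changes are accepted with probability
#' `nonsyn_keep` (the purifying regime; 0.1 means the nonsynonymous
#' substitution rate is one tenth of the synonymous rate), and mutations to
#' stop codons are rejected.  Use with [kaks_nei_gojobori()] to check that
#' the Ka/Ks screen flags purifying selection.
#'
#' @param n_codons Sequence length in codons.
#' @param n_events Number of proposed mutation events.
#' @param nonsyn_keep Acceptance probability for nonsynonymous proposals.
#' @return List with CDS strings `a` and `b`.
#' @export
simulate_purifying_pair <- function(n_codons = 150, n_events = 60,
                                    nonsyn_keep = 0.1) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  c1 <- sample(sense, n_codons, replace = TRUE)
  c2 <- c1
  bases <- c("A", "C", "G", "T")
  for (e in seq_len(n_events)) {
    i <- sample(n_codons, 1)
    pos <- sample(3, 1)
    b <- sample(setdiff(bases, substring(c2[i], pos, pos)), 1)
    mut <- c2[i]
    substring(mut, pos, pos) <- b
    if (code[[mut]] == "*") next
    if (code[[mut]] == code[[c2[i]]] || runif(1) < nonsyn_keep) c2[i] <- mut
  }
  list(a = paste(c1, collapse = ""), b = paste(c2, collapse = ""))
}

#' Derive an orthologous proteome from a synthetic genome
#'
#' Copies every protein, substitutes residues outside the planted domains at
#' `mutation_rate`, and prefixes ids with `ortho_`.  The true ortholog map
#' is the identity pairing.
#'
#' @param genome A [generate_genome()] result.
#' @param mutation_rate Per-position substitution rate outside domains.
#' @param seed RNG seed.
#' @return List: `proteins` (tibble), `ortholog_map` (tibble `gene_a`,
#'   `gene_b`).
#' @export
generate_ortholog_proteome <- function(genome,
                                       mutation_rate = genome$config$ortholog_mutation_rate,
                                       seed = genome$config$seed + 1000L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  man <- genome$manifest$genes
  mutated <- map_chr(seq_len(nrow(genome$proteins)), function(i) {
    p <- genome$proteins$sequence[i]
    doms <- man$domains[[match(genome$proteins$id[i], man$gene_id)]]
    constrained <- unlist(map(seq_len(nrow(doms)), function(j) seq(doms$start[j], doms$end[j])))
    allowed <- setdiff(seq_len(nchar(p)), constrained)
    mutate_protein(p, rbinom(1, length(allowed), mutation_rate), allowed)
  })
  proteins <- tibble(
    id = paste0("ortho_", genome$proteins$id),
    sequence = mutated
  )
  list(
    proteins = proteins,
    ortholog_map = tibble(gene_a = genome$proteins$id, gene_b = proteins$id)
  )
}
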