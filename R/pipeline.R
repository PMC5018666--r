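#' Run the full WRKY family characterization pipeline
#'
#' Executes the stages in order — domain scan, group/subgroup
#' classification, physicochemical and intron features, chromosomal
#' ordering + ordinal renaming + cluster calling, duplication screening,
#' group III all-pairs Ka/Ks, the domain phylogeny, accessory motifs and
#' (optionally) RPKM expression — and collects every stage's table in one
#' result object.  Proteins without any WRKY domain are dropped from the
#' family (they are reported in `$non_family`).
#'
#' @param proteins Tibble `id`, `sequence` (e.g. from [read_fasta()]).
#' @param cds Optional CDS tibble `id`, `sequence` (enables Ka/Ks).
#' @param gene_models Optional gene-model tibble (from [read_gff3()];
#'   enables renaming, clusters, duplication classes, intron annotation).
#' @param counts,gene_lengths Optional expression inputs (see
#'   [expression_matrix()]).
#' @param references Optional reference domain panel for subgroup placement.
#' @param prefix Ordinal naming prefix (e.g. `"SsWRKY"`).
#' @param scan_cfg A [scan_config()].
#' @param method Subgroup placement method, `"tree"` or `"nearest"`.
#' @param cluster_window_bp Gene-cluster window (default 200 kb).
#' @param min_coverage,min_identity Duplicate screening thresholds (%).
#' @param kaks_threshold Ka/Ks purifying-selection cutoff.
#' @param bootstrap_reps Bootstrap replicates for the domain tree (0 = no
#'   supports).
#' @param seed Seed used for the bootstrap stage.
#' @return Object of class `wrky_family`; see [tidy.wrky_family()] and
#'   [glance.wrky_family()].
#' @export
run_pipeline <- function(proteins, cds = NULL, gene_models = NULL,
                         counts = NULL, gene_lengths = NULL,
                         references = NULL, prefix = "WRKY",
                         scan_cfg = scan_config(),
                         method = c("tree", "nearest"),
                         cluster_window_bp = 200000,
                         min_coverage = 80, min_identity = 65,
                         kaks_threshold = 0.5,
                         bootstrap_reps = 0, seed = 1L) {
  method <- match.arg(method)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      wrky_abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  domains <- stage("scan", scan_proteins(proteins, scan_cfg))
  family_ids <- unique(domains$protein_id)
  non_family <- setdiff(proteins$id, family_ids)
  proteins <- filter(proteins, .data$id %in% family_ids)

  classes <- stage("classify", classify_proteins(domains, proteins, references, method))
  props <- stage("features", protein_properties(proteins))

  genes <- proteins |>
    select("id") |>
    left_join(rename(classes, id = "protein_id"), by = "id") |>
    left_join(props, by = "id")

  clusters <- NULL; introns <- NULL
  if (!is.null(gene_models)) {
    gm <- filter(gene_models, .data$gene_id %in% family_ids)
    named <- stage("genome_org", rename_by_position(gm, prefix))
    clusters <- stage("genome_org", find_clusters(gm, cluster_window_bp))
    introns <- stage("features", annotate_introns_all(gm, proteins, domains))
    genes <- genes |>
      left_join(
        select(named, "gene_id", "chromosome", "start", "end", "strand", "family_name"),
        by = c(id = "gene_id")
      ) |>
      left_join(
        introns |>
          group_by(.data$gene_id) |>
          summarise(introns = n(), .groups = "drop"),
        by = c(id = "gene_id")
      ) |>
      mutate(introns = ifelse(is.na(.data$introns), 0L, .data$introns)) |>
      arrange(as.integer(stringr::str_remove(.data$family_name, stringr::fixed(prefix))))
  }

  duplications <- NULL
  if (!is.null(gene_models)) {
    duplications <- stage("evolution", find_duplications(
      proteins, gene_models, min_coverage, min_identity
    ))
  } else {
    duplications <- stage("evolution", mutate(
      find_homolog_pairs(proteins, min_coverage, min_identity),
      dup_class = NA_character_
    ))
  }

  kaks <- NULL
  if (!is.null(cds)) {
    iii <- genes$id[genes$group == "III"]
    kaks <- stage("evolution", kaks_all_pairs(
      filter(cds, .data$id %in% iii), kaks_threshold
    ))
  }

  tree <- NULL
  if (nrow(proteins) >= 3) {
    dom_seqs <- domains |>
      filter(.data$complete) |>
      mutate(seq = stringr::str_sub(
        proteins$sequence[match(.data$protein_id, proteins$id)],
        .data$domain_start, .data$domain_end
      ))
    labels <- make.unique(dom_seqs$protein_id, sep = "_dom")
    if (nrow(dom_seqs) >= 3) {
      tree <- stage("phylo", {
        msa <- progressive_msa(dom_seqs$seq, labels = labels)
        if (bootstrap_reps > 0) {
          bootstrap_support(msa, n_reps = bootstrap_reps, seed = seed)
        } else {
          neighbor_joining(p_distance(msa))
        }
      })
    }
  }

  motifs <- stage("scan", search_motifs(proteins, scan_cfg$leucine_zipper_min))

  expression <- NULL
  if (!is.null(counts)) {
    if (is.null(gene_lengths)) wrky_abort("counts supplied without gene_lengths")
    expression <- stage("expression", {
      em <- expression_matrix(
        filter(counts, .data$gene_id %in% family_ids), gene_lengths
      )
      list(matrix = em, tissue_clustering = cluster_tissues(em))
    })
  }

  structure(
    list(
      genes = genes, domains = domains, motifs = motifs,
      clusters = clusters, introns = introns,
      duplications = duplications, kaks = kaks, tree = tree,
      expression = expression, non_family = non_family,
      log = list(
        package_version = as.character(utils::packageVersion("wrkyscan")),
        seed = seed, method = method,
        thresholds = list(
          cluster_window_bp = cluster_window_bp, min_coverage = min_coverage,
          min_identity = min_identity, kaks_threshold = kaks_threshold,
          finger_window = scan_cfg$finger_window
        )
      )
    ),
    class = "wrky_family"
  )
}

#' @export
print.wrky_family <- function(x, ...) {
  cat("<wrky_family> ", nrow(x$genes), " genes", sep = "")
  tab <- table(x$genes$group)
  cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Tidy a pipeline result into the per-gene table
#'
#' @param x A `wrky_family` object.
#' @param ... Unused.
#' @return The per-gene characterization tibble.
#' @export
tidy.wrky_family <- function(x, ...) x$genes

#' One-row summary of a pipeline result
#'
#' @param x A `wrky_family` object.
#' @param ... Unused.
#' @return One-row tibble of family-level aggregates.
#' @export
glance.wrky_family <- function(x, ...) {
  s <- summarize_family(x$genes)
  extra <- tibble(
    n_clusters = if (is.null(x$clusters)) NA_integer_ else nrow(x$clusters),
    n_clustered_genes = if (is.null(x$clusters)) NA_integer_ else {
      sum(map_int(x$clusters$members, length))
    },
    n_homolog_pairs = if (is.null(x$duplications)) NA_integer_ else nrow(x$duplications),
    n_tandem = if (is.null(x$duplications)) NA_integer_ else {
      sum(x$duplications$dup_class == "tandem", na.rm = TRUE)
    },
    n_segmental = if (is.null(x$duplications)) NA_integer_ else {
      sum(x$duplications$dup_class == "segmental", na.rm = TRUE)
    }
  )
  dplyr::bind_cols(glance(s), extra)
}

#' Chromosome map of family genes
#'
#' @param object A `wrky_family` object with genomic coordinates.
#' @param ... Unused.
#' @return A ggplot object: gene positions along chromosomes, coloured by
#'   group.
#' @export
autoplot.wrky_family <- function(object, ...) {
  dat <- filter(object$genes, !is.na(.data$chromosome))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$chromosome, y = .data$start / 1e6, colour = .data$group
  )) +
    ggplot2::geom_point(shape = 95, size = 6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "position (Mb)", colour = "group") +
    ggplot2::theme_minimal()
}

#' Aggregate a family characterization table
#'
#' Computes the family-level aggregates from a per-gene table (either the
#' packaged willow table from [load_family_table()] or a pipeline result):
#' group and subgroup counts, intron histogram, protein length mean
#' (rounded half-to-even to an integer) and range, isoelectric-point and
#' molecular-weight ranges, per-chromosome counts, counts of genes with at
#' least one ortholog in each reference species (when ortholog columns are
#' present), and the all-pairs count k(k-1)/2 for group III.
#'
#' @param rows Tibble with columns `group`, `length_aa`, `pi`, `mw_kda`,
#'   `introns`, `chromosome` and optionally `at_orthologs`/`pt_orthologs`
#'   list-columns.
#' @return Object of class `wrky_family_summary`.
#' @export
#' @examples
#' summarize_family(load_family_table())
summarize_family <- function(rows) {
  main_group <- ifelse(rows$group %in% c("I", "III"), rows$group,
                       ifelse(startsWith(rows$group, "II"), "II", rows$group))
  group_counts <- table(factor(main_group, levels = c("I", "II", "III")))
  subgroup_counts <- table(factor(
    rows$group[startsWith(rows$group, "II") & rows$group != "III"],
    levels = paste0("II", letters[1:5])
  ))
  k3 <- sum(main_group == "III")
  has_orth <- function(col) {
    if (!col %in% names(rows)) return(NA_integer_)
    sum(map_int(rows[[col]], length) > 0)
  }
  structure(
    list(
      n_genes = nrow(rows),
      group_counts = c(group_counts),
      subgroup_counts = c(subgroup_counts),
      intron_histogram = if ("introns" %in% names(rows)) table(rows$introns) else NULL,
      mean_length_aa = round(mean(rows$length_aa)),
      min_length_aa = min(rows$length_aa),
      max_length_aa = max(rows$length_aa),
      min_pi = min(rows$pi),
      max_pi = max(rows$pi),
      min_mw_kda = min(rows$mw_kda),
      max_mw_kda = max(rows$mw_kda),
      chromosome_counts = if ("chromosome" %in% names(rows)) {
        table(rows$chromosome, useNA = "ifany")
      } else NULL,
      n_at_ortholog_genes = has_orth("at_orthologs"),
      n_pt_ortholog_genes = has_orth("pt_orthologs"),
      group_iii_pairs = k3 * (k3 - 1) / 2
    ),
    class = "wrky_family_summary"
  )
}

#' @export
print.wrky_family_summary <- function(x, ...) {
  cat("<wrky_family_summary>\n")
  cat("  genes:           ", x$n_genes, "\n")
  cat("  groups:          ", paste(names(x$group_counts), x$group_counts,
                                   sep = "=", collapse = ", "), "\n")
  cat("  subgroups (II):  ", paste(names(x$subgroup_counts), x$subgroup_counts,
                                   sep = "=", collapse = ", "), "\n")
  cat("  length (aa):      mean ", x$mean_length_aa, ", range ",
      x$min_length_aa, "-", x$max_length_aa, "\n", sep = "")
  cat("  pI:               ", x$min_pi, "-", x$max_pi, "\n", sep = "")
  cat("  MW (kDa):         ", x$min_mw_kda, "-", x$max_mw_kda, "\n", sep = "")
  cat("  group III pairs: ", x$group_iii_pairs, "\n")
  invisible(x)
}

#' @export
glance.wrky_family_summary <- function(x, ...) {
  tibble(
    n_genes = x$n_genes,
    n_group_i = unname(x$group_counts["I"]),
    n_group_ii = unname(x$group_counts["II"]),
    n_group_iii = unname(x$group_counts["III"]),
    n_iia = unname(x$subgroup_counts["IIa"]),
    n_iib = unname(x$subgroup_counts["IIb"]),
    n_iic = unname(x$subgroup_counts["IIc"]),
    n_iid = unname(x$subgroup_counts["IId"]),
    n_iie = unname(x$subgroup_counts["IIe"]),
    mean_length_aa = x$mean_length_aa,
    min_length_aa = x$min_length_aa,
    max_length_aa = x$max_length_aa,
    min_pi = x$min_pi, max_pi = x$max_pi,
    min_mw_kda = x$min_mw_kda, max_mw_kda = x$max_mw_kda,
    n_at_ortholog_genes = x$n_at_ortholog_genes,
    n_pt_ortholog_genes = x$n_pt_ortholog_genes,
    group_iii_pairs = x$group_iii_pairs
  )
}

#' Tidy a family summary into a long name/value table
#'
#' @param x A `wrky_family_summary`.
#' @param ... Unused.
#' @return Tibble `statistic`, `value`.
#' @export
tidy.wrky_family_summary <- function(x, ...) {
  g <- glance(x)
  tibble(statistic = names(g), value = as.numeric(g[1, ]))
}
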