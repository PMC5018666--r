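# natural numeric ordering key for chromosome names ("Chr2" < "Chr10");
# unplaced (NA) chromosomes sort last
chromosome_rank <- function(chromosome) {
  num <- suppressWarnings(as.numeric(stringr::str_extract(chromosome, "[0-9]+(\\.[0-9]+)?")))
  ifelse(is.na(chromosome), Inf, ifelse(is.na(num), Inf - 1, num))
}

#' Rename family genes by chromosomal position
#'
#' Orders genes by (natural chromosome number, start coordinate) and assigns
#' ordinal names `prefix1..prefixN`.  Genes not placed on any chromosome
#' (`chromosome` is `NA`) receive the final ordinals, as is conventional for
#' unmapped family members.
#'
#' @param genes Gene-model tibble with `gene_id`, `chromosome`, `start`.
#' @param prefix Name prefix, e.g. `"SsWRKY"`.
#' @return The input tibble with a `family_name` column, in naming order.
#' @export
rename_by_position <- function(genes, prefix) {
  if (nrow(genes) == 0) return(mutate(genes, family_name = character(0)))
  if (anyDuplicated(genes$gene_id)) {
    wrky_abort(paste0(
      "duplicate gene_id: ",
      genes$gene_id[duplicated(genes$gene_id)][1]
    ))
  }
  genes |>
    arrange(chromosome_rank(.data$chromosome), .data$start) |>
    mutate(family_name = paste0(prefix, row_number()))
}

#' Call gene clusters with the 200-kb rule
#'
#' Chains family genes along each chromosome: consecutive genes whose
#' start-to-start distance is at most `window_bp` join one cluster, and
#' maximal chains of two or more genes are reported.  Chaining is
#' transitive, so a dense region can form one long cluster even when its
#' extreme members are more than `window_bp` apart.
#'
#' @param genes Gene-model tibble with `gene_id`, `chromosome`, `start`,
#'   `end`.  Unplaced genes (`NA` chromosome) are ignored.
#' @param window_bp Maximum start-to-start gap between consecutive cluster
#'   members (default 200,000 bp).
#' @return Tibble: `cluster_id`, `chromosome`, `n_genes`, `span_bp`,
#'   `members` (list of gene ids sorted by start).
#' @export
find_clusters <- function(genes, window_bp = 200000) {
  placed <- filter(genes, !is.na(.data$chromosome))
  out <- placed |>
    arrange(chromosome_rank(.data$chromosome), .data$start) |>
    group_by(.data$chromosome) |>
    mutate(chain = cumsum(c(0, diff(.data$start)) > window_bp)) |>
    group_by(.data$chromosome, .data$chain) |>
    summarise(
      n_genes = n(),
      span_bp = max(.data$end) - min(.data$start) + 1L,
      members = list(.data$gene_id),
      .groups = "drop"
    ) |>
    filter(.data$n_genes >= 2) |>
    mutate(cluster_id = paste0("cluster", row_number())) |>
    select("cluster_id", "chromosome", "n_genes", "span_bp", "members")
  out
}
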