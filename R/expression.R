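#' Reads per kilobase per million mapped reads
#'
#' @param count Mapped read count (vectorised).
#' @param gene_length_bp Transcript length in bp (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return `count / ((gene_length_bp / 1000) * (total_mapped_reads / 1e6))`.
#' @export
#' @examples
#' rpkm(500, 2000, 1e7) # 25
rpkm <- function(count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0)) wrky_abort("gene_length_bp must be > 0")
  if (any(total_mapped_reads <= 0)) wrky_abort("total_mapped_reads must be > 0")
  count / ((gene_length_bp / 1000) * (total_mapped_reads / 1e6))
}

#' Build an expression matrix (counts, RPKM, log2 RPKM)
#'
#' @param counts Tibble: `gene_id` column plus one integer column per
#'   tissue.
#' @param gene_lengths Tibble: `gene_id`, `length_bp`.
#' @param total_mapped_reads Optional named vector of per-tissue library
#'   sizes; the default uses each tissue's column sum of the supplied count
#'   table (the genome-wide totals are usually unavailable at the family
#'   scale).
#' @return Object of class `wrky_expression`: list with `gene_ids`,
#'   `tissues`, `counts`, `rpkm` and `log2rpkm` matrices.  `log2rpkm` is
#'   `NA` exactly where the count is zero (a gene not expressed in that
#'   tissue).
#' @export
expression_matrix <- function(counts, gene_lengths, total_mapped_reads = NULL) {
  tissues <- setdiff(names(counts), "gene_id")
  cm <- as.matrix(counts[, tissues])
  rownames(cm) <- counts$gene_id
  if (any(cm < 0)) wrky_abort("counts must be nonnegative")
  len <- gene_lengths$length_bp[match(counts$gene_id, gene_lengths$gene_id)]
  if (anyNA(len)) wrky_abort("missing gene length for some genes in the count table")
  if (is.null(total_mapped_reads)) total_mapped_reads <- colSums(cm)
  total_mapped_reads <- total_mapped_reads[tissues]
  rk <- sweep(cm / (len / 1000), 2, total_mapped_reads / 1e6, "/")
  lg <- ifelse(cm > 0, log2(rk), NA_real_)
  structure(
    list(
      gene_ids = counts$gene_id, tissues = tissues,
      counts = cm, rpkm = rk, log2rpkm = lg,
      total_mapped_reads = total_mapped_reads
    ),
    class = "wrky_expression"
  )
}

#' @export
print.wrky_expression <- function(x, ...) {
  cat(
    "<wrky_expression> ", length(x$gene_ids), " genes x ",
    length(x$tissues), " tissues (", paste(x$tissues, collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Heat-map matrix (log2 RPKM, NA for unexpressed)
#'
#' @param em A [expression_matrix()] object.
#' @return Numeric matrix of `log2(rpkm)` with `NA` where the count is zero
#'   (rendered white/blank in heat maps).
#' @export
heatmap_matrix <- function(em) {
  stopifnot(inherits(em, "wrky_expression"))
  em$log2rpkm
}

#' Cluster tissues by expression profile
#'
#' Hierarchical agglomeration (average linkage) on Euclidean distances
#' between tissue columns of the log2 RPKM matrix, with `NA` (unexpressed)
#' set to 0 for the distance computation only.  Tie handling follows
#' [stats::hclust()]'s deterministic ordering of the input columns.
#'
#' @param em A [expression_matrix()] object (>= 2 tissues).
#' @return List: `hclust` (the tree), `newick` (the dendrogram as a Newick
#'   string over tissue names).
#' @export
cluster_tissues <- function(em) {
  stopifnot(inherits(em, "wrky_expression"))
  if (length(em$tissues) < 2) wrky_abort("need at least 2 tissues to cluster")
  lg <- em$log2rpkm
  lg[is.na(lg)] <- 0
  hc <- hclust(dist(t(lg), method = "euclidean"), method = "average")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Tidy an expression matrix
#'
#' @param x A `wrky_expression` object.
#' @param ... Unused.
#' @return Long tibble: `gene_id`, `tissue`, `count`, `rpkm`, `log2rpkm`.
#' @export
tidy.wrky_expression <- function(x, ...) {
  long <- function(m, name) {
    as_tibble(m, rownames = "gene_id") |>
      tidyr::pivot_longer(-"gene_id", names_to = "tissue", values_to = name)
  }
  long(x$counts, "count") |>
    left_join(long(x$rpkm, "rpkm"), by = c("gene_id", "tissue")) |>
    left_join(long(x$log2rpkm, "log2rpkm"), by = c("gene_id", "tissue"))
}

#' Expression heat map
#'
#' log2 RPKM per gene and tissue; unexpressed cells (count 0) are blank.
#'
#' @param object A `wrky_expression` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wrky_expression <- function(object, ...) {
  dat <- tidy.wrky_expression(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$tissue, y = .data$gene_id, fill = .data$log2rpkm
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", midpoint = 0,
      na.value = "white", name = "log2 RPKM"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
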