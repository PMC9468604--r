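#' Pearson correlation with two-sided p-value
#'
#' The correlation of a least-squares linear regression: the Pearson
#' product-moment coefficient, with a two-sided p-value from the t statistic
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Vectors
#' with zero variance yield an explicit undefined result (`r = NA`), never a
#' silent zero.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite values.
#' @return one-row tibble: `r`, `p`, `n`.
#' @export
pairwise_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("correlation needs at least 3 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Lineage-stratified co-expression correlations
#'
#' For each requested gene pair and each lineage, the expression values of
#' the two genes across that lineage's samples are correlated with
#' [pairwise_correlation()]. No multiple-testing correction is applied by
#' default (each pair/lineage is judged at `alpha` on its own); set
#' `adjust = "BH"` for a Benjamini-Hochberg adjusted flag.
#'
#' @param exprs numeric matrix or data frame, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param samples tibble with columns `sample` (matching `colnames(exprs)`)
#'   and `lineage`; every lineage needs at least 3 samples.
#' @param pairs tibble with columns `gene_a`, `gene_b`; unknown genes are an
#'   error naming the gene.
#' @param alpha significance level for the flag, default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param log_transform correlate `log2(x + 1)` instead of raw values.
#' @return tibble: `gene_a`, `gene_b`, `lineage`, `r`, `p`, `n`,
#'   `significant`.
#' @export
lineage_correlations <- function(exprs, samples, pairs, alpha = 0.05,
                                 adjust = c("none", "BH"), log_transform = FALSE) {
  adjust <- match.arg(adjust)
  exprs <- as.matrix(exprs)
  samples <- as_tibble(samples)
  if (anyNA(samples$lineage)) abort("samples carry missing lineage labels")
  if (!all(samples$sample %in% colnames(exprs))) {
    abort("sample annotation names samples absent from the expression matrix")
  }
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  unknown <- setdiff(genes, rownames(exprs))
  if (length(unknown) > 0) {
    abort(sprintf("unknown gene: %s", unknown[1]))
  }
  counts <- table(samples$lineage)
  if (any(counts < 3)) {
    abort(sprintf(
      "lineage '%s' has fewer than 3 samples", names(counts)[which(counts < 3)[1]]
    ))
  }
  if (log_transform) exprs <- log2(exprs + 1)
  lineages <- unique(samples$lineage)
  grid <- tidyr::expand_grid(pairs, lineage = lineages)
  out <- purrr::pmap(grid, function(gene_a, gene_b, lineage, ...) {
    cols <- samples$sample[samples$lineage == lineage]
    pairwise_correlation(exprs[gene_a, cols], exprs[gene_b, cols]) %>%
      mutate(gene_a = gene_a, gene_b = gene_b, lineage = lineage)
  }) %>%
    bind_rows() %>%
    select("gene_a", "gene_b", "lineage", "r", "p", "n")
  p_used <- if (adjust == "BH") stats::p.adjust(out$p, method = "BH") else out$p
  out$significant <- !is.na(p_used) & p_used <= alpha
  out
}

#' Cluster a co-expression correlation matrix
#'
#' Average-linkage hierarchical clustering on the distance `1 - r`, giving
#' the gene ordering used to display correlation heatmaps with co-expressed
#' blocks contiguous. Genes are sorted by name beforehand so the result is
#' deterministic under input permutation.
#'
#' @param r_matrix symmetric correlation matrix with unit diagonal and gene
#'   dimnames.
#' @return list of class `corr_clustering`: `hclust` (the merge tree) and
#'   `order` (gene labels in leaf order).
#' @export
cluster_correlation_matrix <- function(r_matrix) {
  m <- as.matrix(r_matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m)), na.rm = TRUE) > 1e-8) {
    abort("correlation matrix must be symmetric")
  }
  if (max(abs(diag(m) - 1)) > 1e-8) abort("correlation matrix must have unit diagonal")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("g", seq_len(nrow(m)))
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- hclust(as.dist(1 - m), method = "average")
  structure(
    list(hclust = hc, order = hc$labels[hc$order]),
    class = "corr_clustering"
  )
}

#' @export
print.corr_clustering <- function(x, ...) {
  cat("<corr_clustering> leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' Correlation-matrix heatmap in clustered order
#'
#' @param r_matrix symmetric correlation matrix.
#' @param clustering optional [cluster_correlation_matrix()] result; computed
#'   when absent.
#' @return a ggplot object.
#' @export
plot_correlation_matrix <- function(r_matrix, clustering = NULL) {
  if (is.null(clustering)) clustering <- cluster_correlation_matrix(r_matrix)
  ord <- clustering$order
  df <- as_tibble(as.data.frame(as.table(as.matrix(r_matrix)[ord, ord])),
    .name_repair = "minimal"
  )
  names(df) <- c("gene_a", "gene_b", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_a, .data$gene_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white", high = "steelblue",
      limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
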