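# Unsupervised hierarchical clustering of samples on a gene set, emulating
# the defaults of the classic heatmap workflow: genes z-scored across
# samples, Euclidean sample-sample distance, complete linkage.

#' Hierarchically cluster samples on a gene set
#'
#' Rows (genes) are z-scored across samples; constant genes are dropped
#' with a warning. Samples are clustered by complete-linkage agglomeration
#' on Euclidean distances of the z-scored sub-matrix. `hclust` with a fixed
#' input ordering makes the result deterministic; equal-height merges keep
#' the smaller sample index on the left.
#'
#' @param expr Normalized expression matrix (genes x samples), e.g. counts
#'   divided by size factors, on the log2 scale.
#' @param gene_set A [threshold_gene_set()] or character vector of gene ids.
#' @param k Number of flat clusters to cut (default 2).
#' @return A list of class `sample_clustering`: `hclust` (the tree),
#'   `labels` (named integer cluster labels at `k`), `heights`
#'   (merge heights), `newick` (a Newick string of the dendrogram),
#'   `genes_used`.
#' @export
cluster_samples <- function(expr, gene_set, k = 2) {
  ids <- if (inherits(gene_set, "gene_set")) gene_set$ids else gene_set
  ids <- intersect(ids, rownames(expr))
  if (length(ids) < 2L) stop("need >= 2 gene-set genes present in the matrix")
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  sub <- expr[ids, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene(s) before z-scoring", sum(sds == 0)))
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < 2L) stop("fewer than 2 variable genes remain")
  }
  z <- t(scale(t(sub)))
  hc <- stats::hclust(stats::dist(t(z), method = "euclidean"), method = "complete")
  labels <- stats::cutree(hc, k = k)
  structure(list(
    hclust = hc, labels = labels, heights = hc$height,
    newick = hclust_newick(hc), genes_used = rownames(sub)
  ), class = "sample_clustering")
}

# Minimal Newick serialization of an hclust tree (heights as branch lengths).
hclust_newick <- function(hc) {
  n <- length(hc$labels)
  build <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%.6g", hc$labels[-node], parent_h)
    } else {
      h <- hc$height[node]
      left <- build(hc$merge[node, 1], h)
      right <- build(hc$merge[node, 2], h)
      sprintf("(%s,%s):%.6g", left, right, max(parent_h - h, 0))
    }
  }
  root <- nrow(hc$merge)
  paste0("(", build(hc$merge[root, 1], hc$height[root]), ",",
         build(hc$merge[root, 2], hc$height[root]), ");")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("sample clustering: %d samples on %d genes; cluster sizes: %s\n",
              length(x$labels), length(x$genes_used),
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}
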