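#' Hierarchical clustering of tissue/time conditions
#'
#' Agglomerative clustering of condition expression vectors (features = the
#' selected genes) under Euclidean distance. Missing values are imputed as 0
#' ("no change", the least-informative value on the log-ratio scale) before
#' distance computation. Items are ordered lexicographically by label before
#' clustering so distance ties resolve deterministically.
#'
#' @param x a [regen_expr()].
#' @param gene_subset genes to cluster on (default: all).
#' @param linkage one of "complete", "single", "average", "ward".
#' @return an [stats::hclust] tree with condition labels, or a single-leaf
#'   stub of class `regen_leaf` for one condition.
#' @export
cluster_conditions <- function(x, gene_subset = NULL,
                               linkage = c("complete", "single", "average", "ward")) {
  linkage <- match.arg(linkage)
  v <- x$values
  if (!is.null(gene_subset)) {
    if (length(gene_subset) == 0) stopf("'gene_subset' is empty")
    v <- v[gene_subset, , drop = FALSE]
  }
  .cluster_items(t(v), linkage)
}

#' Hierarchical clustering of genes
#'
#' Symmetric to [cluster_conditions()] with genes as the clustered items and
#' conditions as features.
#'
#' @param x a [regen_expr()].
#' @param condition_subset condition labels to use as features (default all).
#' @param linkage linkage method.
#' @export
cluster_genes <- function(x, condition_subset = NULL,
                          linkage = c("complete", "single", "average", "ward")) {
  linkage <- match.arg(linkage)
  v <- x$values
  if (!is.null(condition_subset)) v <- v[, condition_subset, drop = FALSE]
  .cluster_items(v, linkage)
}

.cluster_items <- function(m, linkage) {
  m[is.na(m)] <- 0
  if (nrow(m) < 1) stopf("nothing to cluster")
  if (nrow(m) == 1)
    return(structure(list(labels = rownames(m)), class = "regen_leaf"))
  m <- m[order(rownames(m)), , drop = FALSE]  # deterministic tie-breaking
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(stats::dist(m, method = "euclidean"), method = method)
}

#' Tissue self-sorting score of a condition dendrogram
#'
#' Cuts the tree into `k` clusters and quantifies how well conditions group
#' by tissue of origin: cluster purity (fraction of conditions whose cluster
#' is dominated by their own tissue) and the adjusted Rand index against the
#' tissue labels.
#'
#' @param dend an hclust tree from [cluster_conditions()].
#' @param labels tissue label per leaf, named by leaf label or in leaf-label
#'   order.
#' @param k number of clusters to cut into.
#' @return list: k, purity, ari, assignments.
#' @export
self_sorting_score <- function(dend, labels, k) {
  if (k < 1) stopf("'k' must be >= 1")
  if (inherits(dend, "regen_leaf"))
    return(list(k = 1L, purity = 1, ari = NA_real_,
                assignments = stats::setNames(1L, dend$labels)))
  if (k > length(dend$labels)) stopf("'k' exceeds leaf count")
  cut <- stats::cutree(dend, k = k)
  if (!is.null(names(labels))) labels <- labels[names(cut)]
  purity <- sum(vapply(split(labels, cut),
                       function(l) max(table(l)), 0)) / length(labels)
  ari <- mclust::adjustedRandIndex(cut, labels)
  list(k = as.integer(k), purity = purity, ari = ari, assignments = cut)
}

#' Export a clipped heatmap matrix with its color-scale contract
#'
#' Clips log10 fold changes to a symmetric fold bound (default 5-fold, i.e.
#' +/- log10 5) and records the piecewise-linear color mapping:
#' down-regulation ramps to green, 0 is black, up-regulation ramps to red.
#' Row/column orders typically come from [cluster_genes()] /
#' [cluster_conditions()] leaf orders.
#'
#' @param x a [regen_expr()].
#' @param gene_order,condition_order optional display orders.
#' @param fold_bound clipping bound as a fold change (> 1).
#' @return list of class `regen_heatmap`: `matrix` (clipped values), `scale`
#'   (bound and color ramp description).
#' @export
heatmap_export <- function(x, gene_order = NULL, condition_order = NULL,
                           fold_bound = 5) {
  if (fold_bound <= 1) stopf("'fold_bound' must exceed 1")
  b <- log10(fold_bound)
  m <- x$values
  if (!is.null(gene_order)) m <- m[gene_order, , drop = FALSE]
  if (!is.null(condition_order)) m <- m[, condition_order, drop = FALSE]
  m <- pmin(pmax(m, -b), b)
  structure(list(
    matrix = m,
    scale = list(bound_log10 = b, fold_bound = fold_bound,
                 low = "green", mid = "black", high = "red",
                 mapping = "piecewise-linear in clipped log10 fold change")
  ), class = "regen_heatmap")
}

#' @export
print.regen_heatmap <- function(x, ...) {
  cat(sprintf("regen_heatmap: %d x %d, clipped to +/- %.3f (%g-fold)\n",
              nrow(x$matrix), ncol(x$matrix),
              x$scale$bound_log10, x$scale$fold_bound))
  invisible(x)
}

#' @export
plot.regen_heatmap <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c(x$scale$low, x$scale$mid, x$scale$high))(255)
  b <- x$scale$bound_log10
  m <- x$matrix; m[is.na(m)] <- 0
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  zlim = c(-b, b), col = pal, xlab = "", ylab = "", axes = FALSE, ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Write a heatmap matrix and its color-scale descriptor
#'
#' @param hm a `regen_heatmap`.
#' @param path TSV path for the matrix; the scale goes to `<path>.scale.json`.
#' @export
write_heatmap <- function(hm, path) {
  df <- data.frame(gene_id = rownames(hm$matrix), hm$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(hm$scale, paste0(path, ".scale.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are height differences of the merge tree. Characters with
#' Newick syntax meaning in leaf labels (`: ; , ( )` and space) are replaced
#' by `_`, so the condition label `"FL:1"` exports as `"FL_1"`.
#'
#' @param dend an hclust tree.
#' @param path output file.
#' @export
write_newick <- function(dend, path) {
  clean <- function(l) gsub("[:;,() ]", "_", l)
  if (inherits(dend, "regen_leaf")) {
    writeLines(sprintf("(%s);", clean(dend$labels)), path)
    return(invisible(path))
  }
  phy <- ape::as.phylo(dend)
  phy$tip.label <- clean(phy$tip.label)
  ape::write.tree(phy, file = path)
  invisible(path)
}
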