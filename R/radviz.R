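#' Min-max spring-constant normalization
#'
#' Rescales each gene's expression values to spring constants k in [0, 1]
#' across the displayed conditions: k = (value - min) / (max - min). Genes
#' constant across the display (or a single-condition display) are mapped to
#' the neutral value 0.5. Missing values are imputed as 0 (no change) before
#' scaling.
#'
#' @param x a [regen_expr()].
#' @param gene_subset genes to normalize (default: all).
#' @return list: `k` (matrix of spring constants, genes x conditions) and
#'   `scaling` (per-gene min and max used).
#' @export
normalize_features <- function(x, gene_subset = NULL) {
  v <- x$values
  if (!is.null(gene_subset)) v <- v[gene_subset, , drop = FALSE]
  v[is.na(v)] <- 0
  lo <- apply(v, 1, min); hi <- apply(v, 1, max)
  rng <- hi - lo
  k <- (v - lo) / ifelse(rng > 0, rng, 1)
  flat <- rng == 0 | ncol(v) == 1
  if (ncol(v) == 1)
    warning("single condition: spring constants degenerate to 0.5", call. = FALSE)
  k[flat, ] <- 0.5
  list(k = k, scaling = data.frame(gene_id = rownames(v), min = lo, max = hi,
                                   row.names = NULL, stringsAsFactors = FALSE))
}

# Welch statistics of every gene for class-vs-rest, on the normalized scale.
# Returns |t|, two-sided Bonferroni p and the sector ratio per (gene, class).
.class_stats <- function(k, labels, classes) {
  n_genes <- nrow(k)
  row_var <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1)
  }
  class_means <- sapply(classes, function(cl)
    rowMeans(k[, labels == cl, drop = FALSE]))
  out <- list()
  for (cl in classes) {
    in_cl <- labels == cl
    n1 <- sum(in_cl); n0 <- sum(!in_cl)
    if (n1 < 2) stopf("class '%s' has fewer than 2 conditions", cl)
    m1 <- rowMeans(k[, in_cl, drop = FALSE])
    m0 <- rowMeans(k[, !in_cl, drop = FALSE])
    v1 <- row_var(k[, in_cl, drop = FALSE])
    v0 <- row_var(k[, !in_cl, drop = FALSE])
    se2 <- v1 / n1 + v0 / n0
    t_stat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / max(n1 - 1, 1) +
                          (v0 / n0)^2 / max(n0 - 1, 1)),
                 NA_real_)
    p <- ifelse(is.finite(df) & df > 0,
                2 * stats::pt(-abs(t_stat), df), 1)
    denom <- rowSums(class_means[, setdiff(classes, cl), drop = FALSE])
    ratio <- ifelse(denom > 0, class_means[, cl] / denom,
                    ifelse(class_means[, cl] > 0, Inf, 1))
    out[[cl]] <- data.frame(
      gene_id = rownames(k), class_id = cl, t_stat = t_stat,
      p_bonf = pmin(1, p * n_genes), ratio = ratio,
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Select class-discriminant anchor genes
#'
#' The feature-reduction step of the class-discriminant radial projection:
#' for each labelled class, every gene is scored by the unequal-variance
#' (Welch) t statistic of its min-max-normalized values in that class versus
#' all other conditions, with a Bonferroni-adjusted p-value (multiplied by
#' the gene count, capped at 1) reported for transparency. Genes are ranked
#' per class by |t| and the top `n_per_class` retained. A gene may anchor at
#' most one class: when selected by several, it stays with the class where
#' its |t| is largest and the next-ranked gene is promoted for the losers.
#' Each anchor's sector is `plus` when its normalized class mean exceeds the
#' sum of the other classes' means (ratio > 1), `minus` otherwise.
#' Zero-variance genes score t = 0 and are never selected.
#'
#' @param x a [regen_expr()].
#' @param labels class label per condition (in condition order, or named by
#'   condition label).
#' @param n_per_class anchors to retain per class (30 by default).
#' @return data.frame of anchors: gene_id, class_id, sector, rank, t_stat,
#'   p_bonf, ratio.
#' @export
select_discriminant_genes <- function(x, labels, n_per_class = 30) {
  labs <- colnames(x$values)
  if (!is.null(names(labels))) labels <- labels[labs]
  labels <- as.character(labels)
  if (length(labels) != ncol(x$values))
    stopf("need one class label per condition")
  classes <- unique(labels)
  nf <- normalize_features(x)
  stats_by_class <- .class_stats(nf$k, labels, classes)

  # per-class candidate order: |t| descending, gene order breaking ties
  eligible <- lapply(stats_by_class, function(df)
    df[order(-abs(df$t_stat), seq_len(nrow(df))), ])
  abs_t <- sapply(stats_by_class, function(df) abs(df$t_stat))
  rownames(abs_t) <- rownames(x$values)

  n_per <- min(n_per_class, nrow(x$values))
  repeat {
    sel <- lapply(eligible, function(df) utils::head(df, n_per))
    picked <- unlist(lapply(sel, `[[`, "gene_id"))
    dup <- unique(picked[duplicated(picked)])
    if (length(dup) == 0) break
    for (g in dup) {
      holders <- classes[vapply(sel, function(df) g %in% df$gene_id, TRUE)]
      winner <- holders[which.max(abs_t[g, holders])]
      for (cl in setdiff(holders, winner))
        eligible[[cl]] <- eligible[[cl]][eligible[[cl]]$gene_id != g, ]
    }
  }
  anchors <- do.call(rbind, lapply(classes, function(cl) {
    df <- sel[[cl]]
    df$rank <- seq_len(nrow(df))
    df$sector <- ifelse(df$ratio > 1, "plus", "minus")
    df
  }))
  rownames(anchors) <- NULL
  anchors[, c("gene_id", "class_id", "sector", "rank", "t_stat", "p_bonf", "ratio")]
}

#' Place anchors on the sectored display circle
#'
#' The circle is divided into `2 * n_classes` equal arcs ordered
#' class1+, class2+, ..., class1-, class2-, ..., so each class's minus
#' sector sits diametrically opposite its plus sector. Within a sector,
#' anchors are spaced uniformly with half-gap margins at the arc ends,
#' ordered by rank from the arc's counterclockwise start; a lone anchor
#' lands at the arc midpoint.
#'
#' @param anchors output of [select_discriminant_genes()].
#' @param classes class order around the circle (default: order of first
#'   appearance in `anchors`).
#' @return `anchors` with added `angle` (radians) and `angle_deg` columns.
#' @export
layout_anchors <- function(anchors, classes = unique(anchors$class_id)) {
  n_cl <- length(classes)
  arc <- 2 * pi / (2 * n_cl)
  anchors$angle <- NA_real_
  for (ci in seq_along(classes)) {
    for (sec in c("plus", "minus")) {
      s <- (ci - 1) + if (sec == "minus") n_cl else 0
      rows <- which(anchors$class_id == classes[ci] & anchors$sector == sec)
      if (length(rows) == 0) next
      rows <- rows[order(anchors$rank[rows])]
      m <- length(rows)
      anchors$angle[rows] <- s * arc + (seq_len(m) - 0.5) * arc / m
    }
  }
  anchors$angle_deg <- anchors$angle * 180 / pi
  anchors
}

#' Project samples by spring-force equilibrium
#'
#' Each anchor at circle position S_j pulls a sample toward itself with force
#' f_j = k_j d_j (Hooke's law with spring constant k_j, the normalized
#' expression value, and d_j the distance to the anchor). The equilibrium
#' where the vector sum of forces is zero has the closed form
#' u = sum(k_j S_j) / sum(k_j) -- the k-weighted centroid of the anchor
#' positions, always inside their convex hull. A sample with all k_j = 0 is
#' placed at the origin.
#'
#' @param k spring-constant matrix (genes x conditions) from
#'   [normalize_features()].
#' @param anchors laid-out anchors (with `angle`) from [layout_anchors()].
#' @return data.frame of projected points: condition, x, y.
#' @export
project_samples <- function(k, anchors) {
  if (any(is.na(anchors$angle))) stopf("anchors lack angles; run layout_anchors()")
  kk <- k[anchors$gene_id, , drop = FALSE]
  S <- cbind(cos(anchors$angle), sin(anchors$angle))
  tot <- colSums(kk)
  xy <- t(S) %*% kk  # 2 x conditions, unnormalized
  xy <- sweep(xy, 2, ifelse(tot > 0, tot, 1), "/")
  xy[, tot == 0] <- 0
  data.frame(condition = colnames(k), x = xy[1, ], y = xy[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantify class separation of a 2-D projection
#'
#' Deterministic summary of how well the projected points cluster by class:
#' per-class centroids, the fraction of points whose nearest class centroid
#' is their own, and the mean silhouette width over classes. When all points
#' coincide the silhouette is undefined and reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param points projected points from [project_samples()].
#' @param labels class label per point.
#' @return list: centroids, own_centroid_fraction, mean_silhouette,
#'   degenerate.
#' @export
separation_report <- function(points, labels) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stopf("need at least 2 classes")
  if (any(table(factor(labels, classes)) == 0)) stopf("empty class")
  xy <- as.matrix(points[, c("x", "y")])
  cent <- t(sapply(classes, function(cl) colMeans(xy[labels == cl, , drop = FALSE])))
  d2 <- sapply(classes, function(cl)
    (xy[, 1] - cent[cl, 1])^2 + (xy[, 2] - cent[cl, 2])^2)
  nearest <- classes[max.col(-d2, ties.method = "first")]
  own <- mean(nearest == labels)
  if (max(stats::dist(xy)) == 0) {
    return(list(centroids = cent, own_centroid_fraction = own,
                mean_silhouette = 0, degenerate = TRUE))
  }
  sil <- cluster::silhouette(as.integer(factor(labels, classes)), stats::dist(xy))
  list(centroids = cent, own_centroid_fraction = own,
       mean_silhouette = mean(sil[, "sil_width"]), degenerate = FALSE)
}

#' Fit a class-discriminant RadViz model
#'
#' End-to-end convenience wrapper: select discriminant anchor genes, lay them
#' out on the sectored circle, normalize the anchor features and project the
#' labelled conditions, returning everything as one model object.
#'
#' @param x a [regen_expr()].
#' @param labels class label per condition.
#' @param n_per_class anchors per class.
#' @return object of class `radviz`: anchors, points, labels, scaling,
#'   separation.
#' @export
radviz <- function(x, labels, n_per_class = 30) {
  anchors <- select_discriminant_genes(x, labels, n_per_class)
  anchors <- layout_anchors(anchors)
  nf <- normalize_features(x, anchors$gene_id)
  pts <- project_samples(nf$k, anchors)
  if (!is.null(names(labels))) labels <- labels[pts$condition]
  pts$class_id <- as.character(labels)
  structure(list(anchors = anchors, points = pts, labels = labels,
                 scaling = nf$scaling,
                 separation = separation_report(pts, labels)),
            class = "radviz")
}

#' @export
print.radviz <- function(x, ...) {
  cat(sprintf("radviz: %d anchors (%s), %d samples\n",
              nrow(x$anchors),
              paste(sprintf("%s=%d", names(tb <- table(x$anchors$class_id)), tb),
                    collapse = ", "),
              nrow(x$points)))
  cat(sprintf("  own-centroid fraction %.2f, mean silhouette %.2f\n",
              x$separation$own_centroid_fraction, x$separation$mean_silhouette))
  invisible(x)
}

#' Project new conditions through a fitted RadViz model
#'
#' Applies the stored per-gene min-max scaling and anchor layout to new
#' expression data (values outside the training range are clipped to [0,1]).
#'
#' @param object a fitted `radviz` model.
#' @param newdata a [regen_expr()] containing at least the anchor genes.
#' @param ... unused.
#' @export
predict.radviz <- function(object, newdata, ...) {
  v <- newdata$values[object$anchors$gene_id, , drop = FALSE]
  v[is.na(v)] <- 0
  sc <- object$scaling[match(object$anchors$gene_id, object$scaling$gene_id), ]
  rng <- sc$max - sc$min
  k <- (v - sc$min) / ifelse(rng > 0, rng, 1)
  k[rng == 0, ] <- 0.5
  k <- pmin(pmax(k, 0), 1)
  project_samples(k, object$anchors)
}

#' @export
plot.radviz <- function(x, ...) {
  graphics::plot(cos(seq(0, 2 * pi, length.out = 200)),
                 sin(seq(0, 2 * pi, length.out = 200)),
                 type = "l", asp = 1, xlab = "", ylab = "", axes = FALSE, ...)
  n_cl <- length(unique(x$anchors$class_id))
  for (s in seq_len(2 * n_cl) - 1) {
    a <- s * pi / n_cl
    graphics::segments(0, 0, cos(a), sin(a), col = "grey80", lty = 3)
  }
  graphics::points(cos(x$anchors$angle), sin(x$anchors$angle), pch = 3, cex = 0.6)
  cls <- factor(x$points$class_id)
  graphics::points(x$points$x, x$points$y, col = as.integer(cls), pch = 19)
  graphics::legend("topright", legend = levels(cls), col = seq_along(levels(cls)),
                   pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}
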