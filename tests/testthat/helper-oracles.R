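# Independent oracles and fixture builders used across the suite.

# Small regen_expr from a plain matrix; default condition labels cycle
# through tissues with increasing dpa.
make_xmat <- function(values, tissues = NULL, dpa = NULL) {
  values <- as.matrix(values)
  nc <- ncol(values)
  if (is.null(tissues)) tissues <- rep("FL", nc)
  if (is.null(dpa)) dpa <- seq_len(nc)
  colnames(values) <- paste0(tissues, ":", dpa)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  regen_expr(values)
}

# Exhaustive nearest-pair agglomerative clustering (complete linkage),
# recording merge heights and the partition after every merge.
oracle_agglom <- function(m) {
  D <- as.matrix(stats::dist(m))
  cl <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  partitions <- list()
  while (length(cl) > 1) {
    best <- NULL
    bh <- Inf
    for (i in seq_along(cl)) {
      for (j in seq_len(i - 1)) {
        h <- max(D[cl[[i]], cl[[j]]])
        if (h < bh) { bh <- h; best <- c(j, i) }
      }
    }
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
    heights <- c(heights, bh)
    assign <- integer(nrow(m))
    for (k in seq_along(cl)) assign[cl[[k]]] <- k
    partitions[[length(partitions) + 1]] <- assign
  }
  list(heights = heights, partitions = partitions)
}

# Brute-force (gene x class) discriminant scoring via t.test(), with the
# same one-class-per-gene promotion rule, returning the per-class anchor
# gene sets.
oracle_select <- function(x, labels, n_per) {
  v <- x$values
  v[is.na(v)] <- 0
  K <- t(apply(v, 1, function(r) {
    if (max(r) == min(r)) rep(0.5, length(r)) else (r - min(r)) / (max(r) - min(r))
  }))
  rownames(K) <- rownames(v)
  classes <- unique(labels)
  tstat <- matrix(0, nrow(v), length(classes),
                  dimnames = list(rownames(v), classes))
  for (g in rownames(v)) {
    for (cl in classes) {
      a <- K[g, labels == cl]
      b <- K[g, labels != cl]
      tstat[g, cl] <- tryCatch(unname(stats::t.test(a, b)$statistic),
                               error = function(e) 0)
    }
  }
  elig <- lapply(classes, function(cl) {
    rownames(v)[order(-abs(tstat[, cl]), seq_len(nrow(v)))]
  })
  names(elig) <- classes
  repeat {
    sel <- lapply(elig, utils::head, n_per)
    all_sel <- unlist(sel)
    dup <- unique(all_sel[duplicated(all_sel)])
    if (length(dup) == 0) break
    for (g in dup) {
      holders <- names(sel)[vapply(sel, function(s) g %in% s, TRUE)]
      win <- holders[which.max(abs(tstat[g, holders]))]
      for (cl in setdiff(holders, win)) elig[[cl]] <- setdiff(elig[[cl]], g)
    }
  }
  sel
}

# Full enumeration of the hypergeometric mass from binomial coefficients:
# returns P(X >= j) for X ~ Hypergeom(N, K, n).
oracle_hyper_tail <- function(j, n, K, N) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  js <- lo:hi
  mass <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(mass[js >= j])
}

# Iterative force-balance solver for the spring equilibrium: minimizes the
# potential 0.5 * sum k_j |S_j - u|^2 numerically.
oracle_equilibrium <- function(k, S) {
  fn <- function(u) 0.5 * sum(k * ((S[, 1] - u[1])^2 + (S[, 2] - u[2])^2))
  stats::optim(c(0.3, -0.3), fn, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))$par
}
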