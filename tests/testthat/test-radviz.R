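# 9-condition, 3-class fixture with planted class-discriminant genes.
make_labelled_xmat <- function(n_genes = 40, seed = 1) {
  withr::with_seed(seed, {
    tissues <- rep(c("FL", "SC", "H"), each = 3)
    vals <- matrix(rnorm(n_genes * 9, 0, 0.15), n_genes, 9)
    # plant a few strong class markers
    for (i in 1:6) {
      cls <- ((i - 1) %% 3) + 1
      vals[i, tissues == c("FL", "SC", "H")[cls]] <-
        vals[i, tissues == c("FL", "SC", "H")[cls]] + sample(c(-1, 1), 1) * 0.9
    }
    make_xmat(vals, tissues = tissues, dpa = rep(c(1, 6, 12), 3))
  })
}

test_that("spring-constant normalization is min-max onto [0, 1]", {
  x <- make_xmat(matrix(c(-1, 0, 1), nrow = 1), tissues = rep("FL", 3))
  nf <- normalize_features(x)
  expect_equal(unname(nf$k[1, ]), c(0, 0.5, 1))
  # any input stays inside [0, 1]; constant genes sit at 0.5
  x2 <- make_xmat(rbind(withr::with_seed(1, rnorm(5)), rep(2, 5)),
                  tissues = rep("FL", 5))
  nf2 <- normalize_features(x2)
  expect_true(all(nf2$k >= 0 & nf2$k <= 1))
  expect_equal(unname(nf2$k[2, ]), rep(0.5, 5))
  # single-condition display degenerates to 0.5 with a warning
  expect_warning(nf1 <- normalize_features(make_xmat(matrix(1:3, ncol = 1))),
                 "degenerate")
  expect_true(all(nf1$k == 0.5))
})

test_that("planted class markers are selected with the right sector", {
  # class A conditions at {0.8, 1.0}, others at {0, 0.2}:
  # normalized means 0.9 vs 0.1 -> ratio 0.9 / 0.2 = 4.5, sector plus
  vals <- rbind(c(0.8, 1.0, 0, 0.2, 0.2, 0),
                withr::with_seed(2, rnorm(6, 0, 0.1)))
  x <- make_xmat(vals, tissues = c("FL", "FL", "SC", "SC", "H", "H"),
                 dpa = rep(c(1, 6), 3))
  anchors <- select_discriminant_genes(x, x$conditions$tissue, n_per_class = 1)
  a <- anchors[anchors$gene_id == "g01", ]
  expect_equal(a$class_id, "FL")
  expect_equal(a$sector, "plus")
  expect_equal(a$ratio, 4.5, tolerance = 1e-10)
})

test_that("constant genes score t = 0 and are never selected", {
  vals <- rbind(matrix(withr::with_seed(3, rnorm(5 * 9)), 5, 9), rep(1, 9))
  x <- make_xmat(vals, tissues = rep(c("FL", "SC", "H"), each = 3),
                 dpa = rep(c(1, 6, 12), 3))
  anchors <- select_discriminant_genes(x, x$conditions$tissue, n_per_class = 1)
  expect_false("g06" %in% anchors$gene_id)
})

test_that("selection equals the brute-force (gene x class) oracle", {
  for (seed in 1:4) {
    x <- make_labelled_xmat(n_genes = 40, seed = seed)
    labels <- x$conditions$tissue
    anchors <- select_discriminant_genes(x, labels, n_per_class = 10)
    orc <- oracle_select(x, labels, 10)
    for (cl in unique(labels)) {
      expect_setequal(anchors$gene_id[anchors$class_id == cl], orc[[cl]])
    }
    # a gene anchors at most one class; ranks are unique within class
    expect_false(any(duplicated(anchors$gene_id)))
    expect_true(all(tapply(anchors$rank, anchors$class_id,
                           function(r) !any(duplicated(r)))))
  }
})

test_that("anchor layout fills sectors uniformly with half-gap margins", {
  anchors <- data.frame(
    gene_id = sprintf("g%d", 1:5),
    class_id = c("A", "A", "A", "B", "C"),
    sector = c("plus", "plus", "plus", "plus", "minus"),
    rank = c(1, 2, 3, 1, 1), stringsAsFactors = FALSE
  )
  out <- layout_anchors(anchors, classes = c("A", "B", "C"))
  arc <- pi / 3
  a_angles <- out$angle[out$class_id == "A"]
  expect_equal(diff(a_angles), rep(arc / 3, 2))          # equal gaps
  expect_true(all(a_angles > 0 & a_angles < arc))        # inside the arc
  expect_equal(out$angle[out$class_id == "B"], 1.5 * arc) # lone anchor at midpoint
  # C minus sector is diametrically opposite C plus
  expect_equal(out$angle[out$class_id == "C"], 5.5 * arc)
})

test_that("projection has the weighted-centroid closed form", {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  anchors <- data.frame(gene_id = sprintf("g%d", 1:6), class_id = "A",
                        sector = "plus", rank = 1:6, angle = ang)
  k <- matrix(0, 6, 2, dimnames = list(anchors$gene_id, c("FL:1", "FL:6")))
  k[3, 1] <- 0.7                      # single nonzero spring
  k[, 2] <- 0.4                       # uniform springs, symmetric anchors
  pts <- project_samples(k, anchors)
  expect_equal(c(pts$x[1], pts$y[1]), c(cos(ang[3]), sin(ang[3])))
  expect_equal(c(pts$x[2], pts$y[2]), c(0, 0), tolerance = 1e-12)
  # scaling all springs of a sample leaves its position unchanged
  k2 <- k; k2[, 1] <- 0.5; k2[, 2] <- runif(6)
  pts2 <- project_samples(k2, anchors)
  k3 <- k2 * 3
  pts3 <- project_samples(k3, anchors)
  expect_equal(pts2[, c("x", "y")], pts3[, c("x", "y")])
  # all-zero springs land at the origin; everything stays in the unit disc
  k4 <- k2; k4[, 1] <- 0
  pts4 <- project_samples(k4, anchors)
  expect_equal(c(pts4$x[1], pts4$y[1]), c(0, 0))
  expect_true(all(pts2$x^2 + pts2$y^2 <= 1 + 1e-12))
})

test_that("projection matches the iterative force-balance oracle", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      J <- sample(5:12, 1)
      ang <- runif(J, 0, 2 * pi)
      k <- matrix(runif(J), J, 1,
                  dimnames = list(sprintf("g%d", 1:J), "FL:1"))
    })
    anchors <- data.frame(gene_id = rownames(k), class_id = "A",
                          sector = "plus", rank = seq_len(J), angle = ang)
    pts <- project_samples(k, anchors)
    u <- oracle_equilibrium(k[, 1], cbind(cos(ang), sin(ang)))
    expect_equal(c(pts$x, pts$y), u, tolerance = 1e-6)
  }
})

test_that("separation report scores blobs, and flags degenerate projections", {
  pts <- data.frame(
    condition = sprintf("c%d", 1:9),
    x = rep(c(-1, 0, 1), each = 3) + withr::with_seed(4, rnorm(9, 0, 0.01)),
    y = rep(c(0, 1, 0), each = 3)
  )
  lab <- rep(c("A", "B", "C"), each = 3)
  rep1 <- separation_report(pts, lab)
  expect_equal(rep1$own_centroid_fraction, 1)
  expect_gt(rep1$mean_silhouette, 0.5)
  # identical points: silhouette undefined, reported as 0 with flag
  pts0 <- data.frame(condition = c("a", "b", "c", "d"), x = 0, y = 0)
  rep0 <- separation_report(pts0, c("A", "A", "B", "B"))
  expect_true(rep0$degenerate)
  expect_equal(rep0$mean_silhouette, 0)
  expect_error(separation_report(pts0, rep("A", 4)), "2 classes")
})

test_that("the fitted model separates planted tissue programs", {
  frac_own <- vapply(1:3, function(seed) {
    cfg <- sim_config(n_genes = 90, tissues = c("FL", "SC", "H"),
                      frac_conserved = 0.1, frac_tissue_specific = 0.4,
                      effect_log10_range = c(log10(5), log10(20)),
                      bad_feature_rate = 0, n_control_probes = 0, seed = seed)
    sim <- simulate_probe_data(cfg)
    x <- aggregate_replicates(lowess_normalize(qc_filter(sim$probes)$probes))
    model <- radviz(x, x$conditions$tissue, n_per_class = 10)
    model$separation$own_centroid_fraction
  }, 0)
  expect_true(all(frac_own >= 0.9))
})

test_that("model printing and prediction round-trip", {
  x <- make_labelled_xmat(seed = 6)
  model <- radviz(x, x$conditions$tissue, n_per_class = 5)
  expect_output(print(model), "radviz: 15 anchors")
  pred <- predict(model, x)
  expect_equal(pred$x, model$points$x, tolerance = 1e-12)
  expect_equal(nrow(model$anchors), 15)
  expect_true(all(model$anchors$p_bonf >= 0 & model$anchors$p_bonf <= 1))
})
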