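# Toy profile used across several blocks: four genes, one condition.
toy <- make_xmat(matrix(c(0, 0.2, -0.8, 1.1), ncol = 1))

test_that("tier boundaries are inclusive and direction follows sign", {
  x <- make_xmat(matrix(c(log10(2), -1.2, 0.1), ncol = 1))
  calls <- call_differential(x)
  expect_equal(calls$direction, c("up", "down", "none"))
  expect_equal(calls$tier, c("t2", "t10", "none"))
})

test_that("the four-gene toy lands in the expected tiers", {
  calls <- call_differential(toy)
  calls <- calls[match(rownames(toy$values), calls$gene_id), ]
  expect_equal(calls$tier, c("none", "t1p5", "t5", "t10"))
  expect_equal(calls$direction, c("none", "up", "down", "up"))
})

test_that("tiers nest: every deeper tier implies the shallower ones", {
  x <- make_xmat(matrix(withr::with_seed(1, runif(200, -1.5, 1.5)), ncol = 4),
                 tissues = rep("FL", 4))
  calls <- call_differential(x)
  t_lvl <- c(none = 0, t1p5 = 1, t2 = 2, t5 = 3, t10 = 4)
  lv <- t_lvl[calls$tier]
  expect_true(all((lv >= 2) == (calls$magnitude >= log10(2))))
  expect_true(all((lv >= 3) == (calls$magnitude >= log10(5))))
  expect_true(all((lv >= 4) == (calls$magnitude >= 1)))
})

test_that("summary counts are inclusive, monotone, and double-count direction switches", {
  expect_equal(summarize_counts(call_differential(make_xmat(matrix(0, 3, 2))))$n_up,
               c(0, 0, 0))
  # one gene 6-fold up at one dpa and 3-fold down at another
  x <- make_xmat(matrix(c(log10(6), -log10(3)), nrow = 1),
                 tissues = c("FL", "FL"), dpa = c(1, 6))
  s <- summarize_counts(call_differential(x))
  expect_equal(s$n_up, c(1, 1, 0))    # up at >=2 and >=5
  expect_equal(s$n_down, c(1, 0, 0))  # down at >=2 only
  expect_true(all(diff(s$n_up) <= 0) && all(diff(s$n_down) <= 0))
  expect_equal(s$pct_up, 100 * s$n_up / attr(s, "total"))
})

test_that("summary counts equal brute-force enumeration on small instances", {
  for (seed in 1:3) {
    vals <- withr::with_seed(seed, matrix(runif(50 * 6, -1.3, 1.3), 50, 6))
    x <- make_xmat(vals, tissues = rep(c("FL", "SC"), each = 3),
                   dpa = rep(c(1, 6, 12), 2))
    s <- summarize_counts(call_differential(x))
    for (r in seq_len(nrow(s))) {
      th <- log10(s$threshold[r])
      expect_equal(s$n_up[r], sum(apply(vals, 1, function(v) any(v >= th))))
      expect_equal(s$n_down[r], sum(apply(vals, 1, function(v) any(v <= -th))))
    }
  }
})

test_that("planted 5-fold signatures are counted within binomial tolerance", {
  cfg <- sim_config(n_genes = 150, tissues = c("FL", "T"),
                    effect_log10_range = c(log10(5), log10(20)),
                    bad_feature_rate = 0, n_control_probes = 0, seed = 13)
  sim <- simulate_probe_data(cfg)
  x <- aggregate_replicates(lowess_normalize(qc_filter(sim$probes)$probes))
  peak <- tapply(abs(sim$truth$true_log10_fc), sim$truth$gene_id, max)
  n_planted5 <- sum(peak >= log10(5))
  n_called <- n_differential(call_differential(x), fold = 5)
  expect_gte(n_called, 0.9 * n_planted5)
  expect_lte(n_called, 1.1 * n_planted5 + 3)
})

test_that("fold bands are half-open at the top and unbounded when high is NULL", {
  x <- make_xmat(matrix(c(log10(2), log10(1.7), 0.1), ncol = 1))
  expect_false("g01" %in% band_select(x, 1.5, 2))  # exactly 2-fold excluded
  expect_true("g02" %in% band_select(x, 1.5, 2))
  expect_equal(band_select(x, 2), "g01")
  expect_equal(band_select(toy, 2), c("g03", "g04"))
  expect_equal(band_select(toy, 10), "g04")
  expect_error(band_select(toy, 0.5), ">= 1")
})

test_that("per-tissue counts match hand enumeration and localize planted programs", {
  vals <- rbind(c(0.5, 0, 0.4, 0),
                c(-0.4, -0.5, 0, 0),
                c(0, 0.2, 0, 0.9))
  x <- make_xmat(vals, tissues = c("FL", "FL", "SC", "SC"), dpa = c(1, 6, 1, 6))
  pt <- per_tissue_counts(call_differential(x), fold = 2)
  expect_equal(pt$n_up, c(1, 0, 1, 1))
  expect_equal(pt$n_down, c(1, 1, 0, 0))
  # single-condition matrix: per-tissue counts equal whole-matrix counts
  x1 <- make_xmat(matrix(c(0.5, -0.4), ncol = 1), tissues = "FL", dpa = 1)
  pt1 <- per_tissue_counts(call_differential(x1))
  s1 <- summarize_counts(call_differential(x1), thresholds = 2)
  expect_equal(pt1$n_up, s1$n_up)
  expect_equal(pt1$n_down, s1$n_down)
})

test_that("tissue-specific planted programs elevate their own tissue's counts", {
  cfg <- sim_config(n_genes = 120, tissues = c("FL", "SC", "H"),
                    frac_conserved = 0, frac_tissue_specific = 0.4,
                    bad_feature_rate = 0, n_control_probes = 0, seed = 31)
  sim <- simulate_probe_data(cfg)
  x <- aggregate_replicates(lowess_normalize(qc_filter(sim$probes)$probes))
  pt <- per_tissue_counts(call_differential(x))
  tot <- tapply(pt$n_up + pt$n_down, pt$tissue, sum)
  planted <- table(sub("^tissue_specific:", "",
                       grep("tissue_specific",
                            sim$truth$program[!duplicated(sim$truth$gene_id)],
                            value = TRUE)))
  # tissues with more planted genes show more calls
  expect_equal(order(tot[names(planted)]), order(planted))
})

test_that("direction profiles report the attained tiers per direction", {
  x <- make_xmat(matrix(c(0.4, -0.8), nrow = 1), tissues = c("FL", "FL"),
                 dpa = c(1, 6))
  pr <- direction_profile(x, "g01", "FL")
  expect_setequal(pr$up, c("t1p5", "t2"))
  expect_setequal(pr$down, c("t1p5", "t2", "t5"))
  # monotone up gene has an empty down set
  x2 <- make_xmat(matrix(c(0.4, 0.9), nrow = 1), tissues = c("FL", "FL"),
                  dpa = c(1, 6))
  expect_length(direction_profile(x2, "g01", "FL")$down, 0)
  # a tissue with no measurements yields an empty profile
  expect_length(direction_profile(x2, "g01", "SC")$up, 0)
  expect_error(direction_profile(x2, "nope", "FL"), "unknown gene")
})

test_that("null-gene false calls at the 2-fold tier shrink with replicate noise", {
  rates <- vapply(c(0.15, 0.05, 0.01), function(cv) {
    cfg <- sim_config(n_genes = 100, tissues = "FL", frac_conserved = 0,
                      frac_tissue_specific = 0, replicate_cv = cv,
                      bad_feature_rate = 0, n_control_probes = 0, seed = 77)
    sim <- simulate_probe_data(cfg)
    x <- aggregate_replicates(lowess_normalize(qc_filter(sim$probes)$probes))
    n_differential(call_differential(x), 2) / 100
  }, 0)
  expect_true(all(diff(rates) <= 0))
})
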