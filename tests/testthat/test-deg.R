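# DEG module: representation weights, omnibus ANOVA, BH, effect filter,
# post hoc classification and end-to-end invariants.

test_that("weights are tied under symmetry, monotone in mean RPKM, clipped at log(G+1)", {
  d <- toy_design(days = c(0, 3), n_reps = 2)
  same <- matrix(5, 10, 4, dimnames = list(sprintf("g%02d", 1:10), d$sample_id))
  w_same <- compute_weights(same)
  expect_true(all(abs(w_same$weight - w_same$weight[1]) < 1e-12))

  st <- generate_expression(100, frac_deg = 0, seed = 12)
  w <- compute_weights(st$rpkm)
  ord <- order(rowMeans(st$rpkm))
  expect_true(all(diff(w$weight[ord]) >= -1e-12))
  expect_equal(max(w$weight), log(101), tolerance = 1e-12)

  expect_error(compute_weights(matrix(1, 1, 4)), "at least 2 genes")
})

test_that("unit-weight per-gene ANOVA reproduces the textbook one-way ANOVA", {
  d <- toy_design(days = c(0, 3, 6), n_reps = 3)
  y <- matrix(c(0, 0.1, -0.1, 1, 1.1, 0.9, 2, 2.1, 1.9), 1,
              dimnames = list("g1", d$sample_id))
  got <- anova_omnibus(as_l2fc(y, d), pooling = "per_gene")
  want <- anova_oracle_p(y, d$day)
  expect_equal(got$p, unname(want), tolerance = 1e-12)
})

test_that("a flat gene gets p = 1 and a perfectly separated gene p = 0", {
  d <- toy_design(days = c(0, 3), n_reps = 3)
  y <- rbind(flat = rep(0.7, 6), sep = c(0, 0, 0, 1, 1, 1))
  res <- anova_omnibus(as_l2fc(y, d), pooling = "per_gene")
  expect_equal(res$p, c(1, 0))
  expect_equal(res$F[1], 0)
})

test_that("global pooling makes the weights consequential", {
  d <- toy_design(days = c(0, 3), n_reps = 3)
  set.seed(42)
  y <- matrix(rnorm(20 * 6), 20, dimnames = list(sprintf("g%02d", 1:20),
                                                 d$sample_id))
  w1 <- rep(1, 20)
  w2 <- seq(0.1, 4, length.out = 20)
  p1 <- anova_omnibus(as_l2fc(y, d), weights = w1, pooling = "global")$p
  p2 <- anova_omnibus(as_l2fc(y, d), weights = w2, pooling = "global")$p
  expect_false(isTRUE(all.equal(p1, p2)))
  # but constant weights cancel entirely
  p3 <- anova_omnibus(as_l2fc(y, d), weights = rep(7, 20), pooling = "global")$p
  expect_equal(p1, p3, tolerance = 1e-12)
})

test_that("omnibus p-values are uniform under the global null", {
  st <- generate_expression(2000, frac_deg = 0, noise_sd = 0.25, seed = 31)
  l2fc <- compute_log2fc(st$rpkm, st$design)
  p <- anova_omnibus(l2fc, pooling = "per_gene")$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the hand-computed step-up and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in raw-p order
})

test_that("effect filter follows the SSR/SSE arithmetic", {
  d <- toy_design(days = c(0, 3), n_reps = 2)
  # equal group means, within-group spread: SST = SSE, as_written fails
  y_eq <- matrix(c(-1, 1, -1, 1), 1, dimnames = list("g1", d$sample_id))
  ef <- effect_size_filter(as_l2fc(y_eq, d))
  expect_equal(ef$sst, ef$sse)
  expect_false(ef$effect_pass)

  # groups {0,0} and {1,1}: SSE = 0, SST = 1, both modes pass
  y_sep <- matrix(c(0, 0, 1, 1), 1, dimnames = list("g1", d$sample_id))
  ef1 <- effect_size_filter(as_l2fc(y_sep, d), mode = "as_written")
  ef2 <- effect_size_filter(as_l2fc(y_sep, d), mode = "between_vs_within")
  expect_equal(ef1$sst, 1)
  expect_equal(ef1$sse, 0)
  expect_true(ef1$effect_pass && ef2$effect_pass)
})

test_that("effect filter decisions are scale invariant and equivalent to SSB > 0", {
  d <- toy_design(days = c(0, 3, 6), n_reps = 3)
  set.seed(5)
  y <- matrix(rnorm(30 * 9), 30, dimnames = list(sprintf("g%02d", 1:30),
                                                 d$sample_id))
  ef <- effect_size_filter(as_l2fc(y, d))
  ef_scaled <- effect_size_filter(as_l2fc(3.7 * y, d))
  expect_identical(ef$effect_pass, ef_scaled$effect_pass)
  # as_written passes exactly when any between-group signal exists
  expect_identical(ef$effect_pass, ef$ssb > 1e-12)
})

test_that("post hoc classification assigns per-day membership and direction", {
  d <- toy_design(days = c(0, 3, 6, 9), n_reps = 3)
  base <- rep(0, 3)
  # signal only at day 6
  y <- matrix(c(base, base + c(0.01, -0.01, 0), base + 2 + c(0.01, -0.01, 0), base),
              1, dimnames = list("g1", d$sample_id))
  l2fc <- as_l2fc(y, d)
  rec <- posthoc_and_classify(l2fc, p_adj = 0.001, effect_pass = TRUE)
  expect_true(rec$is_deg)
  expect_identical(rec$deg_days, "6")
  expect_identical(rec$dir_day6, "up")
  expect_identical(rec$dir_day3, "none")
  expect_identical(rec$dir_day9, "none")

  # day groups identical to baseline: t = 0, p = 1, no direction
  flat <- matrix(rep(c(0.3, 0.5, 0.1), 4), 1, dimnames = list("g1", d$sample_id))
  rec2 <- posthoc_and_classify(as_l2fc(flat, d), p_adj = 0.001, effect_pass = TRUE)
  expect_equal(rec2$p_day3, 1)
  expect_identical(rec2$dir_day9, "none")
  expect_false(rec2$is_deg)
})

test_that("DEG calls are invariant to rescaling all RPKM by a positive constant", {
  st <- generate_expression(100, frac_deg = 0.3, seed = 17)
  res1 <- detect_degs(st, floor = 0)
  st2 <- st
  st2$rpkm <- st$rpkm * 13.5
  res2 <- detect_degs(st2, floor = 0)
  expect_identical(res1$records$is_deg, res2$records$is_deg)
  expect_identical(res1$records$deg_days, res2$records$deg_days)
})

test_that("the null DEG rate stays at or below the nominal level", {
  st <- generate_expression(1000, frac_deg = 0, seed = 23)
  res <- detect_degs(st)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(res$records$p_adj <= 0.05), 0.05 + 3 * se)
})
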