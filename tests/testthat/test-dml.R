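# Methylation module: beta computation, block QC, imputation, DML calls.

test_that("beta is the methylated fraction in percent", {
  expect_equal(compute_beta(75, 25), 75)
  expect_equal(compute_beta(0, 10), 0)
  expect_equal(compute_beta(10, 0), 100)
  expect_equal(compute_beta(1, 3), 25)
  expect_true(is.na(compute_beta(0, 0)))
  expect_error(compute_beta(-1, 2), "nonnegative")
})

test_that("block QC applies the failed/outlier rules", {
  # clean block
  clean <- qc_filter(c(50, 51, 49))
  expect_identical(clean$status, "keep")
  expect_identical(clean$survivors, 1:3)

  # more than one failed read discards the block
  expect_identical(qc_filter(c(50, 51, 49), failed = c(TRUE, TRUE, FALSE))$status,
                   "discard")

  # one wild replicate against an array-wise fence: dropped, imputation due
  qc <- qc_filter(c(50, 51, 90), fence = c(lower = -5, upper = 5))
  expect_identical(qc$status, "impute_needed")
  expect_identical(qc$survivors, 1:2)
  expect_identical(which(qc$outlier), 3L)

  # two outliers discard
  expect_identical(qc_filter(c(50, 90, 10), fence = c(lower = -5, upper = 5))$status,
                   "discard")
  expect_error(qc_filter(numeric(0)), "empty block")
})

test_that("QC is idempotent on already-filtered blocks", {
  fence <- c(lower = -5, upper = 5)
  qc1 <- qc_filter(c(50, 51, 90), fence = fence)
  surv <- c(50, 51, 90)[qc1$survivors]
  qc2 <- qc_filter(surv, fence = fence)
  expect_identical(qc2$status, "keep")
  expect_identical(length(qc2$survivors), length(surv))
})

test_that("imputation follows the survivor mean plus correlation-weighted residual", {
  expect_equal(impute_third(c(40, 44)), 42)
  expect_equal(impute_third(c(40, 44), context_residuals = c(0, 0),
                            context_correlations = c(0.9, 0.8)), 42)
  expect_equal(impute_third(c(40, 44), context_residuals = 4,
                            context_correlations = 1), 46)
  # opposite-sign correlations do not cancel the denominator
  expect_equal(impute_third(c(40, 44), context_residuals = c(4, -4),
                            context_correlations = c(1, -1)), 46)
  expect_equal(impute_third(c(99, 100), context_residuals = 5,
                            context_correlations = 1), 100)  # clipped
  expect_error(impute_third(c(1, 2, 3)), "exactly 2")
})

test_that("complete noise-free data passes QC untouched and stays within beta bounds", {
  meth <- generate_methylation(150, frac_dml = 0.1, fail_rate = 0,
                               outlier_rate = 0, noise_sd = 0, seed = 19)
  qc <- qc_methylation(meth)
  expect_true(all(qc$provenance == "observed"))
  expect_equal(qc$beta, compute_beta(meth$mcg, meth$cg))
  expect_true(all(qc$beta >= 0 & qc$beta <= 100, na.rm = TRUE))
})

test_that("QC'd and imputed beta values stay within [0, 100]", {
  meth <- generate_methylation(300, frac_dml = 0.1, fail_rate = 0.05,
                               outlier_rate = 0.03, seed = 29)
  qc <- qc_methylation(meth)
  expect_true(all(qc$beta >= 0 & qc$beta <= 100, na.rm = TRUE))
  expect_gt(sum(qc$provenance == "imputed"), 0)
  expect_true(all(is.na(qc$beta[qc$provenance == "discarded"])))
})

test_that("imputation of masked-at-random cells is mean-unbiased", {
  meth <- generate_methylation(400, frac_dml = 0, fail_rate = 0,
                               outlier_rate = 0, noise_sd = 2, seed = 37)
  true_beta <- compute_beta(meth$mcg, meth$cg)
  # mask one replicate in a random subset of blocks (at most 1 per block)
  set.seed(101)
  mask_probes <- sample(nrow(true_beta), 300)
  groups <- interaction(meth$design$cell_line, meth$design$day, drop = TRUE)
  for (p in mask_probes) {
    g <- sample(levels(groups), 1)
    cols <- which(groups == g)
    meth$failed[p, sample(cols, 1)] <- TRUE
  }
  qc <- qc_methylation(meth)
  imputed_cells <- qc$provenance == "imputed"
  expect_gt(sum(imputed_cells), 200)
  err <- qc$beta[imputed_cells] - true_beta[imputed_cells]
  # Monte-Carlo bound on the mean error (3 standard errors + slack)
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)) + 0.05)
})

test_that("DML calling handles degenerate probes and discarded baselines", {
  d <- toy_design(days = c(0, 3), n_reps = 3)
  beta <- rbind(const = rep(60, 6),
                shift = c(20, 21, 19, 80, 81, 79),
                nobase = c(NA, NA, NA, 50, 51, 49))
  colnames(beta) <- d$sample_id
  res <- call_dml(beta, design = d)
  expect_false("nobase" %in% res$records$probe_id)
  expect_identical(res$excluded, "nobase")
  const_row <- res$records[res$records$probe_id == "const", ]
  expect_equal(const_row$p_raw, 1)
  expect_equal(const_row$delta_day3, 0)
  expect_identical(const_row$dir_day3, "none")
  shift_row <- res$records[res$records$probe_id == "shift", ]
  expect_true(shift_row$is_dml)
  expect_identical(shift_row$dir_day3, "hyper")
  expect_equal(shift_row$delta_day3, 60)
})

test_that("every per-day significant probe has exactly one direction", {
  meth <- generate_methylation(300, frac_dml = 0.2, seed = 41)
  res <- call_dml(qc_methylation(meth), probe_annot = meth$probe_annot)
  for (d in c(3, 6, 9)) {
    p <- res$records[[paste0("p_day", d)]]
    dir <- res$records[[paste0("dir_day", d)]]
    sig <- !is.na(p) & p < 0.05
    expect_true(all(dir[sig] %in% c("hyper", "hypo")))
    expect_true(all(dir[!sig] == "none"))
  }
})

test_that("the null DML rate stays at or below the nominal level", {
  meth <- generate_methylation(500, frac_dml = 0, seed = 43)
  res <- call_dml(qc_methylation(meth), probe_annot = meth$probe_annot)
  se <- sqrt(0.05 * 0.95 / nrow(res$records))
  expect_lte(mean(res$records$is_dml), 0.05 + 3 * se)
})
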