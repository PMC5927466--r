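# Integration module: gene-level methylation summaries, DMEG counts,
# the DEG x promoter-methylation 2x2 and sign concordance.

# Build a minimal annotated DML record table for one day.
dml_records <- function(gene, class, delta, day = 3) {
  n <- length(gene)
  rec <- data.frame(probe_id = sprintf("cg%03d", seq_len(n)),
                    gene_id = gene, location_class = class,
                    stringsAsFactors = FALSE)
  rec[[paste0("delta_day", day)]] <- delta
  rec[[paste0("dir_day", day)]] <- ifelse(delta > 0, "hyper",
                                          ifelse(delta < 0, "hypo", "none"))
  rec
}

# Build a minimal DEG record table with per-day calls and directions.
deg_records <- function(gene, called, dir, day = 3) {
  rec <- data.frame(gene_id = gene, is_deg = called, stringsAsFactors = FALSE)
  rec[[paste0("deg_day", day)]] <- called
  rec[[paste0("dir_day", day)]] <- dir
  rec
}

test_that("gene methylation summaries average significant probes per scope", {
  one <- summarize_gene_methylation(dml_records("gA", "TSS200", 10), 3)
  expect_equal(one$promoter_delta, 10)
  expect_true(one$has_promoter_dml)

  two <- summarize_gene_methylation(
    dml_records(c("gA", "gA"), c("TSS200", "TSS1500"), c(10, -10)), 3)
  expect_equal(two$promoter_delta, 0)
  expect_true(two$has_promoter_dml)

  mix <- summarize_gene_methylation(
    dml_records(rep("gA", 3), c("TSS1500", "Body", "5UTR"), c(10, 30, 20)), 3)
  expect_equal(mix$overall_delta, 20)     # mean of the three
  expect_equal(mix$promoter_delta, 10)
  expect_equal(mix$body_delta, 30)

  # intergenic probes never reach a gene summary
  igr <- summarize_gene_methylation(
    dml_records(NA_character_, "IGR", 15), 3)
  expect_identical(nrow(igr), 0L)
})

test_that("DMEG counts and published-style percentages", {
  expect_equal(count_dmegs_fraction(63, 236), 27)
  expect_equal(count_dmegs_fraction(978, 2135), 46)
  expect_equal(count_dmegs_fraction(1627, 2854), 57)
  expect_equal(count_dmegs_fraction(0, 100), 0)

  genes <- sprintf("g%03d", 1:50)
  degs <- deg_records(genes, called = seq_along(genes) <= 20, dir = "up")
  dmeg <- count_dmegs(degs, genes[1:5], 3)       # 5 of the 20 DEGs flagged
  expect_equal(dmeg$n_deg, 20)
  expect_equal(dmeg$n_dmeg, 5)
  expect_equal(dmeg$pct, 25)

  none <- count_dmegs(deg_records(genes, called = rep(FALSE, 50), dir = "none"),
                      genes[1:5], 3)
  expect_true(is.na(none$pct))
})

test_that("adding a promoter DML to a DEG never decreases the DMEG count", {
  genes <- sprintf("g%02d", 1:20)
  degs <- deg_records(genes, called = seq_along(genes) <= 10, dir = "up")
  base_set <- genes[1:3]
  n0 <- count_dmegs(degs, base_set, 3)$n_dmeg
  n1 <- count_dmegs(degs, c(base_set, genes[4]), 3)$n_dmeg
  expect_gte(n1, n0)
})

test_that("odds ratio and chi-squared match brute-force arithmetic", {
  make_universe <- function(a, b, c_, d) {
    n <- a + b + c_ + d
    u <- sprintf("g%04d", seq_len(n))
    list(universe = u,
         deg = u[seq_len(a + b)],
         dml = c(u[seq_len(a)], u[a + b + seq_len(c_)]))
  }
  # proportional table: OR exactly 1
  s <- make_universe(10, 20, 30, 60)
  res <- deg_dml_association(s$deg, s$dml, s$universe)
  expect_equal(res$odds_ratio, 1)

  # hand-computed chi-squared from expected counts under fixed margins
  s2 <- make_universe(20, 10, 10, 20)
  res2 <- deg_dml_association(s2$deg, s2$dml, s2$universe)
  expect_equal(res2$odds_ratio, 4)
  obs <- c(20, 10, 10, 20)
  n <- sum(obs)
  expected <- outer(c(30, 30), c(30, 30)) / n
  chi2_oracle <- sum((matrix(obs, 2, byrow = TRUE) - expected)^2 / expected)
  expect_equal(res2$chi2, chi2_oracle, tolerance = 1e-12)
  expect_equal(res2$chi2, 20 / 3, tolerance = 1e-12)

  # zero cell: Haldane-Anscombe keeps the OR finite and positive
  s3 <- make_universe(0, 10, 5, 30)
  res3 <- deg_dml_association(s3$deg, s3$dml, s3$universe)
  expect_equal(res3$odds_ratio, (0.5 * 30.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_gt(res3$odds_ratio, 0)

  # random tables: OR equals a d / (b c), margins conserved
  set.seed(11)
  for (i in 1:20) {
    cells <- sample(1:40, 4, replace = TRUE)
    s4 <- make_universe(cells[1], cells[2], cells[3], cells[4])
    r <- deg_dml_association(s4$deg, s4$dml, s4$universe)
    expect_equal(r$odds_ratio, (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-12)
    expect_identical(r$a + r$b, length(s4$deg))
    expect_identical(r$a + r$b + r$c + r$d, length(s4$universe))
  }
  expect_error(deg_dml_association("gX", character(0), "gY"), "universe")
})

test_that("planted DEG-DML coupling pushes the odds ratio above 1 and it grows with q", {
  set.seed(21)
  universe <- sprintf("g%05d", 1:3000)
  deg <- sample(universe, 600)
  or_at <- function(q) {
    background <- 0.10
    p_dml <- ifelse(universe %in% deg, q, background)
    dml <- universe[runif(3000) < p_dml]
    deg_dml_association(deg, dml, universe)$odds_ratio
  }
  or_low <- or_at(0.25)
  or_high <- or_at(0.55)
  expect_gt(or_low, 1)
  expect_gt(or_high, or_low)
})

test_that("concordance quadrants follow the chosen sign convention", {
  genes <- c("gA", "gB")
  summ <- data.frame(gene_id = genes, promoter_delta = c(-5, -7),
                     body_delta = NA_real_, overall_delta = c(-5, -7),
                     has_promoter_dml = TRUE, stringsAsFactors = FALSE)
  degs <- deg_records(genes, called = c(TRUE, TRUE), dir = c("up", "up"))
  res <- concordance(degs, summ, 3, scope = "promoter",
                     convention = "promoter_inverse")
  expect_equal(res$fraction, 1)            # all hypo & up
  res_same <- concordance(degs, summ, 3, scope = "promoter",
                          convention = "same_sign")
  expect_equal(res_same$fraction, 0)

  one <- concordance(deg_records("gA", TRUE, "up"),
                     data.frame(gene_id = "gA", promoter_delta = 9,
                                body_delta = NA_real_, overall_delta = 9,
                                has_promoter_dml = TRUE),
                     3, scope = "promoter", convention = "promoter_inverse")
  expect_equal(one$fraction, 0)            # single hyper & up

  empty <- concordance(deg_records("gA", FALSE, "none"), summ[1, ], 3)
  expect_true(is.na(empty$fraction))
})

test_that("independent balanced signs give concordance near one half", {
  set.seed(33)
  n <- 4000
  genes <- sprintf("g%05d", seq_len(n))
  degs <- deg_records(genes, called = rep(TRUE, n),
                      dir = sample(c("up", "down"), n, replace = TRUE))
  summ <- data.frame(gene_id = genes,
                     promoter_delta = sample(c(-1, 1), n, replace = TRUE),
                     body_delta = NA_real_, overall_delta = NA_real_,
                     has_promoter_dml = TRUE, stringsAsFactors = FALSE)
  res <- concordance(degs, summ, 3, scope = "promoter")
  se <- sqrt(0.25 / n)
  expect_lt(abs(res$fraction - 0.5), 3 * se + 1e-9)
})
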