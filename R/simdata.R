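# Synthetic multi-omic time-course generator with planted effects.
#
# Emulates the study design of an inducible mtDNA-depletion cell model:
# days 0/3/6/9, three replicates for expression and methylation, four for
# metabolomics, with per-day effects planted on a known subset of
# features, replicate noise on the log2 (or percentage-point) scale,
# failed probe reads and displaced outlier replicates. Every generator is
# deterministic given its seed; randomness never touches global RNG state.

DAYS_DEFAULT <- c(0L, 3L, 6L, 9L)

make_design <- function(cell_line, days, n_reps, prefix) {
  grid <- expand.grid(replicate = seq_len(n_reps), day = days,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(
    sample_id = sprintf("%s_d%d_r%d", prefix, grid$day, grid$replicate),
    cell_line = cell_line,
    day = as.integer(grid$day),
    replicate = as.integer(grid$replicate),
    stringsAsFactors = FALSE
  )
}

# Plant per-day effects on a contiguous random run of non-baseline days.
# Returns a feature x day matrix of signed log2 (or percentage) effects.
plant_effects <- function(feature_ids, n_planted, days, effect_size,
                          direction = NULL) {
  nb <- days[days != min(days)]
  truth <- matrix(0, length(feature_ids), length(nb),
                  dimnames = list(feature_ids, as.character(nb)))
  if (n_planted == 0L) return(truth)
  planted <- sample(feature_ids, n_planted)
  for (f in planted) {
    i <- sample.int(length(nb), 1L)               # run start
    j <- sample(seq(i, length(nb)), 1L)           # run end (contiguous)
    dir <- if (is.null(direction)) sample(c(-1, 1), 1L) else direction
    truth[f, i:j] <- dir * effect_size
  }
  truth
}

effect_for_samples <- function(truth, design) {
  eff <- matrix(0, nrow(truth), nrow(design),
                dimnames = list(rownames(truth), design$sample_id))
  for (d in colnames(truth)) {
    cols <- design$day == as.integer(d)
    eff[, cols] <- truth[, d]
  }
  eff
}

#' Simulate an RPKM expression time course with planted DEGs
#'
#' Baseline log2-RPKM is drawn per gene from a normal(3, 2) truncated so
#' RPKM stays above 0.01, spanning the dynamic range over which the
#' sequencing-representation weighting differentiates genes. A fraction
#' `frac_deg` of genes receives a planted shift of `effect_sd` log2 units
#' (random sign, applied over a contiguous random run of non-baseline
#' days); replicate noise is i.i.d. normal on the log2 scale.
#'
#' @param n_genes Number of genes (>= 10).
#' @param frac_deg Fraction of genes with a planted effect, in `[0, 1]`.
#' @param effect_sd Planted per-day effect magnitude, log2 units.
#' @param noise_sd Replicate noise standard deviation, log2 units (> 0).
#' @param n_reps Replicates per time point (default 3).
#' @param days Time points; the smallest is the baseline.
#' @param cell_line Cell-line label for the design table.
#' @param seed Integer seed; identical seeds give identical studies.
#' @return An `expression_study`: list with `rpkm` (gene x sample matrix),
#'   `design`, and `truth` (gene x non-baseline-day matrix of planted
#'   log2 effects; 0 = null).
#' @examples
#' st <- generate_expression(100, frac_deg = 0.2, effect_sd = 2,
#'                           noise_sd = 0.25, seed = 7)
#' sum(rowSums(st$truth != 0) > 0)  # 20 planted genes
#' @export
generate_expression <- function(n_genes, frac_deg = 0.2, effect_sd = 2,
                                noise_sd = 0.25, n_reps = 3L,
                                days = DAYS_DEFAULT, cell_line = "DN-POLG",
                                seed = 1L) {
  if (n_genes < 10L) stop("n_genes must be >= 10", call. = FALSE)
  if (frac_deg < 0 || frac_deg > 1) stop("frac_deg must be in [0, 1]", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  withr::with_seed(seed, {
    design <- make_design(cell_line, days, n_reps, "expr")
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    base <- pmax(stats::rnorm(n_genes, mean = 3, sd = 2), log2(0.01))
    truth <- plant_effects(genes, round(frac_deg * n_genes), days, effect_sd)
    eff <- effect_for_samples(truth, design)
    noise <- matrix(stats::rnorm(n_genes * nrow(design), 0, noise_sd),
                    n_genes, nrow(design))
    rpkm <- 2^(base + eff + noise)
    dimnames(rpkm) <- list(genes, design$sample_id)
    structure(list(rpkm = rpkm, design = design, truth = truth,
                   noise_sd = noise_sd),
              class = "expression_study")
  })
}

#' Simulate a metabolite abundance time course with planted effects
#'
#' Same scheme as [generate_expression()] on the metabolite scale:
#' baseline log2 abundance ~ normal(10, 2) in arbitrary detection units,
#' four replicates per time point by default, planted log2 shifts on a
#' contiguous run of days, log-normal replicate noise.
#'
#' @param n_metab Number of metabolites.
#' @param frac_dem Fraction with a planted effect.
#' @inheritParams generate_expression
#' @return A `metabolite_study`: list with `content` (positive metabolite
#'   x sample matrix), `design`, `truth`.
#' @export
generate_metabolomics <- function(n_metab, frac_dem = 0.25, effect_sd = 0.6,
                                  noise_sd = 0.15, n_reps = 4L,
                                  days = DAYS_DEFAULT, cell_line = "DN-POLG",
                                  seed = 1L) {
  if (n_metab < 10L) stop("n_metab must be >= 10", call. = FALSE)
  if (frac_dem < 0 || frac_dem > 1) stop("frac_dem must be in [0, 1]", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  withr::with_seed(seed, {
    design <- make_design(cell_line, days, n_reps, "met")
    ids <- sprintf("metab_%04d", seq_len(n_metab))
    base <- stats::rnorm(n_metab, mean = 10, sd = 2)
    truth <- plant_effects(ids, round(frac_dem * n_metab), days, effect_sd)
    eff <- effect_for_samples(truth, design)
    noise <- matrix(stats::rnorm(n_metab * nrow(design), 0, noise_sd),
                    n_metab, nrow(design))
    content <- 2^(base + eff + noise)
    dimnames(content) <- list(ids, design$sample_id)
    structure(list(content = content, design = design, truth = truth,
                   noise_sd = noise_sd),
              class = "metabolite_study")
  })
}

#' Simulate non-overlapping gene annotation intervals
#'
#' Places `n_genes` disjoint genes of length 500-5,000 bp on a single
#' chromosome of `genome_length` bases, with random strands; intervals
#' are 0-based half-open (BED convention).
#'
#' @param n_genes Number of genes.
#' @param genome_length Chromosome length in bases.
#' @param seed Integer seed.
#' @return Data frame of class `gene_annotation` with `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
generate_annotation <- function(n_genes, genome_length = 1e7, seed = 1L) {
  withr::with_seed(seed, {
    lens <- sample(500:5000, n_genes, replace = TRUE)
    slack <- genome_length - sum(lens)
    if (slack < 0) {
      stop("n_genes too large for genome_length (genes cannot fit disjointly)",
           call. = FALSE)
    }
    # split the slack into n_genes + 1 random gaps
    cuts <- sort(stats::runif(n_genes, 0, slack))
    gaps <- floor(c(cuts[1], diff(cuts)))
    starts <- cumsum(gaps) + c(0, cumsum(lens[-n_genes]))
    annot <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      chrom = "chr1",
      start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    class(annot) <- c("gene_annotation", "data.frame")
    annot
  })
}

LOCATION_CLASSES <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")

#' Simulate a 450K-style methylation time course with planted DMLs
#'
#' Per-probe baseline beta is drawn from a bimodal mixture on \[0, 100\]
#' (half near-unmethylated, half near-methylated, beta(2,18)/beta(18,2)
#' scaled to percent) matching the characteristic two-peak array profile.
#' Paired intensities are constructed so `mcg/(mcg+cg) * 100` equals the
#' intended beta exactly; replicate noise (percentage points) perturbs the
#' beta before intensity construction. Planted probes shift by
#' `delta_beta` points (random sign, flipped when it would leave
#' \[0, 100\]) over a contiguous run of days. A fraction `fail_rate` of
#' cells is flagged failed and a fraction `outlier_rate` of replicate
#' values is displaced by 3-6 times the replicate noise scale; outliers
#' are injected before the failed mask, so a cell can be both.
#'
#' @param n_probes Number of probes.
#' @param frac_dml Fraction of probes with a planted effect.
#' @param delta_beta Planted shift in percentage points, in (-100, 100).
#' @param fail_rate,outlier_rate Per-cell rates, each in `[0, 0.2]`.
#' @param noise_sd Replicate noise sd in percentage points.
#' @param annot Optional `gene_annotation` to draw probe-gene assignments
#'   from; generated internally when `NULL`.
#' @param frac_igr Fraction of probes left intergenic (no gene).
#' @inheritParams generate_expression
#' @return A `methylation_study`: list with `mcg`, `cg` (probe x sample
#'   intensity matrices), `failed` (logical mask), `probe_annot`
#'   (`probe_id`, `gene_id`, `location_class`), `design`, `truth`.
#' @export
generate_methylation <- function(n_probes, frac_dml = 0.1, delta_beta = 20,
                                 fail_rate = 0.02, outlier_rate = 0.01,
                                 noise_sd = 2, n_reps = 3L,
                                 days = DAYS_DEFAULT, cell_line = "DN-POLG",
                                 annot = NULL, frac_igr = 0.25, seed = 1L) {
  if (abs(delta_beta) >= 100) stop("delta_beta must lie in (-100, 100)", call. = FALSE)
  if (fail_rate < 0 || fail_rate > 0.2) stop("fail_rate must be in [0, 0.2]", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate > 0.2) stop("outlier_rate must be in [0, 0.2]", call. = FALSE)
  withr::with_seed(seed, {
    design <- make_design(cell_line, days, n_reps, "meth")
    probes <- sprintf("cg%06d", seq_len(n_probes))
    n_s <- nrow(design)
    lowhigh <- stats::runif(n_probes) < 0.5
    base <- ifelse(lowhigh,
                   100 * stats::rbeta(n_probes, 2, 18),
                   100 * stats::rbeta(n_probes, 18, 2))

    nb <- days[days != min(days)]
    truth <- matrix(0, n_probes, length(nb),
                    dimnames = list(probes, as.character(nb)))
    n_planted <- round(frac_dml * n_probes)
    if (n_planted > 0L) {
      planted <- sample(probes, n_planted)
      for (f in planted) {
        i <- sample.int(length(nb), 1L)
        j <- sample(seq(i, length(nb)), 1L)
        dir <- sample(c(-1, 1), 1L)
        b <- base[match(f, probes)]
        if (b + dir * delta_beta < 0 || b + dir * delta_beta > 100) dir <- -dir
        truth[f, i:j] <- dir * delta_beta
      }
    }
    eff <- effect_for_samples(truth, design)
    beta <- base + eff
    if (noise_sd > 0) {
      beta <- beta + matrix(stats::rnorm(n_probes * n_s, 0, noise_sd),
                            n_probes, n_s)
    }
    # outliers: displacement well beyond the replicate noise scale
    out_mask <- matrix(stats::runif(n_probes * n_s) < outlier_rate,
                       n_probes, n_s)
    n_out <- sum(out_mask)
    if (n_out > 0L) {
      shift_scale <- max(noise_sd, 1)
      beta[out_mask] <- beta[out_mask] +
        sample(c(-1, 1), n_out, replace = TRUE) *
        stats::runif(n_out, 5, 10) * shift_scale
    }
    beta <- clip(beta, 0, 100)
    failed <- matrix(stats::runif(n_probes * n_s) < fail_rate, n_probes, n_s)

    total <- matrix(stats::runif(n_probes * n_s, 2000, 8000), n_probes, n_s)
    mcg <- total * beta / 100
    cg <- total - mcg
    dimnames(mcg) <- dimnames(cg) <- dimnames(failed) <-
      list(probes, design$sample_id)

    if (is.null(annot)) {
      annot <- generate_annotation(max(10L, ceiling(n_probes / 10)),
                                   seed = seed + 1L)
    }
    igr <- stats::runif(n_probes) < frac_igr
    probe_annot <- data.frame(
      probe_id = probes,
      gene_id = ifelse(igr, NA_character_,
                       sample(annot$gene_id, n_probes, replace = TRUE)),
      location_class = ifelse(igr, "IGR",
                              sample(LOCATION_CLASSES, n_probes, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    structure(list(mcg = mcg, cg = cg, failed = failed,
                   probe_annot = probe_annot, design = design,
                   truth = truth, noise_sd = noise_sd),
              class = "methylation_study")
  })
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression study: %d genes x %d samples, %d planted\n",
              nrow(x$rpkm), ncol(x$rpkm), sum(rowSums(x$truth != 0) > 0)))
  invisible(x)
}

#' @export
print.metabolite_study <- function(x, ...) {
  cat(sprintf("metabolite study: %d metabolites x %d samples, %d planted\n",
              nrow(x$content), ncol(x$content), sum(rowSums(x$truth != 0) > 0)))
  invisible(x)
}

#' @export
print.methylation_study <- function(x, ...) {
  cat(sprintf("methylation study: %d probes x %d samples, %d planted, %d failed cells\n",
              nrow(x$mcg), ncol(x$mcg), sum(rowSums(x$truth != 0) > 0),
              sum(x$failed)))
  invisible(x)
}
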