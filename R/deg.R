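# Differentially expressed gene calling: sequencing-representation
# weights, omnibus ANOVA on log2FC, BH adjustment, SSR/SSE effect-size
# filter and per-day post hoc classification.

#' Sequencing-representation weights from RPKM rate modelling
#'
#' Builds one nonnegative weight per gene reflecting how well the gene is
#' represented in the sequencing output. Per gene, the exponential rate of
#' its RPKM values is the maximum-likelihood estimate
#' `lambda_g = 1 / mean(rpkm_g + floor)` (with the inverse link, the
#' fitted linear predictor is the rate itself). The significance score is
#' the lower-tail probability of the gene's mean RPKM under an exponential
#' law with the transcriptome-wide pooled rate: strongly expressed genes
#' score near 1. The weight is the cumulative hazard of the score under
#' the empirical score distribution, `-log(1 - Fhat(score))` with
#' `Fhat = rank / (G + 1)` (average ranks on ties), clipped at
#' `log(G + 1)` so the top-ranked gene attains exactly the clip value.
#'
#' @param study An `expression_study`, or a plain RPKM matrix.
#' @param floor Additive floor on the RPKM scale.
#' @param clip Maximum weight; default `log(G + 1)`.
#' @return Data frame with `gene_id`, `rate`, `score`, `weight`.
#' @export
compute_weights <- function(study, floor = 0.01, clip = NULL) {
  rpkm <- if (inherits(study, "expression_study")) study$rpkm else as.matrix(study)
  G <- nrow(rpkm)
  if (G < 2L) stop("need at least 2 genes for the empirical score CDF", call. = FALSE)
  if (any(rpkm < 0)) stop("RPKM must be nonnegative", call. = FALSE)
  xf <- rpkm + floor
  gene_mean <- rowMeans(xf)
  rate <- 1 / gene_mean
  pooled_rate <- 1 / mean(xf)
  score <- stats::pexp(gene_mean, rate = pooled_rate)   # 1 - upper tail
  Fhat <- rank(score, ties.method = "average") / (G + 1)
  if (is.null(clip)) clip <- log(G + 1)
  weight <- pmin(-log(1 - Fhat), clip)
  data.frame(gene_id = rownames(rpkm), rate = rate, score = score,
             weight = weight, row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-wise effect-size decomposition and filter
#'
#' Decomposes each gene's log2FC values into the total sum of squares
#' about the gene grand mean (the regression error SSR) and the
#' within-time-group sum of squares (the measurement error SSE), and
#' compares the two spreads at 5% of their 6-sigma widths:
#' `delta = 0.3 * sigma_SSR` with `sigma_SSR = sqrt(SST / (N - 1))`,
#' against `0.3 * sigma_log2FC` with `sigma_log2FC = sqrt(SSE / (N - 1))`.
#'
#' Because SST = SSB + SSE, the literal comparison `SST > SSE` passes
#' whenever any between-group signal exists (SSB > 0); the
#' `between_vs_within` mode instead requires the between-group sum of
#' squares to exceed the within-group one (SSB > SSE), a materially
#' stricter filter. Both use strict inequality.
#'
#' @param l2fc A `log2fc_matrix`.
#' @param mode `"as_written"` (SST > SSE) or `"between_vs_within"`
#'   (SSB > SSE).
#' @return Data frame with `gene_id`, `sst`, `sse`, `ssb`, `n`,
#'   `sigma_ssr`, `sigma_log2fc`, `delta`, `effect_pass`.
#' @export
effect_size_filter <- function(l2fc, mode = c("as_written", "between_vs_within")) {
  mode <- match.arg(mode)
  values <- l2fc$values
  N <- ncol(values)
  if (N < 3L) stop("need N >= 3 samples", call. = FALSE)
  dec <- group_decomposition(values, l2fc$design$day)
  sigma_ssr <- sqrt(dec$sst / (N - 1))
  sigma_l2fc <- sqrt(dec$sse / (N - 1))
  pass <- if (mode == "as_written") dec$sst > dec$sse else dec$ssb > dec$sse
  data.frame(gene_id = rownames(values), sst = dec$sst, sse = dec$sse,
             ssb = dec$ssb, n = N, sigma_ssr = sigma_ssr,
             sigma_log2fc = sigma_l2fc, delta = 0.3 * sigma_ssr,
             effect_pass = pass, row.names = NULL, stringsAsFactors = FALSE)
}

#' Post hoc per-day tests and DEG classification
#'
#' Runs equal-variance two-sample Student t tests of each non-baseline
#' day's log2FC replicates against the day-0 replicates, assigns per-day
#' directions (up/down when the unadjusted p falls below `alpha_posthoc`),
#' and classifies a gene as a DEG when its BH-adjusted omnibus p is at
#' most `alpha`, it passes the effect-size filter, and at least one
#' per-day test is significant.
#'
#' @param l2fc A `log2fc_matrix`.
#' @param p_adj BH-adjusted omnibus p-values aligned with the rows.
#' @param effect_pass Logical vector from [effect_size_filter()].
#' @param alpha Omnibus threshold (inclusive), default 0.05.
#' @param alpha_posthoc Post hoc threshold (strict), default 0.05.
#' @return Data frame with one row per gene: `gene_id`, `p_adj`,
#'   `effect_pass`, per-day columns `p_day<d>`, `dir_day<d>`,
#'   `l2fc_day<d>` (group mean minus baseline mean), `is_deg`, `deg_days`
#'   (comma-separated).
#' @export
posthoc_and_classify <- function(l2fc, p_adj, effect_pass,
                                 alpha = 0.05, alpha_posthoc = 0.05) {
  values <- l2fc$values
  if (length(p_adj) != nrow(values) || length(effect_pass) != nrow(values)) {
    stop("p_adj/effect_pass not aligned with the fold-change rows", call. = FALSE)
  }
  ph <- posthoc_vs_baseline(values, l2fc$design, l2fc$baseline_day,
                            alpha_posthoc, labels = c("up", "down"))
  out <- data.frame(gene_id = rownames(values), p_adj = p_adj,
                    effect_pass = effect_pass,
                    row.names = NULL, stringsAsFactors = FALSE)
  any_sig <- rep(FALSE, nrow(values))
  day_sets <- matrix(FALSE, nrow(values), length(ph),
                     dimnames = list(NULL, names(ph)))
  for (d in names(ph)) {
    out[[paste0("p_day", d)]] <- ph[[d]]$p
    out[[paste0("dir_day", d)]] <- ph[[d]]$direction
    out[[paste0("l2fc_day", d)]] <- ph[[d]]$diff
    day_sets[, d] <- ph[[d]]$p < alpha_posthoc
    any_sig <- any_sig | day_sets[, d]
  }
  out$is_deg <- out$p_adj <= alpha & out$effect_pass & any_sig
  for (d in colnames(day_sets)) {
    out[[paste0("deg_day", d)]] <- out$is_deg & day_sets[, d]
  }
  out$deg_days <- apply(day_sets & out$is_deg, 1, function(z) {
    paste(colnames(day_sets)[z], collapse = ",")
  })
  out
}

#' Full DEG detection pipeline on an expression study
#'
#' Chains [compute_log2fc()], [compute_weights()], [anova_omnibus()],
#' [bh_adjust()], [effect_size_filter()] and [posthoc_and_classify()].
#'
#' @param study An `expression_study` (or list with `rpkm` and `design`).
#' @param alpha,alpha_posthoc Significance thresholds.
#' @param weights `"hazard"` for sequencing-representation weights,
#'   `"none"` for unit weights.
#' @param pooling Error pooling for the omnibus test; weights only matter
#'   under `"global"` pooling.
#' @param effect_mode Effect-filter mode, see [effect_size_filter()].
#' @param floor Additive RPKM floor before log2.
#' @return A `deg_result`: list with `records` (per-gene table), `summary`
#'   (per-day up/down counts and intersection), and the intermediate
#'   `weights`.
#' @examples
#' st <- generate_expression(60, frac_deg = 0.2, seed = 3)
#' res <- detect_degs(st)
#' res$summary$n_deg_total
#' @export
detect_degs <- function(study, alpha = 0.05, alpha_posthoc = 0.05,
                        weights = c("hazard", "none"),
                        pooling = c("per_gene", "global"),
                        effect_mode = c("as_written", "between_vs_within"),
                        floor = 0.01) {
  weights <- match.arg(weights)
  pooling <- match.arg(pooling)
  effect_mode <- match.arg(effect_mode)
  l2fc <- compute_log2fc(study$rpkm, study$design, floor = floor)
  w <- if (weights == "hazard") compute_weights(study$rpkm, floor = floor) else NULL
  omni <- anova_omnibus(l2fc, weights = w, pooling = pooling)
  p_adj <- bh_adjust(omni$p)
  ef <- effect_size_filter(l2fc, mode = effect_mode)
  rec <- posthoc_and_classify(l2fc, p_adj, ef$effect_pass,
                              alpha = alpha, alpha_posthoc = alpha_posthoc)
  rec$p_raw <- omni$p
  structure(list(records = rec, weights = w,
                 effect = ef, summary = summarize_calls(rec, "deg")),
            class = "deg_result")
}

# Per-day up/down counts and the cross-day intersection for a record
# table with deg_day<d>/dir_day<d> columns.
summarize_calls <- function(rec, prefix) {
  day_cols <- grep(paste0("^", prefix, "_day[0-9]"), names(rec), value = TRUE)
  days <- sub(paste0(prefix, "_day"), "", day_cols)
  per_day <- lapply(days, function(d) {
    called <- rec[[paste0(prefix, "_day", d)]]
    dir <- rec[[paste0("dir_day", d)]]
    n <- sum(called)
    up <- sum(called & dir == "up")
    down <- sum(called & dir == "down")
    list(day = d, n = n, up = up, down = down,
         pct_up = if (n > 0) as.numeric(round_half_up(100 * up / n)) else NA_real_)
  })
  names(per_day) <- days
  inter <- Reduce(`&`, lapply(days, function(d) rec[[paste0(prefix, "_day", d)]]))
  list(per_day = per_day,
       n_total = sum(rec[[grep("^is_", names(rec), value = TRUE)[1]]]),
       n_deg_total = sum(rec[[grep("^is_", names(rec), value = TRUE)[1]]]),
       n_intersection = sum(inter))
}
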