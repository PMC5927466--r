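# Differentially enriched metabolite calling: omnibus ANOVA on log2
# relative changes, BH adjustment, and a metabolome-wide effect-size
# threshold taken as the smallest per-cell-line estimate of replicate
# spread.

#' Metabolome-wide effect-size threshold
#'
#' Estimates, per cell line, the replicate measurement spread of log2RC
#' across all metabolite-by-time groups:
#' `sigma_log2RC = sqrt(SSE / (N - 1))` where SSE sums squared deviations
#' from each metabolite-by-time cell mean over the whole matrix and N is
#' the total number of observations. The threshold is 5% of the 6-sigma
#' spread, `0.3 * sigma`, taken as the minimum over the supplied cell
#' lines, so the least noisy assay sets the bar.
#'
#' @param l2rc_list A `log2fc_matrix` or list of them (one per cell line).
#' @param factor Multiplier on sigma (default 0.3, i.e. 5% of 6 sigma).
#' @param allow_zero If `FALSE` (default), noise-free input (SSE = 0) is
#'   an error; if `TRUE` it yields threshold 0.
#' @return List of class `metabolome_threshold` with `sigma` (named per
#'   cell line) and `delta_threshold`.
#' @examples
#' st <- generate_metabolomics(30, frac_dem = 0, noise_sd = 0.15, seed = 2)
#' l2rc <- compute_log2rc(st$content, st$design)
#' metabolome_threshold(l2rc)$delta_threshold
#' @export
metabolome_threshold <- function(l2rc_list, factor = 0.3, allow_zero = FALSE) {
  if (inherits(l2rc_list, "log2fc_matrix")) l2rc_list <- list(l2rc_list)
  sigma <- vapply(l2rc_list, function(l2rc) {
    values <- l2rc$values
    N <- length(values)
    if (N < 2L) stop("need at least 2 observations", call. = FALSE)
    dec <- group_decomposition(values, l2rc$design$day)
    sqrt(sum(dec$sse) / (N - 1))
  }, numeric(1))
  names(sigma) <- vapply(seq_along(l2rc_list), function(i) {
    cl <- unique(l2rc_list[[i]]$design$cell_line)
    if (length(cl) == 1L) cl else paste0("cellline_", i)
  }, character(1))
  thr <- factor * min(sigma)
  if (thr <= 0 && !allow_zero) {
    stop("noise-free input gives a zero threshold; set allow_zero = TRUE ",
         "to accept it", call. = FALSE)
  }
  structure(list(sigma = sigma, delta_threshold = thr, factor = factor),
            class = "metabolome_threshold")
}

#' Fold-change equivalent of a log2 threshold
#'
#' The multiplicative change corresponding to a log2 effect threshold:
#' `2^delta`. A threshold of 0.20 log2 units corresponds to about a
#' 1.15-fold change.
#'
#' @param delta Log2 threshold (scalar or a `metabolome_threshold`).
#' @return `2^delta`.
#' @export
fold_change_equivalent <- function(delta) {
  if (inherits(delta, "metabolome_threshold")) delta <- delta$delta_threshold
  2^delta
}

#' Detect differentially enriched metabolites
#'
#' Omnibus one-way ANOVA across time points per metabolite (unit
#' weights), BH adjustment across metabolites, and an effect filter: the
#' per-metabolite effect is the largest absolute group-mean log2RC over
#' non-baseline days, and must reach the metabolome-wide threshold
#' (inclusive comparison). Per-day membership and direction come from
#' post hoc t tests versus day 0, as for DEGs.
#'
#' @param l2rc A `log2fc_matrix` of log2 relative changes.
#' @param threshold A `metabolome_threshold`, or a single number; 0
#'   disables the effect filter (pure BH ANOVA calls).
#' @param alpha,alpha_posthoc Significance thresholds.
#' @return A `dem_result`: list with `records` (per-metabolite table with
#'   `is_dem`, `effect`, `effect_pass`, per-day columns) and `summary`.
#' @export
detect_dems <- function(l2rc, threshold, alpha = 0.05, alpha_posthoc = 0.05) {
  if (inherits(threshold, "metabolome_threshold")) {
    threshold <- threshold$delta_threshold
  }
  omni <- anova_omnibus(l2rc, pooling = "per_gene")
  p_adj <- bh_adjust(omni$p)
  values <- l2rc$values
  design <- l2rc$design
  dec <- group_decomposition(values, design$day)
  days <- sort(unique(design$day))
  nb <- as.character(days[days != l2rc$baseline_day])
  eff_mat <- abs(dec$group_means[, nb, drop = FALSE])
  effect <- apply(eff_mat, 1, max)
  effect_pass <- effect >= threshold

  ph <- posthoc_vs_baseline(values, design, l2rc$baseline_day,
                            alpha_posthoc, labels = c("up", "down"))
  rec <- data.frame(metabolite_id = rownames(values), p_raw = omni$p,
                    p_adj = p_adj, effect = effect,
                    effect_pass = effect_pass,
                    row.names = NULL, stringsAsFactors = FALSE)
  rec$is_dem <- rec$p_adj <= alpha & rec$effect_pass
  for (d in names(ph)) {
    rec[[paste0("p_day", d)]] <- ph[[d]]$p
    rec[[paste0("dir_day", d)]] <- ph[[d]]$direction
    rec[[paste0("l2rc_day", d)]] <- ph[[d]]$diff
    rec[[paste0("dem_day", d)]] <- rec$is_dem & ph[[d]]$p < alpha_posthoc
  }
  structure(list(records = rec, threshold = threshold,
                 summary = summarize_calls(rec, "dem")),
            class = "dem_result")
}
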