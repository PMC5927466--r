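# 450K-style methylation processing: beta values from paired
# intensities, failed-read/outlier QC per probe-by-cell-by-time block,
# correlation-guided imputation of a dropped third replicate, and
# differentially methylated locus calling with per-day delta-percent-mCG.

#' Beta value from paired methylation intensities
#'
#' `beta = mCG / (mCG + CG) * 100`, the percent methylation at a probe.
#' Cells with zero total intensity are undefined and returned as `NA`
#' (treated as failed reads downstream).
#'
#' @param mcg,cg Nonnegative methylated/unmethylated intensities
#'   (vectors or matrices of equal shape).
#' @return Percent methylation in `[0, 100]`; `NA` where `mcg + cg == 0`.
#' @examples
#' compute_beta(75, 25)  # 75
#' compute_beta(1, 3)    # 25
#' @export
compute_beta <- function(mcg, cg) {
  if (any(mcg < 0, na.rm = TRUE) || any(cg < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  total <- mcg + cg
  beta <- mcg / total * 100
  beta[!is.na(total) & total == 0] <- NA_real_
  beta
}

# 1.5-IQR fence [Q1 - 1.5 IQR, Q3 + 1.5 IQR] with linear-interpolation
# quartiles (stats::quantile type 7).
iqr_fence <- function(residuals) {
  q <- stats::quantile(residuals, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' QC a single probe-by-cell-by-time replicate block
#'
#' Flags outliers as replicates whose residual around the block centre
#' (the median of non-failed replicates, so a wild replicate cannot mask
#' itself by dragging the centre) falls outside a 1.5-IQR fence, and
#' applies the
#' block rules: more than one failed read or more than one outlier
#' discards the block; otherwise the single failed/outlying replicate is
#' dropped. A block reduced from 3 to 2 survivors is marked for
#' imputation.
#'
#' The fence should be the array-wise fence computed by
#' [qc_methylation()] from residuals pooled over all blocks; with the
#' default `fence = NULL` it is computed from the block's own residuals,
#' which on three-replicate blocks is a nearly vacuous test (a fence from
#' three interpolated quartiles almost never excludes its own points).
#'
#' @param beta Numeric replicate beta values for one block.
#' @param failed Logical failed-read flags, same length.
#' @param fence Numeric `c(lower, upper)` residual fence, or `NULL`.
#' @return List with `status` (`"keep"`, `"impute_needed"`,
#'   `"discard"`), `survivors` (indices), `outlier` (logical flags).
#' @export
qc_filter <- function(beta, failed = rep(FALSE, length(beta)), fence = NULL) {
  n <- length(beta)
  if (n == 0L) stop("empty block", call. = FALSE)
  failed <- failed | is.na(beta)
  ok <- !failed
  outlier <- rep(FALSE, n)
  if (sum(ok) >= 2L) {
    res <- beta[ok] - stats::median(beta[ok])
    if (is.null(fence)) fence <- iqr_fence(res)
    eps <- 1e-6   # guards exact-replicate blocks against rounding noise
    outlier[ok] <- res < fence["lower"] - eps | res > fence["upper"] + eps
  }
  if (sum(failed) > 1L || sum(outlier) > 1L) {
    return(list(status = "discard", survivors = integer(0), outlier = outlier))
  }
  survivors <- which(ok & !outlier)
  status <- if (length(survivors) == n) "keep"
            else if (length(survivors) == 2L && n == 3L) "impute_needed"
            else if (length(survivors) >= 2L) "keep"
            else "discard"
  list(status = status, survivors = survivors, outlier = outlier)
}

#' Impute the third replicate of a two-survivor block
#'
#' The imputed value is the trimmed mean of the two survivors (their
#' midpoint) plus a residual estimate borrowed from the other
#' cell-by-time groups of the same probe: residuals of the matching
#' replicate index in context groups, combined with weights proportional
#' to the pairwise correlation between groups,
#' `r_hat = sum(rho_k * resid_k) / sum(|rho_k|)`. With no usable context
#' the plain survivor mean is returned. The result is clipped to
#' `[0, 100]`.
#'
#' @param survivors Numeric vector of the 2 surviving beta values.
#' @param context_residuals Numeric residuals of the matching replicate
#'   in other groups (may be empty).
#' @param context_correlations Correlations between the target group and
#'   each context group, aligned with `context_residuals`.
#' @return Imputed beta value in `[0, 100]`.
#' @export
impute_third <- function(survivors, context_residuals = numeric(0),
                         context_correlations = numeric(0)) {
  if (length(survivors) != 2L) {
    stop("imputation requires exactly 2 surviving replicates", call. = FALSE)
  }
  base <- mean(survivors)
  keep <- is.finite(context_residuals) & is.finite(context_correlations)
  context_residuals <- context_residuals[keep]
  context_correlations <- context_correlations[keep]
  denom <- sum(abs(context_correlations))
  r_hat <- if (length(context_residuals) == 0L || denom == 0) 0 else
    sum(context_correlations * context_residuals) / denom
  clip(base + r_hat, 0, 100)
}

#' Methylation QC: failed reads, outliers, imputation
#'
#' Converts paired intensities to beta values and applies block-level QC
#' over every probe-by-cell-by-time replicate block. Outlier fencing uses
#' residuals around block medians pooled array-wise over all blocks of the
#' dataset (a 1.5-IQR fence on that pooled residual distribution), so
#' that three-replicate blocks are judged against the array's replicate
#' noise rather than against themselves. Blocks reduced to two survivors
#' are brought back to full size by [impute_third()], using the pairwise
#' correlation matrix of cell-by-time groups computed on probes with
#' complete observed data. No background subtraction and no normalization
#' are applied at any point.
#'
#' @param study A `methylation_study` (or list with `mcg`, `cg`,
#'   `failed`, `design`).
#' @return A `methyl_qc` object: list with `beta` (probe x sample, QC'd
#'   and imputed; `NA` in discarded blocks), `provenance` (character
#'   matrix `"observed"`/`"imputed"`/`"discarded"`), `block_status` (data
#'   frame probe x group status), `fence`, `group_cor`.
#' @export
qc_methylation <- function(study) {
  design <- check_design(study$design)
  beta <- compute_beta(study$mcg, study$cg)
  failed <- study$failed | is.na(beta)
  groups <- interaction(design$cell_line, design$day, drop = TRUE, sep = "|")
  group_levels <- levels(groups)
  group_cols <- lapply(group_levels, function(g) which(groups == g))
  names(group_cols) <- group_levels

  # array-wise residual pool: per block, residuals of non-failed
  # replicates around the block centre (median, so a wild replicate
  # cannot mask itself by dragging the centre)
  resid_mat <- matrix(NA_real_, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  for (g in group_levels) {
    cols <- group_cols[[g]]
    b <- beta[, cols, drop = FALSE]
    b[failed[, cols, drop = FALSE]] <- NA
    m <- apply(b, 1, stats::median, na.rm = TRUE)
    resid_mat[, cols] <- b - m
  }
  pooled <- resid_mat[is.finite(resid_mat)]
  # each block's centre replicate sits at exactly 0; dropping that point
  # mass keeps the fence calibrated on the inter-replicate spread
  pooled <- pooled[abs(pooled) > 1e-9]
  fence <- if (length(pooled) >= 4L) iqr_fence(pooled) else c(lower = 0, upper = 0)

  provenance <- matrix("observed", nrow(beta), ncol(beta), dimnames = dimnames(beta))
  beta_qc <- beta
  status <- matrix("keep", nrow(beta), length(group_levels),
                   dimnames = list(rownames(beta), group_levels))
  dropped_idx <- matrix(NA_integer_, nrow(beta), length(group_levels),
                        dimnames = list(rownames(beta), group_levels))

  for (g in group_levels) {
    cols <- group_cols[[g]]
    for (p in seq_len(nrow(beta))) {
      qc <- qc_filter(beta[p, cols], failed[p, cols], fence = fence)
      status[p, g] <- qc$status
      if (qc$status == "discard") {
        beta_qc[p, cols] <- NA_real_
        provenance[p, cols] <- "discarded"
      } else if (length(qc$survivors) < length(cols)) {
        dropped <- setdiff(seq_along(cols), qc$survivors)
        dropped_idx[p, g] <- dropped[1]
        beta_qc[p, cols[dropped]] <- NA_real_
      }
    }
  }

  # pairwise correlation of cell-by-time group mean profiles, over
  # probes fully observed pre-QC
  complete <- rowSums(failed) == 0 & rowSums(is.na(beta)) == 0
  group_cor <- diag(length(group_levels))
  dimnames(group_cor) <- list(group_levels, group_levels)
  if (sum(complete) >= 3L) {
    profiles <- sapply(group_cols, function(cols) {
      rowMeans(beta[complete, cols, drop = FALSE])
    })
    gc <- suppressWarnings(stats::cor(profiles))
    gc[!is.finite(gc)] <- 0
    diag(gc) <- 1
    group_cor <- gc
  }

  # impute dropped third replicates
  for (g in group_levels) {
    cols <- group_cols[[g]]
    todo <- which(status[, g] == "impute_needed")
    for (p in todo) {
      r_miss <- dropped_idx[p, g]
      ctx_res <- numeric(0)
      ctx_rho <- numeric(0)
      for (k in setdiff(group_levels, g)) {
        kcols <- group_cols[[k]]
        if (r_miss > length(kcols)) next
        if (status[p, k] == "discard") next
        val <- beta_qc[p, kcols[r_miss]]
        if (!is.finite(val)) next   # replicate did not survive QC there
        ctx_res <- c(ctx_res, val - mean(beta_qc[p, kcols], na.rm = TRUE))
        ctx_rho <- c(ctx_rho, group_cor[g, k])
      }
      surv <- beta_qc[p, cols]
      surv <- surv[is.finite(surv)]
      beta_qc[p, cols[r_miss]] <- impute_third(surv, ctx_res, ctx_rho)
      provenance[p, cols[r_miss]] <- "imputed"
    }
  }

  structure(list(beta = beta_qc, provenance = provenance,
                 block_status = status, fence = fence,
                 group_cor = group_cor, design = design),
            class = "methyl_qc")
}

#' Call differentially methylated loci
#'
#' Per-probe omnibus one-way ANOVA of QC'd beta values across days, BH
#' adjustment over tested probes, post hoc equal-variance t tests of each
#' day versus day 0 (unadjusted, strict 0.05), per-day delta-percent-mCG
#' (mean beta at day d minus mean beta at day 0, percentage points) and
#' hyper/hypo directions. Probes whose baseline block was discarded, or
#' with fewer than two surviving day groups, are excluded and reported.
#'
#' @param qc A `methyl_qc` from [qc_methylation()], or a beta matrix
#'   (then `design` is required and everything is taken as observed).
#' @param probe_annot Optional probe annotation (`probe_id`, `gene_id`,
#'   `location_class`) merged into the output.
#' @param design Design data frame when `qc` is a plain matrix.
#' @param alpha BH threshold (inclusive) for the omnibus test.
#' @param alpha_posthoc Strict threshold for the per-day tests.
#' @param baseline_day Reference day (default 0).
#' @return A `dml_result`: list with `records` (per-probe table:
#'   `p_adj`, per-day `p_day<d>`, `delta_day<d>`, `dir_day<d>`
#'   hyper/hypo/none, `is_dml`, `dml_day<d>`, `gene_id`,
#'   `location_class`), `excluded` (probe ids), `by_location` (per-day
#'   significant-probe counts per location class), `summary`.
#' @export
call_dml <- function(qc, probe_annot = NULL, design = NULL,
                     alpha = 0.05, alpha_posthoc = 0.05, baseline_day = 0) {
  if (inherits(qc, "methyl_qc")) {
    beta <- qc$beta
    design <- qc$design
    observed <- qc$provenance == "observed"
  } else {
    beta <- as.matrix(qc)
    if (is.null(design)) stop("`design` required for a plain beta matrix", call. = FALSE)
    observed <- matrix(TRUE, nrow(beta), ncol(beta))
  }
  days <- sort(unique(design$day))
  nb <- days[days != baseline_day]
  base_cols <- design$day == baseline_day
  if (!any(base_cols)) stop("baseline day missing from design", call. = FALSE)

  # groups are full (observed/imputed) or entirely NA (discarded)
  day_ok <- sapply(days, function(d) {
    rowSums(is.finite(beta[, design$day == d, drop = FALSE])) >= 2L
  })
  colnames(day_ok) <- as.character(days)
  testable <- day_ok[, as.character(baseline_day)] & rowSums(day_ok) >= 2L
  excluded <- rownames(beta)[!testable]

  b <- beta[testable, , drop = FALSE]
  # omnibus ANOVA, NA-aware (absent groups drop out of the decomposition);
  # group means and sums of squares use the completed (imputed) data, but
  # only observed cells carry error degrees of freedom — an imputed
  # replicate is a function of its survivors, not new information, and
  # counting it inflates F on exactly the probes QC touched
  M <- is.finite(b)
  obs <- M & observed[testable, , drop = FALSE]
  bz <- b; bz[!M] <- 0
  grp <- factor(design$day)
  n_pg <- t(rowsum(t(M * 1), grp))                 # probe x day counts
  s_pg <- t(rowsum(t(bz), grp))                    # probe x day sums
  gm <- s_pg / ifelse(n_pg > 0, n_pg, NA)
  n_tot <- rowSums(n_pg)
  n_eff <- rowSums(t(rowsum(t(obs * 1), grp)))     # observed cells only
  grand <- rowSums(s_pg) / n_tot
  ssb <- rowSums(n_pg * (gm - grand)^2, na.rm = TRUE)
  sst <- rowSums((bz - grand)^2 * M)
  sse <- pmax(sst - ssb, 0)
  T_p <- rowSums(n_pg > 0)
  df_err <- pmax(n_eff - T_p, 1)
  F_ <- (ssb / (T_p - 1)) / (sse / df_err)
  p <- stats::pf(F_, T_p - 1, df_err, lower.tail = FALSE)
  tol <- 1e-12 * pmax(sst, 1)
  p[sst <= tol] <- 1
  p[sst > tol & sse <= tol] <- 0
  p_adj <- bh_adjust(p)

  rec <- data.frame(probe_id = rownames(b), p_raw = p, p_adj = p_adj,
                    row.names = NULL, stringsAsFactors = FALSE)
  any_sig <- rep(FALSE, nrow(b))
  day_sig <- list()
  base_mean <- rowMeans(b[, base_cols, drop = FALSE], na.rm = TRUE)
  v0 <- rowSums((b[, base_cols, drop = FALSE] - base_mean)^2, na.rm = TRUE)
  n0 <- pmax(rowSums(obs[, base_cols, drop = FALSE]), 1)
  for (d in nb) {
    cols <- design$day == d
    bd <- b[, cols, drop = FALSE]
    ndp <- rowSums(is.finite(bd))
    nde <- pmax(rowSums(obs[, cols, drop = FALSE]), 1)
    md <- rowMeans(bd, na.rm = TRUE)
    vd <- rowSums((bd - md)^2, na.rm = TRUE)
    delta <- md - base_mean
    df <- pmax(n0 + nde - 2L, 1L)
    se <- sqrt((v0 + vd) / df * (1 / n0 + 1 / nde))
    tt <- delta / se
    pd <- 2 * stats::pt(-abs(tt), df)
    zero_se <- is.finite(md) & is.finite(se) &
      se <= 1e-12 * pmax(abs(base_mean) + abs(md), 1)
    pd[zero_se] <- ifelse(abs(delta[zero_se]) <= 1e-12, 1, 0)
    pd[ndp < 2L] <- NA                              # group discarded
    delta[ndp < 2L] <- NA
    dir <- rep("none", nrow(b))
    sig <- !is.na(pd) & pd < alpha_posthoc & delta != 0
    dir[sig & delta > 0] <- "hyper"
    dir[sig & delta < 0] <- "hypo"
    rec[[paste0("p_day", d)]] <- pd
    rec[[paste0("delta_day", d)]] <- delta
    rec[[paste0("dir_day", d)]] <- dir
    day_sig[[as.character(d)]] <- sig
    any_sig <- any_sig | sig
  }
  rec$is_dml <- rec$p_adj <= alpha & any_sig
  for (d in names(day_sig)) {
    rec[[paste0("dml_day", d)]] <- rec$is_dml & day_sig[[d]]
  }
  if (!is.null(probe_annot)) {
    idx <- match(rec$probe_id, probe_annot$probe_id)
    rec$gene_id <- probe_annot$gene_id[idx]
    rec$location_class <- probe_annot$location_class[idx]
  }
  by_location <- NULL
  if (!is.null(probe_annot)) {
    by_location <- lapply(names(day_sig), function(d) {
      tab <- table(rec$location_class[rec[[paste0("dml_day", d)]]])
      as.data.frame(tab, stringsAsFactors = FALSE)
    })
    names(by_location) <- names(day_sig)
  }
  structure(list(records = rec, excluded = excluded,
                 by_location = by_location,
                 summary = summarize_dml(rec, names(day_sig))),
            class = "dml_result")
}

summarize_dml <- function(rec, days) {
  per_day <- lapply(days, function(d) {
    called <- rec[[paste0("dml_day", d)]]
    dir <- rec[[paste0("dir_day", d)]]
    list(day = d, n = sum(called),
         hyper = sum(called & dir == "hyper"),
         hypo = sum(called & dir == "hypo"))
  })
  names(per_day) <- days
  list(per_day = per_day, n_total = sum(rec$is_dml))
}
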