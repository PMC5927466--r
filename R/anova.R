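# One-way fixed-effects ANOVA kernel shared by the expression, metabolite
# and methylation callers, with an optional gene-weighted globally pooled
# error term, plus per-day post hoc t tests and BH adjustment.

# Sum-of-squares decomposition of each matrix row across groups.
# Returns SST (about the row grand mean), SSB (between groups), SSE
# (within groups), group means, group sizes.
group_decomposition <- function(values, group) {
  group <- as.factor(group)
  n_k <- as.vector(table(group))
  grand <- rowMeans(values)
  sst <- rowSums((values - grand)^2)
  totals <- t(rowsum(t(values), group))          # feature x group sums
  gm <- sweep(totals, 2, n_k, "/")               # feature x group means
  ssb <- as.vector((gm - grand)^2 %*% n_k)
  sse <- pmax(sst - ssb, 0)
  list(sst = sst, ssb = ssb, sse = sse, group_means = gm,
       group_sizes = n_k, grand_mean = grand)
}

#' Per-feature omnibus ANOVA across time groups
#'
#' Tests, for every row of a log2 fold-change matrix, whether the group
#' means differ across time points. Two error models are offered:
#'
#' * `pooling = "per_gene"` (default): the per-feature slice of the
#'   feature-by-time cell-means model, i.e. an ordinary one-way
#'   fixed-effects ANOVA per feature with
#'   `F = (SSB/(T-1)) / (SSE/(N-T))`. A constant per-feature weight
#'   cancels in this ratio, so weights are ignored here.
#' * `pooling = "global"`: the residual variance is pooled across all
#'   features as a weighted least-squares fit of the joint cell-means
#'   model, with observation weights `w_g` per feature (see
#'   [compute_weights()]). Each feature's time-effect mean square
#'   `w_g * SSB_g / (T-1)` is tested against the pooled weighted error
#'   mean square on `G * (N - T)` degrees of freedom. This is where the
#'   sequencing-representation weights become consequential.
#'
#' Features whose values are identical in all samples have no testable
#' effect and receive `p = 1` by convention. Features with zero
#' within-group variance but distinct group means receive `p = 0`.
#'
#' @param l2fc A `log2fc_matrix` from [compute_log2fc()] /
#'   [compute_log2rc()], or a plain matrix (then `design` is required).
#' @param weights Optional data frame from [compute_weights()] (or a
#'   numeric vector aligned with rows). Only used with global pooling;
#'   `NULL` means unit weights.
#' @param pooling `"per_gene"` or `"global"`.
#' @param design Design data frame; taken from `l2fc` when absent.
#' @return Data frame with `feature_id`, `F`, `p`, `ssb`, `sse`, `sst`.
#' @export
anova_omnibus <- function(l2fc, weights = NULL,
                          pooling = c("per_gene", "global"),
                          design = NULL) {
  pooling <- match.arg(pooling)
  if (inherits(l2fc, "log2fc_matrix")) {
    values <- l2fc$values
    design <- l2fc$design
  } else {
    values <- as.matrix(l2fc)
    if (is.null(design)) stop("`design` required for a plain matrix", call. = FALSE)
  }
  group <- factor(design$day)
  n_k <- table(group)
  T_ <- nlevels(group)
  N <- ncol(values)
  if (T_ < 2L) stop("need at least 2 time groups", call. = FALSE)
  if (pooling == "per_gene" && any(n_k < 2L)) {
    stop("every time group needs >= 2 replicates under per-gene pooling",
         call. = FALSE)
  }
  dec <- group_decomposition(values, group)

  tol <- 1e-12 * pmax(dec$sst, 1)
  if (pooling == "per_gene") {
    msb <- dec$ssb / (T_ - 1)
    mse <- dec$sse / (N - T_)
    F_ <- msb / mse
    p <- stats::pf(F_, T_ - 1, N - T_, lower.tail = FALSE)
    degen_flat <- dec$sst <= tol              # identical everywhere
    p[degen_flat] <- 1
    F_[degen_flat] <- 0
    degen_sep <- !degen_flat & dec$sse <= tol # perfect separation
    p[degen_sep] <- 0
    F_[degen_sep] <- Inf
  } else {
    w <- extract_weights(weights, rownames(values), nrow(values))
    mse_pool <- sum(w * dec$sse) / (nrow(values) * (N - T_))
    if (mse_pool <= 0) stop("zero pooled residual variance", call. = FALSE)
    F_ <- (w * dec$ssb / (T_ - 1)) / mse_pool
    p <- stats::pf(F_, T_ - 1, nrow(values) * (N - T_), lower.tail = FALSE)
  }
  data.frame(feature_id = rownames(values), F = F_, p = p,
             ssb = dec$ssb, sse = dec$sse, sst = dec$sst,
             row.names = NULL, stringsAsFactors = FALSE)
}

extract_weights <- function(weights, ids, n) {
  if (is.null(weights)) return(rep(1, n))
  if (is.data.frame(weights)) {
    w <- weights$weight[match(ids, weights$gene_id)]
  } else {
    w <- as.numeric(weights)
  }
  if (length(w) != n || anyNA(w)) {
    stop("weights do not align with the feature rows", call. = FALSE)
  }
  w
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' (`p_adj(i) = min_{j >= i} m/rank_j * p_(j)`, capped at 1), delegated to
#' [stats::p.adjust()] after validating the input range.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Equal-variance two-sample t tests of each non-baseline day versus the
# baseline day, vectorised over matrix rows. Returns, per day, matrices of
# p-values, mean differences and directions.
posthoc_vs_baseline <- function(values, design, baseline_day = 0,
                                alpha_posthoc = 0.05,
                                labels = c("up", "down")) {
  days <- sort(unique(design$day))
  days <- days[days != baseline_day]
  base_cols <- design$day == baseline_day
  n0 <- sum(base_cols)
  y0 <- values[, base_cols, drop = FALSE]
  m0 <- rowMeans(y0)
  v0 <- rowSums((y0 - m0)^2)
  out <- list()
  for (d in days) {
    cols <- design$day == d
    nd <- sum(cols)
    if (nd < 2L || n0 < 2L) stop("day group with < 2 replicates", call. = FALSE)
    yd <- values[, cols, drop = FALSE]
    md <- rowMeans(yd)
    vd <- rowSums((yd - md)^2)
    df <- n0 + nd - 2L
    sp2 <- (v0 + vd) / df
    se <- sqrt(sp2 * (1 / n0 + 1 / nd))
    diff <- md - m0
    tt <- diff / se
    p <- 2 * stats::pt(-abs(tt), df)
    zero_se <- se <= 1e-12 * pmax(abs(m0) + abs(md), 1)
    p[zero_se] <- ifelse(abs(diff[zero_se]) <= 1e-12, 1, 0)
    dir <- rep("none", nrow(values))
    sig <- p < alpha_posthoc & diff != 0
    dir[sig & diff > 0] <- labels[1]
    dir[sig & diff < 0] <- labels[2]
    out[[as.character(d)]] <- list(p = p, diff = diff, direction = dir)
  }
  out
}
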