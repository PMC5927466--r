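# Log2 fold/relative change relative to the baseline-day mean.
#
# The same kernel serves expression (log2FC of RPKM) and metabolomics
# (log2RC of abundance): each feature is expressed as log2 of its value
# over that feature's mean at the baseline day, after an additive floor
# that keeps zero measurements finite.

#' Log2 fold change versus the baseline-day mean
#'
#' Converts a nonnegative feature-by-sample matrix into log2 fold changes
#' relative to each feature's mean at the baseline day:
#' `log2((x + floor) / mean(x[baseline] + floor))`. An additive floor
#' (default 0.01, on the measurement scale) keeps zero values finite
#' without dropping features.
#'
#' @param x Numeric feature-by-sample matrix, all values `>= 0`. Column
#'   names must match `design$sample_id`.
#' @param design Data frame with columns `sample_id`, `cell_line`, `day`,
#'   `replicate`.
#' @param baseline_day Day used as the reference (default 0).
#' @param floor Additive floor applied before taking logs (default 0.01).
#'   With `floor = 0`, features that are all zero at baseline are an error.
#' @return An object of class `log2fc_matrix`: a list with `values` (same
#'   shape as `x`), `design`, `baseline_day` and `floor`.
#' @examples
#' d <- data.frame(sample_id = c("a", "b", "c", "d"),
#'                 cell_line = "DN-POLG", day = c(0, 0, 3, 3),
#'                 replicate = c(1, 2, 1, 2))
#' x <- matrix(c(4, 4, 8, 8), 1, dimnames = list("g1", d$sample_id))
#' compute_log2fc(x, d, floor = 0)$values   # 0 0 1 1
#' @export
compute_log2fc <- function(x, design, baseline_day = 0, floor = 0.01) {
  check_design(design)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(x < 0)) stop("input matrix must be nonnegative", call. = FALSE)
  if (is.null(colnames(x)) || !setequal(colnames(x), design$sample_id)) {
    stop("column names of `x` must match design$sample_id", call. = FALSE)
  }
  x <- x[, design$sample_id, drop = FALSE]
  base_cols <- design$day == baseline_day
  if (!any(base_cols)) {
    stop("baseline day ", baseline_day, " not present in design", call. = FALSE)
  }
  xf <- x + floor
  base_mean <- rowMeans(xf[, base_cols, drop = FALSE])
  if (any(base_mean <= 0)) {
    stop("feature with zero baseline mean and floor = 0; raise `floor`",
         call. = FALSE)
  }
  values <- log2(xf / base_mean)
  structure(
    list(values = values, design = design,
         baseline_day = baseline_day, floor = floor),
    class = "log2fc_matrix"
  )
}

#' Log2 relative change for metabolite abundances
#'
#' Alias of [compute_log2fc()] on the metabolite scale: log2 of each
#' metabolite's abundance over its baseline-day mean. Abundances are
#' strictly positive vendor-style detection units, so the default floor
#' is 0; a positive floor is available for non-detects coded as 0.
#'
#' @inheritParams compute_log2fc
#' @return A `log2fc_matrix` object (values are log2RC).
#' @export
compute_log2rc <- function(x, design, baseline_day = 0, floor = 0) {
  compute_log2fc(x, design, baseline_day = baseline_day, floor = floor)
}

#' @export
print.log2fc_matrix <- function(x, ...) {
  cat(sprintf("log2 fold-change matrix: %d features x %d samples (baseline day %s, floor %g)\n",
              nrow(x$values), ncol(x$values), x$baseline_day, x$floor))
  invisible(x)
}
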