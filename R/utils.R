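# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Integer rounding used for reported percentages. `base::round()` rounds
#' half to even; published-style percentages round half away from zero.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @keywords internal
#' @noRd
stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Clip a numeric vector/matrix into [lo, hi] preserving dim.
clip <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Derive a reproducible per-stage seed (< 2^31) from a base seed and a
# stage name, so stages can be re-run in isolation.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

# Validate a design data.frame (sample_id, cell_line, day, replicate).
check_design <- function(design) {
  req <- c("sample_id", "cell_line", "day", "replicate")
  missing <- setdiff(req, names(design))
  if (length(missing)) {
    stop("design is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("design sample_id values must be unique", call. = FALSE)
  }
  invisible(design)
}
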