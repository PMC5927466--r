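# Shared fixture builders for the test suite. Everything is generated in
# code; no files on disk.

# Minimal design: one cell line, given days, n replicates each.
toy_design <- function(days = c(0, 3, 6, 9), n_reps = 3, cell_line = "DN-POLG") {
  grid <- expand.grid(replicate = seq_len(n_reps), day = days)
  data.frame(
    sample_id = sprintf("s_d%d_r%d", grid$day, grid$replicate),
    cell_line = cell_line,
    day = as.integer(grid$day),
    replicate = as.integer(grid$replicate),
    stringsAsFactors = FALSE
  )
}

# Wrap a plain matrix as a log2fc_matrix (values already on log2 scale).
as_l2fc <- function(values, design, baseline_day = 0, floor = 0) {
  colnames(values) <- design$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  }
  structure(list(values = values, design = design,
                 baseline_day = baseline_day, floor = floor),
            class = "log2fc_matrix")
}

# Independent one-way ANOVA oracle: p-value per row via stats::lm/anova.
anova_oracle_p <- function(values, group) {
  apply(values, 1, function(y) {
    stats::anova(stats::lm(y ~ factor(group)))[["Pr(>F)"]][1]
  })
}

# Planted feature ids (any nonzero truth entry).
planted_ids <- function(study) {
  rownames(study$truth)[rowSums(study$truth != 0) > 0]
}

# Sensitivity and observed FDR of a call set against truth.
recovery <- function(called, truth_pos) {
  list(sensitivity = mean(truth_pos %in% called),
       fdr = if (length(called) > 0) mean(!(called %in% truth_pos)) else 0)
}
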