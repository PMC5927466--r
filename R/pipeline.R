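# End-to-end driver: configuration, design validation, simulate ->
# deg/dem/dml -> integrate, artifact writing and a structured run report.

#' Pipeline configuration
#'
#' Collects every tunable the downstream stages read: the top-level seed
#' (fanned out to per-stage seeds by a stage-name hash so stages can be
#' re-run in isolation), significance thresholds, the log floor, effect
#' modes, promoter classes, concordance convention, layer toggles and
#' simulation sizes. Serializes to YAML and round-trips losslessly.
#'
#' @param seed Top-level integer seed.
#' @param alpha,alpha_posthoc Significance thresholds shared by stages.
#' @param floor Additive RPKM floor before log2.
#' @param weights,pooling,effect_mode DEG-stage options, see
#'   [detect_degs()].
#' @param promoter_classes Location classes counted as promoter.
#' @param concordance_convention See [concordance()].
#' @param layers Character subset of `c("expression", "metabolomics",
#'   "methylation")` to run.
#' @param sim Named list of simulation sizes/levels passed to the
#'   generators (`n_genes`, `frac_deg`, `effect_sd`, `noise_sd`,
#'   `n_metab`, `frac_dem`, `met_effect_sd`, `met_noise_sd`, `n_probes`,
#'   `frac_dml`, `delta_beta`, `fail_rate`, `outlier_rate`,
#'   `meth_noise_sd`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.05, alpha_posthoc = 0.05,
                            floor = 0.01,
                            weights = "hazard", pooling = "per_gene",
                            effect_mode = "as_written",
                            promoter_classes = PROMOTER_CLASSES_DEFAULT,
                            concordance_convention = "promoter_inverse",
                            layers = c("expression", "metabolomics", "methylation"),
                            sim = list()) {
  sim_defaults <- list(n_genes = 500L, frac_deg = 0.2, effect_sd = 2,
                       noise_sd = 0.25, n_metab = 200L, frac_dem = 0.25,
                       met_effect_sd = 0.6, met_noise_sd = 0.15,
                       n_probes = 1000L, frac_dml = 0.1, delta_beta = 20,
                       fail_rate = 0.02, outlier_rate = 0.01,
                       meth_noise_sd = 2)
  sim <- utils::modifyList(sim_defaults, sim)
  structure(list(seed = as.integer(seed), alpha = alpha,
                 alpha_posthoc = alpha_posthoc, floor = floor,
                 weights = weights, pooling = pooling,
                 effect_mode = effect_mode,
                 promoter_classes = promoter_classes,
                 concordance_convention = concordance_convention,
                 layers = layers, sim = sim),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "sim")])
  cfg$sim <- utils::modifyList(cfg$sim, raw$sim %||% list())
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate design tables across omic layers
#'
#' Checks that every layer's design has unique sample ids, includes the
#' baseline day, shares a common day grid and has at least two replicates
#' per cell-line-by-day group.
#'
#' @param designs Named list of design data frames.
#' @param baseline_day Baseline day every layer must contain.
#' @return List with `ok` (logical) and `violations` (character vector).
#' @export
validate_design <- function(designs, baseline_day = 0) {
  if (!length(designs)) stop("need at least one design", call. = FALSE)
  if (is.null(names(designs))) names(designs) <- paste0("layer", seq_along(designs))
  violations <- character(0)
  grids <- lapply(designs, function(d) sort(unique(d$day)))
  for (nm in names(designs)) {
    d <- designs[[nm]]
    miss <- setdiff(c("sample_id", "cell_line", "day", "replicate"), names(d))
    if (length(miss)) {
      violations <- c(violations, sprintf("%s: missing columns %s", nm,
                                          paste(miss, collapse = ",")))
      next
    }
    if (anyDuplicated(d$sample_id)) {
      violations <- c(violations, sprintf("%s: duplicate sample_id", nm))
    }
    if (!baseline_day %in% d$day) {
      violations <- c(violations, sprintf("%s: baseline day %s absent", nm,
                                          baseline_day))
    }
    reps <- table(d$cell_line, d$day)
    if (any(reps[reps > 0] < 2)) {
      violations <- c(violations, sprintf("%s: a cell-line x day group has < 2 replicates", nm))
    }
  }
  if (length(grids) > 1L &&
      !all(vapply(grids[-1], identical, logical(1), grids[[1]]))) {
    violations <- c(violations, "layers disagree on the day grid")
  }
  list(ok = length(violations) == 0L, violations = violations)
}

#' Run the full synthetic tri-omic pipeline
#'
#' Simulates the enabled layers from per-stage seeds derived from the
#' config seed, runs DEG/DEM/DML detection, and — when both expression
#' and methylation are enabled — integrates them (per-day DMEG counts,
#' the DEG-by-promoter-methylation odds ratio, and sign concordance).
#' All stage tables are written under `out_dir` before the report, and
#' identical config + seed reproduce the report exactly.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory for stage artifacts (`NULL` skips
#'   writing).
#' @return A `run_report`: nested list of per-stage counts, DMEG counts
#'   and percentages, contingency and concordance results, and the
#'   config fingerprint.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  s <- config$sim
  report <- list(config_fingerprint = config_fingerprint(config))
  artifacts <- list()
  days_nb <- c(3, 6, 9)

  annot <- generate_annotation(max(10L, ceiling(s$n_genes)),
                               seed = stage_seed(config$seed, "annotation"))

  deg_res <- dem_res <- dml_res <- NULL
  designs <- list()

  if ("expression" %in% config$layers) {
    expr <- generate_expression(s$n_genes, s$frac_deg, s$effect_sd,
                                s$noise_sd,
                                seed = stage_seed(config$seed, "expression"))
    designs$expression <- expr$design
    deg_res <- detect_degs(expr, alpha = config$alpha,
                           alpha_posthoc = config$alpha_posthoc,
                           weights = config$weights,
                           pooling = config$pooling,
                           effect_mode = config$effect_mode,
                           floor = config$floor)
    report$deg <- stage_counts(deg_res$summary)
    artifacts$expr <- expr
  }
  if ("metabolomics" %in% config$layers) {
    met <- generate_metabolomics(s$n_metab, s$frac_dem, s$met_effect_sd,
                                 s$met_noise_sd,
                                 seed = stage_seed(config$seed, "metabolomics"))
    designs$metabolomics <- met$design
    l2rc <- compute_log2rc(met$content, met$design)
    thr <- metabolome_threshold(l2rc)
    dem_res <- detect_dems(l2rc, thr, alpha = config$alpha,
                           alpha_posthoc = config$alpha_posthoc)
    report$dem <- stage_counts(dem_res$summary)
    report$dem$delta_threshold <- thr$delta_threshold
    artifacts$met <- met
  }
  if ("methylation" %in% config$layers) {
    meth <- generate_methylation(s$n_probes, s$frac_dml, s$delta_beta,
                                 s$fail_rate, s$outlier_rate,
                                 s$meth_noise_sd, annot = annot,
                                 seed = stage_seed(config$seed, "methylation"))
    designs$methylation <- meth$design
    qc <- qc_methylation(meth)
    dml_res <- call_dml(qc, probe_annot = meth$probe_annot,
                        alpha = config$alpha,
                        alpha_posthoc = config$alpha_posthoc)
    report$dml <- list(per_day = dml_res$summary$per_day,
                       n_total = dml_res$summary$n_total,
                       n_excluded = length(dml_res$excluded))
    artifacts$meth <- meth
    artifacts$qc <- qc
  }

  verdict <- validate_design(designs)
  if (!verdict$ok) {
    stop("inconsistent designs across layers: ",
         paste(verdict$violations, collapse = "; "), call. = FALSE)
  }

  if (!is.null(deg_res) && !is.null(dml_res)) {
    integration <- list()
    prom_any <- character(0)
    for (d in days_nb) {
      summ <- summarize_gene_methylation(dml_res, d,
                                         promoter_classes = config$promoter_classes)
      dmeg <- count_dmegs(deg_res, summ, d)
      conc <- concordance(deg_res, summ, d, scope = "promoter",
                          convention = config$concordance_convention)
      integration[[as.character(d)]] <-
        list(n_deg = dmeg$n_deg, n_dmeg = dmeg$n_dmeg, pct = dmeg$pct,
             concordance = conc$fraction)
      prom_any <- union(prom_any, summ$gene_id[summ$has_promoter_dml])
    }
    deg_any <- deg_res$records$gene_id[deg_res$records$is_deg]
    universe <- annot$gene_id
    assoc <- deg_dml_association(intersect(deg_any, universe),
                                 intersect(prom_any, universe), universe)
    report$integration <- list(
      per_day = integration,
      n_dmeg_total = sum(deg_any %in% prom_any),
      pct_dmeg_total = if (length(deg_any) > 0)
        count_dmegs_fraction(sum(deg_any %in% prom_any), length(deg_any))
        else NA_real_,
      contingency = unclass(assoc))
  }

  if (!is.null(out_dir)) {
    write_artifacts(artifacts, deg_res, dem_res, dml_res, annot,
                    report, out_dir)
  }
  structure(report, class = "run_report")
}

stage_counts <- function(summary) {
  list(per_day = summary$per_day, n_total = summary$n_deg_total,
       n_intersection = summary$n_intersection)
}

config_fingerprint <- function(config) {
  flat <- unlist(unclass(config))
  paste0("cfg-", sum(utf8ToInt(paste(names(flat), flat, collapse = ";"))))
}

write_artifacts <- function(artifacts, deg_res, dem_res, dml_res, annot,
                            report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_bed6(annot, file.path(out_dir, "genes.bed"))
  if (!is.null(artifacts$expr)) {
    write_matrix_tsv(artifacts$expr$rpkm, file.path(out_dir, "rpkm.tsv"))
    write_table_tsv(artifacts$expr$design, file.path(out_dir, "design_expression.tsv"))
    write_table_tsv(deg_res$records, file.path(out_dir, "deg.tsv"))
  }
  if (!is.null(artifacts$met)) {
    write_matrix_tsv(artifacts$met$content, file.path(out_dir, "metabolites.tsv"))
    write_table_tsv(artifacts$met$design, file.path(out_dir, "design_metabolomics.tsv"))
    write_table_tsv(dem_res$records, file.path(out_dir, "dem.tsv"))
  }
  if (!is.null(artifacts$meth)) {
    write_matrix_tsv(artifacts$meth$mcg, file.path(out_dir, "mcg.tsv"))
    write_matrix_tsv(artifacts$meth$cg, file.path(out_dir, "cg.tsv"))
    write_matrix_tsv(artifacts$qc$beta, file.path(out_dir, "beta.tsv"))
    write_table_tsv(artifacts$meth$probe_annot, file.path(out_dir, "probe_annot.tsv"))
    write_table_tsv(dml_res$records, file.path(out_dir, "dml.tsv"))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("tri-omic pipeline report\n")
  for (stage in intersect(c("deg", "dem", "dml"), names(x))) {
    cat(sprintf("  %s: %d total\n", stage, x[[stage]]$n_total))
  }
  if (!is.null(x$integration)) {
    cat(sprintf("  DMEG: %d (%s%% of DEGs), OR = %.3f\n",
                x$integration$n_dmeg_total,
                format(x$integration$pct_dmeg_total),
                x$integration$contingency$odds_ratio))
  }
  invisible(x)
}
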