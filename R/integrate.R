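# Cross-referencing methylation with expression: gene-level methylation
# summaries, differentially methylated DEG (DMEG) counts, the DEG-by-
# promoter-methylation odds ratio with chi-squared test, and sign
# concordance between methylation change and expression direction.

PROMOTER_CLASSES_DEFAULT <- c("TSS1500", "TSS200")
BODY_CLASSES_DEFAULT <- c("Body", "1stExon")

#' Gene-level methylation change summaries for one day
#'
#' Averages per-day delta-percent-mCG of a gene's significant probes
#' into promoter, gene-body and gene-overall summaries. Promoter probes
#' are the array's TSS1500/TSS200 classes by default; body probes are
#' Body and 1st exon; the overall summary averages all probes inside the
#' gene, its untranslated regions and its promoter (everything but
#' intergenic probes). A probe counts as significant at a day when its
#' per-day direction is hyper or hypo (i.e. its pairwise test passed).
#'
#' @param dml A `dml_result` (with annotated records) or its `records`
#'   data frame.
#' @param day Day to summarize (e.g. 3, 6 or 9).
#' @param promoter_classes,body_classes Location classes counted as
#'   promoter / gene body.
#' @return Data frame with `gene_id`, `promoter_delta`, `body_delta`,
#'   `overall_delta` (`NA` when no qualifying probe), `has_promoter_dml`.
#'   Genes with no significant probe at that day are absent.
#' @export
summarize_gene_methylation <- function(dml, day,
                                       promoter_classes = PROMOTER_CLASSES_DEFAULT,
                                       body_classes = BODY_CLASSES_DEFAULT) {
  rec <- if (inherits(dml, "dml_result")) dml$records else dml
  dcol <- paste0("dir_day", day)
  vcol <- paste0("delta_day", day)
  if (!all(c(dcol, vcol, "gene_id", "location_class") %in% names(rec))) {
    stop("records lack annotated per-day columns for day ", day, call. = FALSE)
  }
  sig <- rec[!is.na(rec$gene_id) & rec[[dcol]] != "none", , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(gene_id = character(0), promoter_delta = numeric(0),
                      body_delta = numeric(0), overall_delta = numeric(0),
                      has_promoter_dml = logical(0), stringsAsFactors = FALSE))
  }
  overall_classes <- union(union(promoter_classes, body_classes),
                           c("5UTR", "3UTR"))
  scope_mean <- function(classes) {
    sub <- sig[sig$location_class %in% classes, , drop = FALSE]
    tapply(sub[[vcol]], sub$gene_id, mean)
  }
  prom <- scope_mean(promoter_classes)
  body <- scope_mean(body_classes)
  over <- scope_mean(overall_classes)
  genes <- sort(unique(sig$gene_id))
  data.frame(
    gene_id = genes,
    promoter_delta = as.numeric(prom[genes]),
    body_delta = as.numeric(body[genes]),
    overall_delta = as.numeric(over[genes]),
    has_promoter_dml = genes %in% names(prom),
    stringsAsFactors = FALSE
  )
}

#' Differentially methylated DEG counts for one day
#'
#' Counts that day's DEGs whose promoter carries a significant
#' methylation change at the same day, and reports the percentage of the
#' day's DEGs (rounded to the nearest integer, half away from zero).
#'
#' @param degs A `deg_result` or its `records` data frame.
#' @param summaries Output of [summarize_gene_methylation()] for `day`,
#'   or a character vector of gene ids with a promoter DML at that day.
#' @param day Day to evaluate.
#' @return List with `n_deg`, `n_dmeg`, `pct` (NA when there are no DEGs
#'   at that day).
#' @examples
#' count_dmegs_fraction(63, 236)   # 27
#' @export
count_dmegs <- function(degs, summaries, day) {
  rec <- if (inherits(degs, "deg_result")) degs$records else degs
  dcol <- paste0("deg_day", day)
  if (!dcol %in% names(rec)) stop("no DEG calls for day ", day, call. = FALSE)
  deg_genes <- rec$gene_id[rec[[dcol]]]
  prom_genes <- if (is.character(summaries)) summaries else
    summaries$gene_id[summaries$has_promoter_dml]
  n_deg <- length(deg_genes)
  n_dmeg <- sum(deg_genes %in% prom_genes)
  list(n_deg = n_deg, n_dmeg = n_dmeg,
       pct = if (n_deg > 0) count_dmegs_fraction(n_dmeg, n_deg) else NA_real_)
}

#' DMEG percentage from counts
#'
#' `100 * n_dmeg / n_deg`, rounded to the nearest integer (half away
#' from zero) — the published-style percentage.
#'
#' @param n_dmeg,n_deg Counts.
#' @return Integer-valued percentage.
#' @export
count_dmegs_fraction <- function(n_dmeg, n_deg) {
  as.numeric(round_half_up(100 * n_dmeg / n_deg))
}

#' DEG-by-promoter-methylation association
#'
#' Builds the 2x2 table over the gene universe — differentially
#' expressed or not, against carrying a promoter methylation change or
#' not — and reports the odds ratio `(a d) / (b c)` (with a
#' Haldane-Anscombe +0.5 on every cell when any cell is zero) and the
#' Pearson chi-squared test without continuity correction (df = 1).
#'
#' @param deg_genes Character vector of DEG gene ids (any day).
#' @param dml_genes Character vector of gene ids with a promoter DML.
#' @param universe Character vector of all genes considered.
#' @return List of class `contingency_result`: `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `chi2`, `p`.
#' @export
deg_dml_association <- function(deg_genes, dml_genes, universe) {
  if (!all(deg_genes %in% universe) || !all(dml_genes %in% universe)) {
    stop("universe must contain every DEG and DML gene", call. = FALSE)
  }
  deg <- universe %in% deg_genes
  dml <- universe %in% dml_genes
  a <- sum(deg & dml); b <- sum(deg & !dml)
  c_ <- sum(!deg & dml); d <- sum(!deg & !dml)
  cells <- c(a, b, c_, d)
  or_cells <- if (any(cells == 0)) cells + 0.5 else cells
  odds_ratio <- (or_cells[1] * or_cells[4]) / (or_cells[2] * or_cells[3])
  tab <- matrix(cells, 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(a = a, b = b, c = c_, d = d, odds_ratio = odds_ratio,
                 chi2 = unname(ct$statistic), p = unname(ct$p.value)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 DEG x promoter-DML: a=%d b=%d c=%d d=%d  OR=%.3f  chi2=%.3f  p=%.3g\n",
              x$a, x$b, x$c, x$d, x$odds_ratio, x$chi2, x$p))
  invisible(x)
}

#' Methylation-expression sign concordance for one day
#'
#' Places each gene that has both an expression direction at the day and
#' a nonzero methylation change (in the chosen scope) into one of four
#' sign quadrants, and reports the concordant fraction. Under the
#' `promoter_inverse` convention — the classical regulatory expectation
#' for promoters — hypomethylation with upregulation and
#' hypermethylation with downregulation count as concordant; under
#' `same_sign`, matching signs count.
#'
#' @param degs A `deg_result` or its `records`.
#' @param summaries Output of [summarize_gene_methylation()] for `day`.
#' @param day Day to evaluate.
#' @param scope `"promoter"`, `"body"` or `"overall"` methylation summary.
#' @param convention `"promoter_inverse"` or `"same_sign"`.
#' @return List of class `concordance_result`: `quadrants` (named counts
#'   hyper_up, hyper_down, hypo_up, hypo_down), `n`, `concordant`,
#'   `fraction` (`NA` when no eligible gene).
#' @export
concordance <- function(degs, summaries, day,
                        scope = c("promoter", "body", "overall"),
                        convention = c("promoter_inverse", "same_sign")) {
  scope <- match.arg(scope)
  convention <- match.arg(convention)
  rec <- if (inherits(degs, "deg_result")) degs$records else degs
  dcol <- paste0("dir_day", day)
  vcol <- paste0(scope, "_delta")
  idx <- match(rec$gene_id, summaries$gene_id)
  delta <- summaries[[vcol]][idx]
  dir <- rec[[dcol]]
  eligible <- dir %in% c("up", "down") & !is.na(delta) & delta != 0
  up <- dir[eligible] == "up"
  hyper <- delta[eligible] > 0
  quadrants <- c(hyper_up = sum(hyper & up), hyper_down = sum(hyper & !up),
                 hypo_up = sum(!hyper & up), hypo_down = sum(!hyper & !up))
  n <- sum(eligible)
  concordant <- if (convention == "promoter_inverse") {
    quadrants["hypo_up"] + quadrants["hyper_down"]
  } else {
    quadrants["hyper_up"] + quadrants["hypo_down"]
  }
  structure(list(quadrants = quadrants, n = n,
                 concordant = unname(concordant),
                 fraction = if (n > 0) unname(concordant) / n else NA_real_,
                 scope = scope, convention = convention),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance (%s, %s): %d/%d = %s\n", x$scope, x$convention,
              x$concordant, x$n,
              if (is.na(x$fraction)) "NA" else sprintf("%.2f", x$fraction)))
  invisible(x)
}
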