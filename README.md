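# triomics

Differential analysis and integration of multi-omic time courses in
isogenic cell models — expression, metabolomics and DNA methylation
measured over a shared day grid (0, 3, 6, 9), as in inducible
mitochondrial-DNA depletion experiments where all three layers remodel
progressively.

For computational biologists who have (or want to simulate) a gene ×
sample RPKM matrix, a metabolite abundance matrix and paired 450K-style
methylation intensities with a common replicate design, and who want the
per-layer differential calls plus the methylation–expression
integration, reproducibly and with measurable error rates.

## What it computes

**DEGs.** Per gene, log2 fold change versus the day-0 mean
(`log2FC = log2((x + c) / mean(x_day0 + c))`, floor `c = 0.01` RPKM),
one-way ANOVA across time groups (the per-gene slice of the gene × time
cell-means model, or a globally pooled weighted-least-squares variant in
which per-gene sequencing-representation weights — the cumulative hazard
of exponential-rate significance scores — become consequential),
Benjamini–Hochberg adjustment at `p_adj ≤ 0.05`, a gene-wise effect-size
filter comparing `0.3·σ_SSR` against `0.3·σ_log2FC` (i.e. SST vs SSE),
and per-day Student t tests versus day 0 (`p < 0.05`) that assign
up/down directions.

**DEMs.** The same machinery on log2 relative changes of metabolite
abundances, with a metabolome-wide effect threshold
`0.3 × min over cell lines of sqrt(SSE_log2RC/(N−1))`; a threshold of
0.20 log2 units is a `2^0.20 ≈ 1.15`-fold change.

**DMLs.** Probe `β = mCG/(mCG+CG) × 100`; block QC (discard on >1
failed read or >1 outlier by a 1.5-IQR fence on residuals around block
medians, pooled array-wise), imputation of dropped third replicates from
the survivor midpoint adjusted by correlation-weighted residuals of
other cell × time groups; per-probe ANOVA across days (imputed cells
carry no error degrees of freedom), BH, post hoc t tests, per-day
`Δ%mCG` with hyper/hypo directions by location class.

**Integration.** Per-day differentially methylated DEG (DMEG) counts
and percentages, the DEG × promoter-methylation 2×2 odds ratio
(Haldane–Anscombe corrected) with Pearson chi-squared, and sign
concordance between methylation change and expression direction
(promoter-inverse or same-sign convention).

**Synthetic data.** Generators plant per-day effects on known feature
subsets at the design's sample sizes (N = 3 expression/methylation,
N = 4 metabolomics), with log-scale replicate noise, failed probe reads
and displaced outlier replicates, so sensitivity and observed FDR are
measurable without any external data.

## Worked example

```r
library(triomics)

st  <- generate_expression(500, frac_deg = 0.2, effect_sd = 2,
                           noise_sd = 0.25, seed = 42)
res <- detect_degs(st)

res$summary$per_day[["3"]]
#> $day
#> [1] "3"
#> $n
#> [1] 47
#> $up
#> [1] 30
#> $down
#> [1] 17
#> $pct_up
#> [1] 64

res$summary$n_deg_total      # 101 DEGs across the time course
res$summary$n_intersection   # 25 DEGs common to all three days

truth  <- rownames(st$truth)[rowSums(st$truth != 0) > 0]
called <- res$records$gene_id[res$records$is_deg]
mean(truth %in% called)          # sensitivity 1
mean(!(called %in% truth))       # observed FDR 0.01
```

Of the 500 simulated genes, 100 carry planted log2 shifts of magnitude 2
over contiguous day runs; 47 genes are called at day 3 (30 up, 17 down),
101 in total, and against the known truth the caller recovers every
planted gene with one false positive.

The full pipeline — simulate all three layers, call DEGs/DEMs/DMLs,
integrate — runs from one config:

```r
report <- run_pipeline(pipeline_config(seed = 11), out_dir = "run1")
report   # per-stage counts, DMEG percentages, odds ratio, concordance
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`
(`--config config.yaml --seed N --out DIR`).

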