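Package: triomics
Title: Tri-Omic Time-Course Differential Analysis and Methylation-Expression Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential analysis of multi-omic time courses in isogenic cell
    models: weighted ANOVA detection of differentially expressed genes from
    RPKM matrices with an SSR/SSE effect-size filter and per-day post hoc
    tests; differentially enriched metabolite calling on log2 relative changes
    with a metabolome-wide effect threshold; 450K-style methylation QC
    (failed-read and IQR outlier filtering, correlation-guided imputation),
    beta-value computation and differentially methylated locus calling; and
    integration of methylation with expression (differentially methylated DEG
    counts, odds ratios, sign concordance). Includes a synthetic-data
    generator with planted effects so the whole pipeline is testable end to
    end without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
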