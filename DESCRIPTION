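Package: zratioDS
Title: Z-Ratio Differential Expression Analysis of Trisomy 21 Brain
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Z-score / Z-ratio differential expression
    statistic for microarray-style log2 intensity data, with per-array
    standardization, +/-3 winsorization, group-mean contrasts and a 1.96
    over-expression call rule. Provides readers for the GEO series-matrix
    dialect and plain TSV matrices, per-chromosome and per-brain-structure
    enrichment summaries, cross-stratum squared Pearson correlation of
    Z-ratio profiles, paired Wilcoxon signed-rank and t tests, a seeded
    synthetic trisomy-21 gene-dosage data generator with ground-truth
    labels for calibration and recovery studies, and a deterministic
    end-to-end pipeline built on SummarizedExperiment containers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
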