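---
title: "Quantifying transcriptome-wide over-expression in trisomy 21 brain: methods and design"
author: "zratioDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptome-wide over-expression in trisomy 21 brain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zratioDS)
```

## The scientific problem

Down syndrome (trisomy 21) triples the copy number of every chromosome-21
gene, yet its neurophenotype cannot be explained by chromosome 21 alone.
Two mechanisms are usually invoked: a *gene-dosage effect* — triplicated,
dose-sensitive genes are expressed at roughly 150% of the euploid level (a
3:2 copy ratio) — and a *cascade effect*, in which over-expressed
chromosome-21 regulators (transcription factors, chromatin proteins)
perturb genes on other chromosomes. Testing either requires a
differential-expression statistic that can be computed per brain structure
and per age stratum from microarray-style log2 intensity data, and
summaries that localize over-expression by chromosome.

`zratioDS` implements that workflow: the Z-score / Z-ratio statistic,
over-expression calling, per-chromosome and per-structure enrichment
tables, cross-stratum correlation of differential-expression profiles, and
a synthetic gene-dosage data generator used to calibrate and validate the
whole pipeline.

## The statistic

**Per-array Z-scores.** For gene $g$ on array (sample) $s$ with log2
intensity $x_{gs}$,
$$ z_{gs} = \frac{x_{gs} - \bar{x}_{\cdot s}}{\mathrm{sd}(x_{\cdot s})}, $$
where mean and standard deviation run over all genes on that array. Two
points are deliberate design choices:

* **Axis.** Standardization is *per array*, across genes — the orientation
  of Z-score normalization for arrays. It makes arrays comparable without a
  separate between-array normalization step, because any affine
  transformation of a single array's intensities leaves its Z-scores
  unchanged (a property the test suite asserts to 1e-9).
* **Denominator.** The sample ($n-1$) standard deviation is used
  everywhere. At transcriptome scale the choice is numerically negligible,
  but fixing it makes exactness tests meaningful.

**Winsorization.** Z-scores are then normalized onto the linear scale
$[-3, +3]$: values beyond the bound are set to the bound
(`clipZScores()`). Winsorizing, rather than dropping outliers or
rescaling, keeps the gene universe size fixed — the denominators of all
percentage summaries depend on that. (The conventional association of
$\pm 3$ with a two-tailed $p < 0.001$ is slightly off — 3.29 is the exact
0.001 cutoff — but 3.0 is the standard bound for this normalization and is
what the package uses.)

**Z-ratio.** Within a stratum, per-gene means of the clipped Z-scores are
taken over DS and over control samples, and for each gene
$$ \mathrm{Zratio}_g \;=\; \frac{\bar z_{g,\mathrm{DS}} - \bar z_{g,\mathrm{Con}}}
        {\mathrm{sd}\!\left(\{\bar z_{g',\mathrm{DS}} - \bar z_{g',\mathrm{Con}}\}_{g'}\right)}. $$
Because every gene shares the one denominator, the Z-ratio vector has
sample standard deviation exactly 1, which is what licenses a fixed normal
cutoff.

**Calling.** Genes with Z-ratio strictly greater than 1.96 (the two-tailed
5% normal point) are called over-expressed; strictly below $-1.96$,
under-expressed. Ties at exactly the threshold are not called. No
multiple-testing correction is applied to this rule — that is a property
of the statistic as used in this literature, not an oversight — so the
expected false-positive fraction under the null is the normal tail
probability, 2.5%, and the package verifies exactly that by simulation.
Under-expression calls are computed for completeness but the headline
summaries count over-expression only.

**Strata.** The "brain" stratum pools all samples per condition before the
group means; each brain region and each age rank is additionally analyzed
as its own stratum. Z-scores are computed once, globally per array, and
strata then subset the standardized columns — standardization is a
property of the array, not of the contrast.

## Summaries and their denominators

`summarizeByChromosome()` reports, per chromosome, the count of called
genes and the percentage of that chromosome's protein-coding genes. The
default denominators are the GRCh38.p13 reference totals
(`referenceChromosomeCounts()`, e.g. 234 protein-coding genes on
chromosome 21) rather than the number of universe genes on the array,
because a chromosome's biological share is the more interpretable
baseline; universe-based denominators are the fallback when no reference
totals are supplied (and the right choice for the scaled-down synthetic
universe). `summarizeByStructure()` divides each stratum's call count by
the fixed gene-universe size.

Percentages are rounded half-up to two decimals (`roundHalfUp()`), the
convention of published summary tables; base `round()`'s round-half-even
would disagree on exact halves such as $0.125 \to 0.13$.

## Correlation across strata

Agreement between two strata's differential-expression profiles is the
squared Pearson correlation of their Z-ratio vectors over shared genes
(`zratioCorrelation()`) — the $R^2$ a linear fit of one profile on the
other reports, which is how such comparisons are conventionally presented.
Spearman correlation was considered and rejected: the quantity of interest
is linear profile agreement, not rank agreement. The pairwise matrix
(`correlationMatrix()`) is symmetric with unit diagonal by construction;
at least three shared genes and non-degenerate variance are required,
otherwise the correlation is undefined and the package errors rather than
returning `NA`.

Age-rank profiles are computed on pooled-region data within each rank — a
design choice, since region-within-rank sample counts are too small to
stratify twice.

## Paired tests

`pairedTests()` compares two matched profiles (for example a region's
Z-ratio vector against the whole brain's) with both a two-tailed Wilcoxon
signed-rank test and a paired t test at $\alpha = 0.05$. Zero differences
are dropped before ranking (the signed-rank convention). The exact null
distribution is used for up to 25 non-zero pairs and the normal
approximation with continuity correction beyond that; the test suite
checks the exact branch against a brute-force enumeration of all $2^n$
sign assignments.

## The synthetic data generator

`generateDataset()` simulates the study design the analysis assumes:

$$ x_{gs} = \beta_g + \Delta_g \cdot [\text{condition}_s = \mathrm{DS}]
            + \varepsilon_{gs},\qquad
   \varepsilon_{gs} \sim N(0, \sigma^2_{\text{noise}}) $$

with per-gene baselines $\beta_g \sim N(8, 2^2)$ drawn once and shared
across samples. The effect $\Delta_g$ is $\log_2(\text{dosageFold})$ for
dose-sensitive chromosome-21 genes, `cascadeLog2Shift` for cascade genes
on other chromosomes, and 0 otherwise — effects are additive on the log2
scale, i.e. multiplicative fold-changes on the linear scale, matching the
input data type.

Defaults, chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| `dosageFold` | 1.5 | the canonical ~1.5-fold over-expression of triplicated genes (3:2 copy ratio) |
| `doseSensitiveFraction` | 0.15 | dose compensation spares most chromosome-21 genes; 15% matches the share of chromosome-21 genes observed over-expressed in DS brain |
| `cascadeFraction` | 0.026 | the genome-wide ~2.6% over-expression attributed to trans effects |
| `cascadeLog2Shift` | 0.3 | a modest trans effect (~1.23-fold); no effect-size distribution is reported for cascade genes, so a single mean shift is used — a stated modeling choice |
| `baselineMean`, `baselineSd` | 8, 2 | typical log2 microarray intensity spread (~4–12 for the bulk of genes) |
| `noiseSd` | 0.3 | realistic combined biological + technical log2 variability |
| gene universe | `scaledChromosomeCounts(4360)` | GRCh38.p13 chromosome totals scaled so chromosome 21 keeps 50 genes — proportional structure at desk scale; pass `referenceChromosomeCounts()` for full size |
| sample design | 4 regions × 6 age ranks × 2 per cell | 48 DS + 48 control, near the study scale of 58 + 58, over the four regions most associated with the DS neurophenotype (OFC, MFC, HIP, CBC) |

Truth-label *counts* are fixed deterministically (`round(fraction ×
count)`); label *identities* and all noise come from the seeded generator,
so a config plus seed reproduces the dataset bit for bit, and the
generator restores the caller's RNG state.

**What the generator does not emulate** — and hence what passing tests do
and do not show about real data: array-level batch effects are excluded by
design (per-array standardization removes affine array effects anyway,
which a test asserts); there is no gene–gene correlation structure, no GO
category structure, no sex effects, no dosage-compensation gradient beyond
the binary dose-sensitive flag, and cascade effects share a single shift
rather than a distribution. Calibration results therefore validate the
statistic's machinery, not the biology of any particular dataset.

## Calibration and recovery

`nullCalibrationRun()` generates effect-free replicates and pushes each
through the full pipeline; the per-replicate fraction of genes called at
1.96 is compared with the 0.025 normal tail. `recoveryRun()` scores calls
against the truth labels: recall of dose-sensitive chromosome-21 genes,
false positives among null genes, and the per-chromosome summary, whose
chromosome-21 row should strictly dominate when effects are present.

Problem sizes used by the test suite and the acceptance script — the
package's own choice of desk scale: ~4,360-gene universes (50 genes on
chromosome 21) for recovery runs at 25 + 25 samples, ~5,000 genes at
20 + 20 samples × 20 replicates for null calibration, and 50 × 8 matrices
for the oracle-equivalence checks against an independently written naive
loop implementation.

## Numerical and degenerate-input policy

* Missing matrix cells (`null`, `NA`, empty) are imputed by the gene's row
  mean at parse time and counted in the parse report; the per-array
  Z-score needs a complete column, and row-mean imputation is neutral for
  the gene's contrast.
* A constant array (zero variance) is a hard error naming the sample; a
  contrast whose per-gene differences are all identical is a degenerate
  contrast error. Neither is silently repaired.
* Chromosome labels are normalized (strip `chr`, `23`→X, `24`→Y);
  anything outside 1–22, X, Y is rejected by the annotation reader and
  treated as unannotated by the aligner.
* Samples without usable metadata are dropped with a warning; zero
  overlap between matrix and metadata is an error. Alignment is
  idempotent.
* Age-rank labels are matched case-insensitively against a configurable
  rank list (`defaultAgeRanks()`): the labels for the oldest rank vary
  between sources ("39–42" vs "40–42 years"), so the vocabulary is a
  parameter, not a constant.
* All randomness flows from a single seed per run; pipeline artifacts are
  byte-identical across reruns with the same config and seed.

## Known limitations

The statistic inherits the limitations of its field: no per-gene variance
moderation (a gene's own replicate variance never enters), no
multiple-testing control at the 1.96 rule, and sensitivity of the Z-ratio
denominator to the fraction of truly changed genes (strong signals
deflate the apparent magnitude of everything else). The reader supports
gene-level series-matrix input only — probe-to-gene collapsing is assumed
to have happened upstream. GO-category enrichment is out of scope: the
pipeline exports per-stratum over-expressed gene lists
(`exportGeneLists()`) in a one-symbol-per-line format suitable for
external enrichment tools.
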