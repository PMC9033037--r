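## Seeded generator for trisomy-21 gene-dosage expression datasets with
## ground-truth labels, plus the calibration and recovery harnesses built
## on top of it.

#' Configuration for the synthetic trisomy-21 dataset generator
#'
#' Builds and validates the generator configuration. The defaults emulate
#' the study conditions of a DS-versus-control post-mortem brain microarray
#' design at desk scale:
#'
#' * `nGenesPerChromosome`: GRCh38.p13 protein-coding totals scaled so
#'   chromosome 21 carries 50 genes (~4,360 genes in total); pass
#'   `referenceChromosomeCounts()` for a full-size universe.
#' * `dosageFold = 1.5`: the canonical ~1.5-fold over-expression of
#'   triplicated, dose-sensitive chromosome-21 genes (a 2:3 copy-number
#'   ratio), applied additively as `log2(1.5)` on the log2 scale.
#' * `doseSensitiveFraction = 0.15`: not every chromosome-21 gene responds
#'   to dosage (dose compensation); 15% matches the share of chromosome-21
#'   genes found over-expressed in DS brain.
#' * `cascadeFraction = 0.026`, `cascadeLog2Shift = 0.3`: a small
#'   trans-acting fraction of genes on other chromosomes shifted in DS,
#'   mirroring the genome-wide ~2.6% over-expression attributed to
#'   chromosome-21 regulators.
#' * `baselineMean = 8`, `baselineSd = 2`: per-gene baseline log2
#'   intensities typical of microarray data (bulk of genes between ~4 and
#'   ~12).
#' * `noiseSd = 0.3`: i.i.d. Gaussian per-observation noise on the log2
#'   scale, a realistic combined biological/technical variability.
#' * Samples span every condition x region x age-rank cell with
#'   `nSamplesPerGroup` samples each; defaults give 48 DS + 48 control,
#'   close to the study's 58 + 58.
#'
#' @param nGenesPerChromosome named vector, chromosome -> gene count.
#' @param nSamplesPerGroup samples per (condition x region x age-rank) cell.
#' @param regions,ageRanks stratum label vectors.
#' @param dosageFold linear fold-change of dose-sensitive chr21 genes in DS.
#' @param doseSensitiveFraction fraction of chr21 genes carrying the effect.
#' @param cascadeFraction fraction of non-21 genes shifted in DS.
#' @param cascadeLog2Shift mean log2 shift of cascade genes in DS.
#' @param baselineMean,baselineSd distribution of per-gene baselines.
#' @param noiseSd per-observation Gaussian noise SD (log2 scale).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return A validated list of class `SyntheticConfig`.
#' @seealso [generateDataset()], [nullCalibrationRun()], [recoveryRun()]
#' @export
syntheticConfig <- function(nGenesPerChromosome = scaledChromosomeCounts(4360),
                            nSamplesPerGroup = 2L,
                            regions = c("OFC", "MFC", "HIP", "CBC"),
                            ageRanks = defaultAgeRanks(),
                            dosageFold = 1.5,
                            doseSensitiveFraction = 0.15,
                            cascadeFraction = 0.026,
                            cascadeLog2Shift = 0.3,
                            baselineMean = 8,
                            baselineSd = 2,
                            noiseSd = 0.3,
                            seed = 1L) {
  config <- list(
    nGenesPerChromosome = nGenesPerChromosome,
    nSamplesPerGroup = as.integer(nSamplesPerGroup),
    regions = as.character(regions),
    ageRanks = as.character(ageRanks),
    dosageFold = dosageFold,
    doseSensitiveFraction = doseSensitiveFraction,
    cascadeFraction = cascadeFraction,
    cascadeLog2Shift = cascadeLog2Shift,
    baselineMean = baselineMean,
    baselineSd = baselineSd,
    noiseSd = noiseSd,
    seed = as.integer(seed)
  )
  class(config) <- "SyntheticConfig"
  validateSyntheticConfig(config)
  config
}

validateSyntheticConfig <- function(config) {
  counts <- config$nGenesPerChromosome
  if (is.null(names(counts)) || !all(names(counts) %in% CHROMOSOMES)) {
    stop("configuration error: gene counts must be named by chromosome")
  }
  if (any(counts < 0) || sum(counts) < 2) {
    stop("configuration error: need at least two genes")
  }
  fracs <- c(config$doseSensitiveFraction, config$cascadeFraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("configuration error: fractions must lie in [0, 1]")
  }
  if (config$dosageFold <= 0) {
    stop("configuration error: dosageFold must be positive")
  }
  if (config$noiseSd < 0 || config$baselineSd < 0) {
    stop("configuration error: standard deviations must be non-negative")
  }
  if (config$nSamplesPerGroup < 1L || !length(config$regions) ||
      !length(config$ageRanks)) {
    stop("configuration error: need at least one sample per design cell")
  }
  nPerCondition <- config$nSamplesPerGroup * length(config$regions) *
    length(config$ageRanks)
  if (nPerCondition < 1L) {
    stop("configuration error: empty sample design")
  }
  invisible(config)
}

#' Generate a synthetic trisomy-21 expression dataset
#'
#' Simulates log2 intensities as `baseline_g + effect(g, condition_s) +
#' Normal(0, noiseSd)`: per-gene baselines are drawn once and shared across
#' samples; dose-sensitive chromosome-21 genes gain `log2(dosageFold)` in
#' DS samples (a multiplicative fold-change on the linear scale); cascade
#' genes on other chromosomes gain `cascadeLog2Shift` in DS samples; all
#' other genes are null. Truth-label counts are fixed by rounding
#' `fraction x gene count`; label identities are drawn by the seeded
#' generator, so the same config and seed reproduce the dataset bit for
#' bit.
#'
#' @param config a [syntheticConfig()] object.
#' @return A list with:
#'   * `experiment`: a [TrisomyExperiment-class] (assay `"log2"`, metadata
#'     and chromosome annotation attached),
#'   * `truth`: data.frame `gene_id`, `label` in
#'     `{dose_sensitive_21, cascade, null}`,
#'   * `metadata`, `annotation`: the plain tables backing the experiment,
#'   * `config`: the configuration echo.
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  validateSyntheticConfig(config)
  counts <- config$nGenesPerChromosome[config$nGenesPerChromosome > 0]

  annotation <- data.frame(
    gene_id = unlist(lapply(names(counts), function(chr) {
      sprintf("G%s_%04d", chr, seq_len(counts[[chr]]))
    }), use.names = FALSE),
    chromosome = rep(names(counts), counts),
    stringsAsFactors = FALSE
  )
  nGenes <- nrow(annotation)

  cells <- expand.grid(
    replicate = seq_len(config$nSamplesPerGroup),
    age_rank = config$ageRanks,
    region = config$regions,
    condition = c("control", "DS"),
    stringsAsFactors = FALSE
  )
  metadata <- data.frame(
    sample_id = sprintf(
      "%s_%s_A%02d_%02d", cells$condition, cells$region,
      match(cells$age_rank, config$ageRanks), cells$replicate
    ),
    condition = cells$condition,
    sex = rep_len(c("female", "male"), nrow(cells)),
    age_rank = cells$age_rank,
    region = cells$region,
    stringsAsFactors = FALSE
  )
  if (sum(metadata$condition == "DS") < 1L ||
      sum(metadata$condition == "control") < 1L) {
    stop("configuration error: need samples in both conditions")
  }

  on21 <- annotation$chromosome == "21"
  nDose <- round(config$doseSensitiveFraction * sum(on21))
  nCascade <- round(config$cascadeFraction * sum(!on21))

  withSeed(config$seed, {
    label <- rep("null", nGenes)
    label[sample(which(on21), nDose)] <- "dose_sensitive_21"
    label[sample(which(!on21), nCascade)] <- "cascade"

    baseline <- rnorm(nGenes, config$baselineMean, config$baselineSd)
    effect <- numeric(nGenes)
    effect[label == "dose_sensitive_21"] <- log2(config$dosageFold)
    effect[label == "cascade"] <- config$cascadeLog2Shift

    values <- baseline +
      outer(effect, as.numeric(metadata$condition == "DS")) +
      matrix(rnorm(nGenes * nrow(metadata), 0, config$noiseSd),
        nrow = nGenes
      )
  })
  dimnames(values) <- list(annotation$gene_id, metadata$sample_id)

  experiment <- suppressWarnings(
    alignDataset(values, metadata, annotation)
  )
  list(
    experiment = experiment,
    truth = data.frame(
      gene_id = annotation$gene_id, label = label,
      stringsAsFactors = FALSE
    ),
    metadata = metadata,
    annotation = annotation,
    config = config
  )
}

#' False-positive calibration on effect-free data
#'
#' Requires a null configuration (both effect fractions zero), generates
#' `nReps` independent datasets with consecutive seeds, runs the full
#' Z-score / Z-ratio pipeline on each (whole-brain stratum) and returns the
#' fraction of genes called over-expressed per replicate. Under the null,
#' Z-ratios are approximately standard normal, so the expected fraction at
#' threshold 1.96 is the normal tail probability 0.025.
#'
#' @param config a null [syntheticConfig()] (`doseSensitiveFraction` and
#'   `cascadeFraction` both 0).
#' @param nReps number of replicates.
#' @param threshold over-expression call cutoff.
#' @param clipBound winsorization bound.
#' @return Numeric vector of per-replicate false-positive fractions.
#' @export
nullCalibrationRun <- function(config, nReps = 20L, threshold = 1.96,
                               clipBound = 3) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$doseSensitiveFraction != 0 || config$cascadeFraction != 0) {
    stop("null calibration needs a configuration with zero effect fractions")
  }
  vapply(seq_len(nReps), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    dat <- generateDataset(cfg)
    z <- zratioForStratum(dat$experiment, clipBound = clipBound)
    calls <- callOverexpressed(z, threshold = threshold)
    length(overexpressed(calls)) / length(geneIds(z))
  }, numeric(1L))
}

#' Recovery of the gene-dosage signal against ground truth
#'
#' Generates one dataset, runs the whole-brain Z-ratio pipeline, and scores
#' the calls against the generator's truth labels: recall is the fraction
#' of dose-sensitive chromosome-21 genes called over-expressed, the
#' false-positive rate is the fraction of null genes called. The
#' per-chromosome summary (universe denominators) is returned so the
#' chromosome-21 dominance of the dosage signal can be checked.
#'
#' @param config a [syntheticConfig()] with at least one non-null gene.
#' @param threshold over-expression call cutoff.
#' @param clipBound winsorization bound.
#' @return A list: `recall`, `falsePositiveRate`, `chromosomeSummary`,
#'   `zratio` ([ZRatioVector-class]), `calls` ([CallSet-class]), `truth`.
#' @export
recoveryRun <- function(config, threshold = 1.96, clipBound = 3) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$doseSensitiveFraction == 0 && config$cascadeFraction == 0) {
    stop("recovery needs at least one non-null gene configured")
  }
  dat <- generateDataset(config)
  z <- zratioForStratum(dat$experiment, clipBound = clipBound)
  calls <- callOverexpressed(z, threshold = threshold)
  doseGenes <- dat$truth$gene_id[dat$truth$label == "dose_sensitive_21"]
  nullGenes <- dat$truth$gene_id[dat$truth$label == "null"]
  list(
    recall = if (length(doseGenes)) {
      mean(doseGenes %in% overexpressed(calls))
    } else {
      NA_real_
    },
    falsePositiveRate = mean(nullGenes %in% overexpressed(calls)),
    chromosomeSummary = summarizeByChromosome(
      calls, dat$annotation, dat$truth$gene_id
    ),
    zratio = z,
    calls = calls,
    truth = dat$truth
  )
}

#' Write a synthetic dataset to disk
#'
#' Emits the same dialects the readers accept: the expression matrix as
#' plain TSV or as a series-matrix file, the metadata CSV, the annotation
#' TSV, a truth-labels TSV and the configuration as YAML.
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @param dialect `"tsv"` or `"series_matrix"` for the expression matrix.
#' @return Invisibly, the named vector of file paths written.
#' @export
writeSyntheticDataset <- function(dataset, dir,
                                  dialect = c("tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  values <- assay(dataset$experiment, "log2")
  paths <- c(
    matrix = file.path(dir, if (dialect == "tsv") {
      "expression.tsv"
    } else {
      "series_matrix.txt"
    }),
    metadata = file.path(dir, "metadata.csv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml")
  )
  if (dialect == "tsv") {
    writeExpressionTSV(values, paths[["matrix"]])
  } else {
    writeSeriesMatrix(values, dataset$metadata, paths[["matrix"]])
  }
  writeSampleMetadata(dataset$metadata, paths[["metadata"]])
  writeGeneAnnotation(dataset$annotation, paths[["annotation"]])
  write.table(dataset$truth, paths[["truth"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeSyntheticConfig(dataset$config, paths[["config"]])
  invisible(paths)
}

#' Read / write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @return `readSyntheticConfig()` returns a validated
#'   [syntheticConfig()] object.
#' @export
readSyntheticConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$nGenesPerChromosome <- unlist(raw$nGenesPerChromosome)
  do.call(syntheticConfig, raw)
}

#' @rdname readSyntheticConfig
#' @param config a [syntheticConfig()] object.
#' @export
writeSyntheticConfig <- function(config, path) {
  stopifnot(inherits(config, "SyntheticConfig"))
  yaml::write_yaml(
    lapply(unclass(config), function(x) {
      if (!is.null(names(x))) as.list(x) else x
    }),
    path
  )
  invisible(path)
}
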