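smallConfig <- function(nSamplesPerGroup = 5L, ...) {
  syntheticConfig(
    nGenesPerChromosome = scaledChromosomeCounts(400),
    regions = "HIP", ageRanks = "30-39 y",
    nSamplesPerGroup = nSamplesPerGroup,
    ...
  )
}

test_that("generation is bit-reproducible given the seed", {
  cfg <- smallConfig(seed = 99L)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(
    SummarizedExperiment::assay(a$experiment, "log2"),
    SummarizedExperiment::assay(b$experiment, "log2")
  )
  expect_identical(a$truth, b$truth)

  c <- generateDataset(smallConfig(seed = 100L))
  expect_false(identical(
    SummarizedExperiment::assay(a$experiment, "log2"),
    SummarizedExperiment::assay(c$experiment, "log2")
  ))
  # the generator restores the caller's RNG stream
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(generateDataset(cfg))
  expect_identical(rnorm(1), before)
})

test_that("noiseless doubling shifts dose-sensitive genes by exactly 1", {
  cfg <- smallConfig(noiseSd = 0, dosageFold = 2, seed = 3L)
  dat <- generateDataset(cfg)
  values <- SummarizedExperiment::assay(dat$experiment, "log2")
  isDS <- dat$metadata$condition == "DS"
  diff <- rowMeans(values[, isDS]) - rowMeans(values[, !isDS])
  dose <- dat$truth$label == "dose_sensitive_21"
  cascade <- dat$truth$label == "cascade"
  expect_true(all(diff[dose] == 1))
  expect_true(all(abs(diff[cascade] - cfg$cascadeLog2Shift) < 1e-12))
  expect_true(all(diff[!dose & !cascade] == 0))
})

test_that("truth label counts follow the configured fractions exactly", {
  cfg <- syntheticConfig(
    nGenesPerChromosome = c("1" = 200L, "21" = 50L),
    regions = "HIP", ageRanks = "2-10 y", nSamplesPerGroup = 2L,
    doseSensitiveFraction = 0.3, cascadeFraction = 0.1
  )
  dat <- generateDataset(cfg)
  tab <- table(dat$truth$label)
  expect_identical(unname(tab[["dose_sensitive_21"]]), 15L) # 0.3 * 50
  expect_identical(unname(tab[["cascade"]]), 20L) # 0.1 * 200
  dose <- dat$truth$gene_id[dat$truth$label == "dose_sensitive_21"]
  expect_true(all(
    dat$annotation$chromosome[match(dose, dat$annotation$gene_id)] == "21"
  ))

  null <- generateDataset(smallConfig(
    doseSensitiveFraction = 0, cascadeFraction = 0
  ))
  expect_true(all(null$truth$label == "null"))
})

test_that("invalid configurations are rejected", {
  expect_error(smallConfig(doseSensitiveFraction = 1.2), "fractions")
  expect_error(smallConfig(dosageFold = 0), "dosageFold")
  expect_error(smallConfig(noiseSd = -1), "non-negative")
  expect_error(smallConfig(nSamplesPerGroup = 0L), "at least one sample")
  expect_error(
    syntheticConfig(nGenesPerChromosome = c(bad = 10L)),
    "named by chromosome"
  )
})

test_that("null calibration tracks the normal tail probability", {
  cfg <- syntheticConfig(
    nGenesPerChromosome = scaledChromosomeCounts(2000),
    regions = "HIP", ageRanks = "30-39 y", nSamplesPerGroup = 15L,
    doseSensitiveFraction = 0, cascadeFraction = 0, seed = 7L
  )
  fractions <- nullCalibrationRun(cfg, nReps = 8L)
  expect_length(fractions, 8L)
  se <- sqrt(0.025 * 0.975 / (2000 * 8))
  expect_lt(abs(mean(fractions) - 0.025), 4 * se + 0.002)
  # a stricter threshold calls far fewer genes
  strict <- nullCalibrationRun(cfg, nReps = 4L, threshold = 3)
  expect_lt(mean(strict), 0.006) # normal tail at 3 is ~0.00135
  # deterministic for a fixed config
  expect_identical(nullCalibrationRun(cfg, nReps = 2L),
                   nullCalibrationRun(cfg, nReps = 2L))
  expect_error(nullCalibrationRun(smallConfig(), 2L), "zero effect")
})

test_that("noiseless recovery is perfect and recall is frozen at seed 1", {
  clean <- recoveryRun(smallConfig(noiseSd = 0, seed = 5L))
  expect_identical(clean$recall, 1)
  expect_identical(clean$falsePositiveRate, 0)

  # regression fixture: the standard recovery conditions at seed 1
  cfg <- syntheticConfig(
    nGenesPerChromosome = scaledChromosomeCounts(4360),
    regions = "DFC", ageRanks = "30-39 y", nSamplesPerGroup = 25L,
    dosageFold = 1.5, noiseSd = 0.3, seed = 1L
  )
  out <- recoveryRun(cfg)
  expect_identical(out$recall, FROZEN_RECALL_SEED1)
  chr <- out$chromosomeSummary
  expect_identical(
    chr$chromosome[which.max(chr$percentage)], "21"
  )
  expect_error(
    recoveryRun(smallConfig(doseSensitiveFraction = 0, cascadeFraction = 0)),
    "non-null"
  )
})

test_that("recall responds monotonically to effect size and noise", {
  base <- function(...) {
    syntheticConfig(
      nGenesPerChromosome = scaledChromosomeCounts(600),
      regions = "HIP", ageRanks = "30-39 y", nSamplesPerGroup = 4L,
      doseSensitiveFraction = 0.5, ...
    )
  }
  meanRecall <- function(...) {
    mean(vapply(1:10, function(s) {
      recoveryRun(base(..., seed = 100L + s))$recall
    }, numeric(1)))
  }
  byFold <- c(
    meanRecall(dosageFold = 1.15, noiseSd = 0.5),
    meanRecall(dosageFold = 1.5, noiseSd = 0.5),
    meanRecall(dosageFold = 2.5, noiseSd = 0.5)
  )
  expect_true(all(diff(byFold) >= 0))
  byNoise <- c(
    meanRecall(dosageFold = 1.3, noiseSd = 0.2),
    meanRecall(dosageFold = 1.3, noiseSd = 0.7),
    meanRecall(dosageFold = 1.3, noiseSd = 1.5)
  )
  expect_true(all(diff(byNoise) <= 0))
})

test_that("shared effects correlate strata; null data do not", {
  # a strong shared trans signal so the effect variance dominates the
  # per-stratum sampling noise in both regions
  shared <- generateDataset(syntheticConfig(
    nGenesPerChromosome = scaledChromosomeCounts(1000),
    regions = c("HIP", "CBC"), ageRanks = "30-39 y",
    cascadeFraction = 0.1, cascadeLog2Shift = 0.6,
    nSamplesPerGroup = 20L, seed = 17L
  ))
  te <- shared$experiment
  r2 <- zratioCorrelation(
    zratioForStratum(te, region = "HIP", stratum = "HIP"),
    zratioForStratum(te, region = "CBC", stratum = "CBC")
  )

  nullDat <- generateDataset(syntheticConfig(
    nGenesPerChromosome = scaledChromosomeCounts(1000),
    regions = c("HIP", "CBC"), ageRanks = "30-39 y",
    nSamplesPerGroup = 20L, doseSensitiveFraction = 0,
    cascadeFraction = 0, seed = 17L
  ))
  r2null <- zratioCorrelation(
    zratioForStratum(nullDat$experiment, region = "HIP", stratum = "HIP"),
    zratioForStratum(nullDat$experiment, region = "CBC", stratum = "CBC")
  )
  expect_gt(r2, 0.4)
  expect_lt(r2null, 0.1)
  expect_gt(r2, r2null + 0.3)
})

test_that("datasets and configs round-trip through disk formats", {
  cfg <- smallConfig(seed = 31L)
  dat <- generateDataset(cfg)
  dir <- withr::local_tempdir()

  paths <- writeSyntheticDataset(dat, dir, dialect = "tsv")
  expect_true(all(file.exists(paths)))
  back <- readExpressionTSV(paths[["matrix"]])
  expect_lt(max(abs(
    back$values - SummarizedExperiment::assay(dat$experiment, "log2")
  )), 1e-9)
  ann <- readGeneAnnotation(paths[["annotation"]])
  expect_identical(ann, dat$annotation)
  meta <- readSampleMetadata(paths[["metadata"]])
  expect_identical(meta$condition, dat$metadata$condition)

  cfg2 <- readSyntheticConfig(paths[["config"]])
  expect_identical(cfg2$seed, cfg$seed)
  expect_identical(cfg2$nGenesPerChromosome, cfg$nGenesPerChromosome)
  expect_identical(cfg2$dosageFold, cfg$dosageFold)

  sm <- writeSyntheticDataset(dat, withr::local_tempdir(),
                              dialect = "series_matrix")
  parsed <- readSeriesMatrix(sm[["matrix"]])
  expect_lt(max(abs(
    parsed$values - SummarizedExperiment::assay(dat$experiment, "log2")
  )), 1e-9)
  expect_identical(parsed$metadata$condition, dat$metadata$condition)
})
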