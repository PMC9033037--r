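## End-to-end orchestration: config -> dataset -> Z-ratios per stratum ->
## calls -> summaries -> correlations -> report, with deterministic TSV
## artifacts.

#' Pipeline run configuration
#'
#' Exactly one input mode must be active: real input (paths to an
#' expression matrix, a metadata CSV and optionally an annotation TSV) or
#' synthetic input (a [syntheticConfig()]). All thresholds of the analysis
#' are set here; all randomness flows from the single `seed` (for synthetic
#' runs it overrides the seed inside the synthetic config, so one number
#' pins down the whole run).
#'
#' @param matrixPath path to an expression matrix (plain TSV, or a
#'   series-matrix file — detected by its `!`-prefixed header).
#' @param metadataPath path to a sample-metadata CSV (optional for
#'   series-matrix input, whose metadata is parsed from the header).
#' @param annotationPath optional path to a gene -> chromosome TSV.
#' @param synthetic a [syntheticConfig()] object (synthetic mode).
#' @param clipBound winsorization bound for Z-scores.
#' @param callThreshold over-expression call cutoff.
#' @param regions regions to analyze as strata; `NULL` = every region
#'   present in the metadata.
#' @param ageRanks age ranks to analyze as strata; `NULL` = every rank
#'   present.
#' @param includeWholeBrain analyze the pooled whole-brain stratum?
#' @param chromosomeTotals per-chromosome percentage denominators
#'   (default [referenceChromosomeCounts()]); `NULL` falls back to counts
#'   of annotated universe genes.
#' @param outputDir directory for TSV artifacts; `NULL` writes nothing.
#' @param seed integer seed for the run.
#' @param logLevel `"quiet"`, `"info"` or `"debug"`.
#' @return A validated list of class `RunConfig`.
#' @export
runConfig <- function(matrixPath = NULL, metadataPath = NULL,
                      annotationPath = NULL, synthetic = NULL,
                      clipBound = 3, callThreshold = 1.96,
                      regions = NULL, ageRanks = NULL,
                      includeWholeBrain = TRUE,
                      chromosomeTotals = referenceChromosomeCounts(),
                      outputDir = NULL, seed = 1L, logLevel = "info") {
  realMode <- !is.null(matrixPath)
  synMode <- !is.null(synthetic)
  if (realMode == synMode) {
    stop("exactly one of matrixPath / synthetic must be given")
  }
  if (synMode) stopifnot(inherits(synthetic, "SyntheticConfig"))
  stopifnot(clipBound > 0, callThreshold > 0)
  config <- list(
    matrixPath = matrixPath, metadataPath = metadataPath,
    annotationPath = annotationPath, synthetic = synthetic,
    clipBound = clipBound, callThreshold = callThreshold,
    regions = regions, ageRanks = ageRanks,
    includeWholeBrain = isTRUE(includeWholeBrain),
    chromosomeTotals = chromosomeTotals,
    outputDir = outputDir, seed = as.integer(seed),
    logLevel = match.arg(logLevel, c("quiet", "info", "debug"))
  )
  class(config) <- "RunConfig"
  config
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the [runConfig()] arguments; a `synthetic` mapping is
#' passed through [syntheticConfig()].
#'
#' @param path YAML file path.
#' @return A `RunConfig` object.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    raw$synthetic$nGenesPerChromosome <-
      unlist(raw$synthetic$nGenesPerChromosome)
    raw$synthetic <- do.call(syntheticConfig, raw$synthetic)
  }
  if (!is.null(raw$chromosomeTotals)) {
    raw$chromosomeTotals <- unlist(raw$chromosomeTotals)
  }
  do.call(runConfig, raw)
}

loadPipelineInput <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- config$seed
    dat <- generateDataset(syn)
    return(list(experiment = dat$experiment, warnings = character()))
  }
  warnings <- character()
  firstLine <- readLines(config$matrixPath, n = 1L)
  if (startsWith(firstLine, "!")) {
    parsed <- readSeriesMatrix(config$matrixPath)
    values <- parsed$values
    meta <- parsed$metadata
    if (parsed$report$nImputed > 0) {
      warnings <- c(warnings, sprintf(
        "%d missing cell(s) imputed by row means", parsed$report$nImputed
      ))
    }
  } else {
    parsed <- readExpressionTSV(config$matrixPath)
    values <- parsed$values
    meta <- NULL
    if (parsed$report$nImputed > 0) {
      warnings <- c(warnings, sprintf(
        "%d missing cell(s) imputed by row means", parsed$report$nImputed
      ))
    }
  }
  if (!is.null(config$metadataPath)) {
    meta <- readSampleMetadata(config$metadataPath)
  }
  if (is.null(meta)) stop("no sample metadata available for real input")
  ann <- if (!is.null(config$annotationPath)) {
    readGeneAnnotation(config$annotationPath)
  } else {
    NULL
  }
  experiment <- withCallingHandlers(
    alignDataset(values, meta, ann),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  list(experiment = experiment, warnings = warnings)
}

## Strata present in both conditions; others are skipped with a warning
## entry rather than aborting the run.
usableStrata <- function(labels, condition, wanted) {
  present <- sort(unique(labels[labels != "unknown"]))
  if (!is.null(wanted)) present <- present[present %in% wanted]
  ok <- vapply(present, function(lab) {
    sum(labels == lab & condition == "DS") >= 1L &&
      sum(labels == lab & condition == "control") >= 1L
  }, logical(1L))
  list(use = present[ok], skipped = present[!ok])
}

#' Run the full analysis pipeline
#'
#' Executes input loading/alignment (or synthetic generation), per-array
#' Z-score standardization with winsorization, the Z-ratio contrast for the
#' whole-brain stratum, every analyzable region and every analyzable age
#' rank, over-expression calling, the per-chromosome and per-structure
#' summaries, cross-stratum R-squared matrices (regions and age ranks
#' separately), and paired Wilcoxon/t tests of each region's Z-ratio
#' profile against the whole brain's. Identical inputs, configuration and
#' seed give identical reports and byte-identical TSV artifacts.
#'
#' @param config a [runConfig()] object.
#' @return A list of class `RunReport`: `experiment`, `warnings`,
#'   `zratios` (named list of [ZRatioVector-class]), `calls` (named list of
#'   [CallSet-class]), `callCounts`, `chromosomeSummary`,
#'   `structureSummary`, `correlations` (`structures`, `ageRanks`),
#'   `pairedTests`, `clip`, `config`, `version`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  log <- function(level, stage, ...) {
    pipeLog(level, stage, ..., logLevel = config$logLevel)
  }
  log("info", "input", "loading dataset")
  input <- loadPipelineInput(config)
  te <- input$experiment
  warnings <- input$warnings
  log("info", "input", sprintf(
    "%d genes x %d samples", nrow(te), ncol(te)
  ))

  te <- clipZScores(computeZScores(te), bound = config$clipBound)
  log("debug", "zscore", sprintf(
    "%d entr(ies) winsorized at +/-%g",
    metadata(te)$clip$nClipped, config$clipBound
  ))

  condition <- as.character(sampleCondition(te))
  regions <- usableStrata(brainRegion(te), condition, config$regions)
  ranks <- usableStrata(
    as.character(colData(te)$age_rank), condition, config$ageRanks
  )
  for (lab in c(regions$skipped, ranks$skipped)) {
    warnings <- c(warnings, sprintf(
      "stratum '%s' skipped: missing a condition group", lab
    ))
  }

  zratios <- list()
  if (config$includeWholeBrain) {
    zratios[["brain"]] <- zratioForStratum(te, stratum = "brain")
  }
  for (reg in regions$use) {
    zratios[[reg]] <- zratioForStratum(te, region = reg, stratum = reg)
    log("debug", "zratio", sprintf("region %s done", reg))
  }
  rankVectors <- list()
  for (rank in ranks$use) {
    rankVectors[[rank]] <- zratioForStratum(
      te, ageRank = rank, stratum = rank
    )
    log("debug", "zratio", sprintf("age rank %s done", rank))
  }
  if (!length(zratios) && !length(rankVectors)) {
    stop("no analyzable strata: every stratum lacks a condition group")
  }

  calls <- lapply(c(zratios, rankVectors), callOverexpressed,
    threshold = config$callThreshold
  )
  callCounts <- vapply(calls, function(cs) length(overexpressed(cs)),
    integer(1L)
  )
  log("info", "calls", paste(
    sprintf("%s=%d", names(callCounts), callCounts),
    collapse = " "
  ))

  universe <- geneIds(te)
  chromosomeSummary <- if (!is.null(calls[["brain"]])) {
    summarizeByChromosome(
      calls[["brain"]], geneAnnotation(te), universe,
      chromosomeTotals = config$chromosomeTotals
    )
  } else {
    NULL
  }
  structureSummary <- summarizeByStructure(
    calls[names(calls) %in% c("brain", regions$use)], length(universe)
  )

  correlations <- list(
    structures = if (length(zratios) >= 2L) correlationMatrix(zratios),
    ageRanks = if (length(rankVectors) >= 2L) correlationMatrix(rankVectors)
  )

  tests <- list()
  if (!is.null(zratios[["brain"]])) {
    brainZ <- zratio(zratios[["brain"]])
    for (reg in regions$use) {
      tests[[reg]] <- tryCatch(
        pairedTests(unname(zratio(zratios[[reg]])), unname(brainZ)),
        error = function(e) {
          warnings <<- c(warnings, sprintf(
            "paired tests for '%s' skipped: %s", reg, conditionMessage(e)
          ))
          NULL
        }
      )
    }
  }

  report <- list(
    experiment = te,
    warnings = warnings,
    zratios = c(zratios, rankVectors),
    calls = calls,
    callCounts = callCounts,
    chromosomeSummary = chromosomeSummary,
    structureSummary = structureSummary,
    correlations = correlations,
    pairedTests = tests,
    clip = metadata(te)$clip,
    config = config,
    version = as.character(packageVersion("zratioDS"))
  )
  class(report) <- "RunReport"
  if (!is.null(config$outputDir)) writeReportArtifacts(report)
  report
}

writeReportArtifacts <- function(report) {
  dir <- report$config$outputDir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(report$zratios)) {
    writeZRatioTSV(
      report$zratios[[name]], report$calls[[name]],
      file.path(dir, sprintf("zratio_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", name)))
    )
  }
  if (!is.null(report$chromosomeSummary)) {
    writeSummaryTSV(
      report$chromosomeSummary, file.path(dir, "chromosome_summary.tsv")
    )
  }
  writeSummaryTSV(
    report$structureSummary, file.path(dir, "structure_summary.tsv")
  )
  if (!is.null(report$correlations$structures)) {
    writeSummaryTSV(
      report$correlations$structures,
      file.path(dir, "correlation_structures.tsv")
    )
  }
  if (!is.null(report$correlations$ageRanks)) {
    writeSummaryTSV(
      report$correlations$ageRanks,
      file.path(dir, "correlation_ageranks.tsv")
    )
  }
  invisible(dir)
}

#' Export per-stratum over-expressed gene lists
#'
#' Writes one plain-text file per stratum with the over-expressed gene
#' symbols, one per line, sorted; a stratum without calls still produces an
#' (empty) file. The format suits external enrichment tools, which is why
#' symbols containing whitespace are rejected.
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
exportGeneLists <- function(report, dir) {
  stopifnot(inherits(report, "RunReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (name in names(report$calls)) {
    genes <- sort(overexpressed(report$calls[[name]]))
    if (any(grepl("[[:space:]]", genes))) {
      stop(sprintf(
        "invalid gene symbol(s) with whitespace in stratum '%s'", name
      ))
    }
    path <- file.path(
      dir, sprintf("overexpressed_%s.txt", gsub("[^A-Za-z0-9._-]", "_", name))
    )
    writeLines(genes, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf(
    "zratioDS run (v%s): %d genes x %d samples, seed %d\n",
    x$version, nrow(x$experiment), ncol(x$experiment), x$config$seed
  ))
  cat(sprintf(
    "clip bound %g (%d entries winsorized), call threshold %g\n",
    x$clip$bound, x$clip$nClipped, x$config$callThreshold
  ))
  cat("over-expression calls per stratum:\n")
  print(x$callCounts)
  if (!is.null(x$chromosomeSummary)) {
    top <- x$chromosomeSummary[
      order(-x$chromosomeSummary$percentage)[1:3], , drop = FALSE
    ]
    cat("top chromosomes by over-expressed percentage:\n")
    print(top, row.names = FALSE)
  }
  if (length(x$warnings)) {
    cat(sprintf("%d warning(s); first: %s\n", length(x$warnings),
                x$warnings[[1L]]))
  }
  invisible(x)
}
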