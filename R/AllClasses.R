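#' TrisomyExperiment: expression container for the DS/control brain design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' `"log2"` assay of gene x sample log2 intensities, sample metadata
#' (`condition`, `sex`, `age_rank`, `region`) in `colData`, and the gene ->
#' chromosome annotation in `rowData$chromosome` (`NA` for unannotated
#' genes, which are kept in the gene universe but excluded from chromosome
#' summaries). Validity requires unique gene and sample identifiers, finite
#' log2 values, and a `condition` factor with levels `control`/`DS` and no
#' missing entries.
#'
#' Use [alignDataset()] (or the synthetic generator) to construct one from a
#' matrix, a metadata table and an annotation table.
#'
#' @aliases TrisomyExperiment-class
#' @exportClass TrisomyExperiment
setClass("TrisomyExperiment", contains = "SummarizedExperiment")

setValidity("TrisomyExperiment", function(object) {
  msg <- character()
  if (!"log2" %in% assayNames(object)) {
    msg <- c(msg, "assay 'log2' is required")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "gene identifiers must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample identifiers must be present and unique")
  }
  if ("log2" %in% assayNames(object) &&
      !all(is.finite(assay(object, "log2")))) {
    msg <- c(msg, "assay 'log2' must be finite after missing-value handling")
  }
  cond <- colData(object)$condition
  if (is.null(cond)) {
    msg <- c(msg, "colData must contain a 'condition' column")
  } else if (!is.factor(cond) || !identical(levels(cond), c("control", "DS"))) {
    msg <- c(msg, "'condition' must be a factor with levels control, DS")
  } else if (anyNA(cond)) {
    msg <- c(msg, "'condition' must not contain missing values")
  }
  if (!"chromosome" %in% colnames(rowData(object))) {
    msg <- c(msg, "rowData must contain a 'chromosome' column (NA allowed)")
  }
  if (length(msg)) msg else TRUE
})

#' GroupMeanZ: per-gene mean Z-scores for a DS/control contrast
#'
#' Holds, for one stratum, the per-gene arithmetic means of the (clipped)
#' Z-scores over the DS and the control samples, together with the two
#' sample counts. Produced by [groupMeanZ()], consumed by [computeZRatio()].
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot meanZDS,meanZCon per-gene mean Z-score in the DS / control group.
#' @slot nDS,nCon number of samples in each group (both >= 1).
#' @aliases GroupMeanZ-class
#' @exportClass GroupMeanZ
setClass("GroupMeanZ",
  representation(
    geneIds = "character",
    meanZDS = "numeric",
    meanZCon = "numeric",
    nDS = "integer",
    nCon = "integer"
  )
)

setValidity("GroupMeanZ", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (length(object@meanZDS) != n || length(object@meanZCon) != n) {
    msg <- c(msg, "mean vectors must match the number of genes")
  }
  if (anyDuplicated(object@geneIds)) {
    msg <- c(msg, "gene identifiers must be unique")
  }
  if (object@nDS < 1L || object@nCon < 1L) {
    msg <- c(msg, "each condition group needs at least one sample")
  }
  if (length(msg)) msg else TRUE
})

#' ZRatioVector: per-gene Z-ratio statistic for one stratum
#'
#' The Z-ratio for gene g is the difference of its group-mean Z-scores
#' (DS minus control) divided by the sample standard deviation of those
#' differences over all genes. By construction the vector of Z-ratios has
#' sample standard deviation exactly 1.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot zratio per-gene Z-ratio values (unitless).
#' @slot stratum label of the stratum the contrast was computed in
#'   (`"brain"`, a region code, or an age rank).
#' @slot sdOfDifferences the shared denominator: sample SD of the per-gene
#'   group-mean differences.
#' @aliases ZRatioVector-class
#' @exportClass ZRatioVector
setClass("ZRatioVector",
  representation(
    geneIds = "character",
    zratio = "numeric",
    stratum = "character",
    sdOfDifferences = "numeric"
  )
)

setValidity("ZRatioVector", function(object) {
  msg <- character()
  if (length(object@zratio) != length(object@geneIds)) {
    msg <- c(msg, "zratio must have one value per gene")
  }
  if (anyDuplicated(object@geneIds)) {
    msg <- c(msg, "gene identifiers must be unique")
  }
  if (length(object@stratum) != 1L) {
    msg <- c(msg, "stratum must be a single label")
  }
  if (length(object@sdOfDifferences) != 1L ||
      !is.finite(object@sdOfDifferences) || object@sdOfDifferences <= 0) {
    msg <- c(msg, "sdOfDifferences must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' CallSet: over- and under-expression calls for one stratum
#'
#' Genes whose Z-ratio is strictly greater than the threshold (default 1.96,
#' the two-tailed 5% normal cutoff) are called over-expressed; strictly less
#' than minus the threshold, under-expressed. Ties at exactly the threshold
#' are not called. The two sets are disjoint by construction.
#'
#' @slot stratum stratum label the calls belong to.
#' @slot threshold the positive call cutoff used.
#' @slot overexpressed,underexpressed character vectors of gene identifiers.
#' @aliases CallSet-class
#' @exportClass CallSet
setClass("CallSet",
  representation(
    stratum = "character",
    threshold = "numeric",
    overexpressed = "character",
    underexpressed = "character"
  )
)

setValidity("CallSet", function(object) {
  msg <- character()
  if (length(object@threshold) != 1L || object@threshold <= 0) {
    msg <- c(msg, "threshold must be a single positive number")
  }
  if (length(intersect(object@overexpressed, object@underexpressed))) {
    msg <- c(msg, "over- and under-expressed sets must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrisomyExperiment", function(object) {
  callNextMethod()
  cond <- table(colData(object)$condition)
  cat(sprintf(
    "condition: %d control, %d DS | annotated genes: %d/%d\n",
    cond[["control"]], cond[["DS"]],
    sum(!is.na(rowData(object)$chromosome)), nrow(object)
  ))
})

setMethod("show", "GroupMeanZ", function(object) {
  cat(sprintf(
    "GroupMeanZ: %d genes | n = %d DS, %d control\n",
    length(object@geneIds), object@nDS, object@nCon
  ))
})

setMethod("show", "ZRatioVector", function(object) {
  cat(sprintf(
    "ZRatioVector '%s': %d genes | SD of differences = %.4g | range [%.2f, %.2f]\n",
    object@stratum, length(object@geneIds), object@sdOfDifferences,
    min(object@zratio), max(object@zratio)
  ))
})

setMethod("show", "CallSet", function(object) {
  cat(sprintf(
    "CallSet '%s' (|Z-ratio| > %.2f): %d over-expressed, %d under-expressed\n",
    object@stratum, object@threshold,
    length(object@overexpressed), length(object@underexpressed)
  ))
})
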