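#' Accessors for zratioDS classes
#'
#' Small accessor functions in place of direct slot access: `geneIds()`,
#' `zratio()`, `stratumLabel()`, `sdOfDifferences()` for [ZRatioVector-class]
#' and [GroupMeanZ-class] objects; `overexpressed()`, `underexpressed()`,
#' `callThreshold()` for [CallSet-class]; `sampleCondition()`,
#' `brainRegion()`, `ageRank()` for the per-sample metadata columns of a
#' [TrisomyExperiment-class].
#'
#' @param x an object of the documented class.
#' @return The corresponding component: character vectors for identifier
#'   accessors, numeric vectors/scalars for the statistic accessors, factors
#'   or character vectors for the metadata accessors.
#' @name accessors
NULL

#' @rdname accessors
setMethod("geneIds", "GroupMeanZ", function(x) x@geneIds)

#' @rdname accessors
setMethod("geneIds", "ZRatioVector", function(x) x@geneIds)

#' @rdname accessors
setMethod("geneIds", "TrisomyExperiment", function(x) rownames(x))

#' @rdname accessors
setMethod("zratio", "ZRatioVector", function(x) {
  setNames(x@zratio, x@geneIds)
})

#' @rdname accessors
setMethod("stratumLabel", "ZRatioVector", function(x) x@stratum)

#' @rdname accessors
setMethod("stratumLabel", "CallSet", function(x) x@stratum)

#' @rdname accessors
setMethod("sdOfDifferences", "ZRatioVector", function(x) x@sdOfDifferences)

#' @rdname accessors
setMethod("overexpressed", "CallSet", function(x) x@overexpressed)

#' @rdname accessors
setMethod("underexpressed", "CallSet", function(x) x@underexpressed)

#' @rdname accessors
setMethod("callThreshold", "CallSet", function(x) x@threshold)

#' @rdname accessors
setMethod("sampleCondition", "TrisomyExperiment", function(x) {
  colData(x)$condition
})

#' @rdname accessors
setMethod("brainRegion", "TrisomyExperiment", function(x) {
  as.character(colData(x)$region)
})

#' @rdname accessors
setMethod("ageRank", "TrisomyExperiment", function(x) {
  as.character(colData(x)$age_rank)
})

#' Mean Z-score components of a GroupMeanZ object
#'
#' @param x a [GroupMeanZ-class] object.
#' @return `groupMeans()` returns a two-column matrix (`DS`, `control`) of
#'   per-gene mean Z-scores; `groupSizes()` the named sample counts.
#' @export
groupMeans <- function(x) {
  stopifnot(is(x, "GroupMeanZ"))
  cbind(DS = setNames(x@meanZDS, x@geneIds), control = x@meanZCon)
}

#' @rdname groupMeans
#' @export
groupSizes <- function(x) {
  stopifnot(is(x, "GroupMeanZ"))
  c(DS = x@nDS, control = x@nCon)
}

#' Per-sample metadata of a TrisomyExperiment as a plain table
#'
#' Returns the sample metadata in the same layout the readers accept
#' (`sample_id`, `condition`, `sex`, `age_rank`, `region`), convenient for
#' round-tripping through [alignDataset()] or the writers.
#'
#' @param x a [TrisomyExperiment-class] object.
#' @return A `data.frame` with one row per sample.
#' @export
sampleMetadata <- function(x) {
  stopifnot(is(x, "TrisomyExperiment"))
  cd <- colData(x)
  data.frame(
    sample_id = colnames(x),
    condition = as.character(cd$condition),
    sex = as.character(cd$sex),
    age_rank = as.character(cd$age_rank),
    region = as.character(cd$region),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Gene annotation of a TrisomyExperiment as a plain table
#'
#' @param x a [TrisomyExperiment-class] object.
#' @param dropUnannotated drop genes with no chromosome assignment?
#' @return A `data.frame` with columns `gene_id` and `chromosome`.
#' @export
geneAnnotation <- function(x, dropUnannotated = TRUE) {
  stopifnot(is(x, "TrisomyExperiment"))
  ann <- data.frame(
    gene_id = rownames(x),
    chromosome = as.character(rowData(x)$chromosome),
    stringsAsFactors = FALSE
  )
  if (dropUnannotated) ann <- ann[!is.na(ann$chromosome), , drop = FALSE]
  row.names(ann) <- NULL
  ann
}
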