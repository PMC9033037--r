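#' Per-array Z-score standardization
#'
#' Standardizes each array (sample column) independently across all genes:
#' the Z-score of gene g on array s is its log2 intensity minus the mean
#' log2 intensity of all genes on that array, divided by their sample
#' standard deviation (n - 1 denominator). Standardizing per array removes
#' array-level location and scale differences, so no separate
#' between-array normalization step is needed.
#'
#' @param x numeric gene x sample matrix of log2 intensities, or a
#'   [TrisomyExperiment-class] (its `"log2"` assay is standardized and the
#'   result stored as assay `"zscore"`).
#' @param ... unused.
#' @return Same shape as the input: a matrix of Z-scores, or the experiment
#'   with a `"zscore"` assay added.
#' @details Every column must have at least two distinct values; a constant
#'   array has no scale and raises an error naming the offending sample.
#'   Unclipped columns have mean 0 and sample SD 1 to within 1e-9.
#' @seealso [clipZScores()], [computeZRatio()]
#' @examples
#' m <- matrix(c(5, 7, 6, 9), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' computeZScores(m) # first column: -sqrt(2)/2, +sqrt(2)/2
#' @rdname computeZScores
#' @export
setMethod("computeZScores", "matrix", function(x, ...) {
  if (nrow(x) < 2L) stop("need at least two genes to standardize an array")
  sds <- apply(x, 2L, stats::sd)
  degenerate <- which(!is.finite(sds) | sds == 0)
  if (length(degenerate)) {
    stop(sprintf(
      "degenerate array: sample '%s' has zero variance across genes",
      colnames(x)[degenerate[1L]] %||% as.character(degenerate[1L])
    ))
  }
  z <- scale(x, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
})

#' @rdname computeZScores
setMethod("computeZScores", "TrisomyExperiment", function(x, ...) {
  assay(x, "zscore") <- computeZScores(assay(x, "log2"))
  x
})

#' Winsorize Z-scores to a symmetric bound
#'
#' Normalizes Z-scores onto the linear scale `[-bound, +bound]` (default
#' bound 3): values beyond the bound are set to the bound, everything else
#' is untouched. Winsorizing rather than dropping outliers keeps the gene
#' universe size fixed, which the downstream percentage denominators rely
#' on.
#'
#' @param x a Z-score matrix, or a [TrisomyExperiment-class] whose
#'   `"zscore"` assay is clipped in place.
#' @param bound positive clip bound on the Z-score scale.
#' @param ... unused.
#' @return The clipped matrix, with the number of altered entries in
#'   `attr(, "nClipped")`; or the experiment with `metadata(x)$clip`
#'   recording `bound` and `nClipped`.
#' @rdname clipZScores
#' @export
setMethod("clipZScores", "matrix", function(x, bound = 3, ...) {
  stopifnot(is.numeric(bound), length(bound) == 1L, bound > 0)
  out <- pmin(pmax(x, -bound), bound)
  attr(out, "nClipped") <- sum(x > bound | x < -bound)
  out
})

#' @rdname clipZScores
setMethod("clipZScores", "TrisomyExperiment", function(x, bound = 3, ...) {
  if (!"zscore" %in% assayNames(x)) {
    stop("run computeZScores() before clipZScores()")
  }
  z <- clipZScores(assay(x, "zscore"), bound = bound)
  n <- attr(z, "nClipped")
  attr(z, "nClipped") <- NULL
  assay(x, "zscore") <- z
  metadata(x)$clip <- list(bound = bound, nClipped = n)
  x
})

#' Per-gene group-mean Z-scores for a DS/control contrast
#'
#' Averages the (clipped) Z-scores per gene within the DS and the control
#' samples of one stratum. The stratum is selected either by an explicit
#' logical/character sample subset (matrix method) or by region / age-rank
#' labels (experiment method); both condition groups must be non-empty
#' after filtering.
#'
#' @param x a Z-score matrix, or a [TrisomyExperiment-class] carrying a
#'   `"zscore"` assay.
#' @param condition (matrix method) vector over columns with values
#'   `"DS"`/`"control"`.
#' @param samples optional subset of columns defining the stratum: logical
#'   over columns, or sample identifiers.
#' @param region,ageRank (experiment method) optional stratum labels; `NULL`
#'   pools all samples, i.e. the whole-brain stratum.
#' @param ... unused.
#' @return A [GroupMeanZ-class] object.
#' @rdname groupMeanZ
#' @export
setMethod("groupMeanZ", "matrix", function(x, condition, samples = NULL, ...) {
  if (length(condition) != ncol(x)) {
    stop("'condition' must have one entry per sample column")
  }
  condition <- as.character(condition)
  sel <- rep(TRUE, ncol(x))
  if (!is.null(samples)) {
    sel <- if (is.logical(samples)) samples else colnames(x) %in% samples
  }
  isDS <- sel & condition == "DS"
  isCon <- sel & condition == "control"
  if (!any(isDS) || !any(isCon)) {
    stop("stratum error: a condition group is empty after filtering")
  }
  new("GroupMeanZ",
    geneIds = rownames(x),
    meanZDS = rowMeans(x[, isDS, drop = FALSE]),
    meanZCon = rowMeans(x[, isCon, drop = FALSE]),
    nDS = sum(isDS), nCon = sum(isCon)
  )
})

#' @rdname groupMeanZ
setMethod("groupMeanZ", "TrisomyExperiment",
  function(x, region = NULL, ageRank = NULL, ...) {
    if (!"zscore" %in% assayNames(x)) {
      stop("run computeZScores() (and clipZScores()) before groupMeanZ()")
    }
    sel <- rep(TRUE, ncol(x))
    if (!is.null(region)) sel <- sel & brainRegion(x) %in% region
    ranks <- as.character(colData(x)$age_rank)
    if (!is.null(ageRank)) sel <- sel & ranks %in% ageRank
    groupMeanZ(assay(x, "zscore"),
      condition = as.character(sampleCondition(x)), samples = sel
    )
  }
)

#' Z-ratio differential expression statistic
#'
#' For each gene the Z-ratio is the difference of its group-mean Z-scores,
#' DS minus control, divided by the sample standard deviation of those
#' differences across all genes in the stratum. The shared denominator
#' makes the vector of Z-ratios have sample standard deviation exactly 1,
#' so the conventional 1.96 normal cutoff applies directly.
#'
#' @param g a [GroupMeanZ-class] object (at least two genes).
#' @param stratum label recorded on the result (`"brain"`, a region code or
#'   an age rank).
#' @return A [ZRatioVector-class].
#' @details If every per-gene difference is identical the denominator is
#'   zero and the contrast is degenerate; an error is raised.
#' @examples
#' g <- new("GroupMeanZ", geneIds = c("a", "b", "c"),
#'          meanZDS = c(-1, 0, 1), meanZCon = c(0, 0, 0),
#'          nDS = 2L, nCon = 2L)
#' zratio(computeZRatio(g)) # -1, 0, 1: the differences already have SD 1
#' @export
computeZRatio <- function(g, stratum = "brain") {
  stopifnot(is(g, "GroupMeanZ"))
  if (length(g@geneIds) < 2L) stop("need at least two genes for a Z-ratio")
  d <- g@meanZDS - g@meanZCon
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) {
    stop("degenerate contrast: all per-gene differences are identical")
  }
  new("ZRatioVector",
    geneIds = g@geneIds, zratio = unname(d / s),
    stratum = as.character(stratum), sdOfDifferences = s
  )
}

#' Call over- and under-expressed genes from a Z-ratio vector
#'
#' Genes with Z-ratio strictly greater than `threshold` are called
#' over-expressed; strictly less than `-threshold`, under-expressed. The
#' default 1.96 is the two-tailed 5% cutoff of the standard normal, the
#' conventional rule for this statistic; values exactly at the threshold
#' are not called.
#'
#' @param z a [ZRatioVector-class].
#' @param threshold positive call cutoff.
#' @return A [CallSet-class].
#' @export
callOverexpressed <- function(z, threshold = 1.96) {
  stopifnot(is(z, "ZRatioVector"), is.numeric(threshold),
            length(threshold) == 1L, threshold > 0)
  new("CallSet",
    stratum = z@stratum, threshold = threshold,
    overexpressed = z@geneIds[z@zratio > threshold],
    underexpressed = z@geneIds[z@zratio < -threshold]
  )
}

#' One-shot Z-ratio for a stratum of a TrisomyExperiment
#'
#' Convenience wrapper running the full statistic for one stratum:
#' standardize per array and winsorize (if not already done), average per
#' condition within the stratum, and form the Z-ratio.
#'
#' @param x a [TrisomyExperiment-class].
#' @param region,ageRank optional stratum selectors; both `NULL` gives the
#'   whole-brain stratum.
#' @param clipBound winsorization bound applied if `x` has no `"zscore"`
#'   assay yet.
#' @param stratum label for the result; defaults to the selector used.
#' @return A [ZRatioVector-class].
#' @export
zratioForStratum <- function(x, region = NULL, ageRank = NULL, clipBound = 3,
                             stratum = NULL) {
  stopifnot(is(x, "TrisomyExperiment"))
  if (!"zscore" %in% assayNames(x)) {
    x <- clipZScores(computeZScores(x), bound = clipBound)
  }
  label <- stratum %||% paste(c(region, ageRank), collapse = "/")
  if (!nzchar(label)) label <- "brain"
  computeZRatio(groupMeanZ(x, region = region, ageRank = ageRank),
    stratum = label
  )
}

#' Write a Z-ratio vector with its calls as TSV
#'
#' Columns `gene_id`, `zratio` (12 significant digits) and `call`
#' (`over`/`under`/`none`), one row per gene in the vector's order.
#'
#' @param z a [ZRatioVector-class].
#' @param calls the matching [CallSet-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeZRatioTSV <- function(z, calls, path) {
  stopifnot(is(z, "ZRatioVector"), is(calls, "CallSet"))
  call <- rep("none", length(z@geneIds))
  call[z@geneIds %in% calls@overexpressed] <- "over"
  call[z@geneIds %in% calls@underexpressed] <- "under"
  tab <- data.frame(
    gene_id = z@geneIds,
    zratio = sprintf("%.12g", z@zratio),
    call = call, stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
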