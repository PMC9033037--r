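#' @rdname computeZScores
#' @export
setGeneric("computeZScores", function(x, ...) standardGeneric("computeZScores"))

#' @rdname clipZScores
#' @export
setGeneric("clipZScores", function(x, bound = 3, ...) {
  standardGeneric("clipZScores")
})

#' @rdname groupMeanZ
#' @export
setGeneric("groupMeanZ", function(x, ...) standardGeneric("groupMeanZ"))

#' @rdname zratioCorrelation
#' @export
setGeneric("zratioCorrelation", function(a, b, ...) {
  standardGeneric("zratioCorrelation")
})

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("zratio", function(x) standardGeneric("zratio"))

#' @rdname accessors
#' @export
setGeneric("stratumLabel", function(x) standardGeneric("stratumLabel"))

#' @rdname accessors
#' @export
setGeneric("sdOfDifferences", function(x) standardGeneric("sdOfDifferences"))

#' @rdname accessors
#' @export
setGeneric("overexpressed", function(x) standardGeneric("overexpressed"))

#' @rdname accessors
#' @export
setGeneric("underexpressed", function(x) standardGeneric("underexpressed"))

#' @rdname accessors
#' @export
setGeneric("callThreshold", function(x) standardGeneric("callThreshold"))

#' @rdname accessors
#' @export
setGeneric("sampleCondition", function(x) standardGeneric("sampleCondition"))

#' @rdname accessors
#' @export
setGeneric("brainRegion", function(x) standardGeneric("brainRegion"))

#' @rdname accessors
#' @export
setGeneric("ageRank", function(x) standardGeneric("ageRank"))
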