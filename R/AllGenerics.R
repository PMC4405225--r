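#' @rdname FundusImage-class
#' @param object,x a FundusImage (or other FundusRank object)
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname FundusImage-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname ImageFeatures-class
#' @export
setGeneric("gsValues", function(x) standardGeneric("gsValues"))

#' @rdname ImageFeatures-class
#' @export
setGeneric("combinedHistograms", function(x) standardGeneric("combinedHistograms"))

#' @rdname ImageFeatures-class
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname ImageFeatures-class
#' @export
setGeneric("extractionTime", function(x) standardGeneric("extractionTime"))

#' @rdname BoundaryHistogram-class
#' @export
setGeneric("histogramValues", function(x) standardGeneric("histogramValues"))

#' @rdname BoundaryHistogram-class
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname IntensityDistribution-class
#' @export
setGeneric("intensityMean", function(x) standardGeneric("intensityMean"))

#' @rdname IntensityDistribution-class
#' @export
setGeneric("intensitySd", function(x) standardGeneric("intensitySd"))

#' @rdname FundusDataset-class
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname FundusDataset-class
#' @export
setGeneric("labels", function(x) standardGeneric("labels"))

#' @rdname FundusDataset-class
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))
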