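#' Construct a FundusImage
#'
#' @param pixels numeric or integer matrix of 8-bit intensities.
#' @param sourceId opaque identifier, e.g. a file name or synthetic label.
#' @return a validated [FundusImage-class] object.
#' @examples
#' img <- FundusImage(matrix(0:3, 2, 2), "toy")
#' dim(img)
#' @export
FundusImage <- function(pixels, sourceId = "unnamed") {
  storage.mode(pixels) <- "integer"
  new("FundusImage", pixels = pixels, sourceId = as.character(sourceId))
}

#' @rdname FundusImage-class
#' @export
setMethod("pixels", "FundusImage", function(x) x@pixels)

#' @rdname FundusImage-class
#' @export
setMethod("sourceId", "FundusImage", function(x) x@sourceId)

#' @rdname FundusImage-class
#' @export
setMethod("dim", "FundusImage", function(x) dim(x@pixels))

setMethod("show", "FundusImage", function(object) {
  cat(sprintf("FundusImage '%s': %d x %d, intensity range [%d, %d]\n",
              object@sourceId, nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels)))
})

#' Construct a WindowConfig
#'
#' @param windowSize pixels per block side (>= 1).
#' @param sMax number of intensity histogram bins (>= 2).
#' @return a validated [WindowConfig-class].
#' @examples
#' WindowConfig(8, 8)
#' @export
WindowConfig <- function(windowSize = 8L, sMax = 2L) {
  new("WindowConfig", windowSize = as.integer(windowSize),
      sMax = as.integer(sMax))
}

setMethod("show", "WindowConfig", function(object) {
  cat(sprintf("WindowConfig: windowSize = %d px, sMax = %d bins\n",
              object@windowSize, object@sMax))
})

#' Construct a FundusDataset
#'
#' @param images list of [FundusImage-class] objects.
#' @param labels data.frame with columns `source_id`, `diseased`,
#'   `severity_grade`.
#' @param masks optional list of logical lesion masks, one per image.
#' @param maxGrade maximum admissible severity grade R.
#' @return a validated [FundusDataset-class].
#' @export
FundusDataset <- function(images, labels, masks = list(), maxGrade = 4L) {
  labels$diseased <- as.integer(labels$diseased)
  labels$severity_grade <- as.integer(labels$severity_grade)
  new("FundusDataset", images = images, labels = labels, masks = masks,
      maxGrade = as.integer(maxGrade))
}

#' @rdname FundusDataset-class
#' @export
setMethod("images", "FundusDataset", function(x) x@images)

#' @rdname FundusDataset-class
#' @export
setMethod("labels", "FundusDataset", function(x) x@labels)

#' @rdname FundusDataset-class
#' @export
setMethod("masks", "FundusDataset", function(x) x@masks)

#' @rdname FundusDataset-class
#' @export
setMethod("length", "FundusDataset", function(x) length(x@images))

#' @rdname FundusDataset-class
#' @param i index vector
#' @param j,drop,... unused
#' @export
setMethod("[", "FundusDataset", function(x, i, j, ..., drop = FALSE) {
  new("FundusDataset", images = x@images[i],
      labels = x@labels[i, , drop = FALSE],
      masks = if (length(x@masks)) x@masks[i] else list(),
      maxGrade = x@maxGrade)
})

setMethod("show", "FundusDataset", function(object) {
  tab <- table(factor(object@labels$severity_grade, levels = 0:object@maxGrade))
  cat(sprintf("FundusDataset: %d images, grades 0..%d\n",
              length(object@images), object@maxGrade))
  cat("  per grade:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
})

#' @rdname ImageFeatures-class
#' @export
setMethod("gsValues", "ImageFeatures", function(x) x@gsValues)

#' @rdname ImageFeatures-class
#' @export
setMethod("combinedHistograms", "ImageFeatures", function(x) x@combinedHistograms)

#' @rdname ImageFeatures-class
#' @export
setMethod("gridShape", "ImageFeatures", function(x) x@gridShape)

#' @rdname ImageFeatures-class
#' @export
setMethod("extractionTime", "ImageFeatures", function(x) x@extractionTimeMs)

#' @rdname ImageFeatures-class
#' @export
setMethod("sourceId", "ImageFeatures", function(x) x@sourceId)

setMethod("show", "ImageFeatures", function(object) {
  cat(sprintf(
    "ImageFeatures '%s': %d x %d blocks, GS range [%.4g, %.4g], %.2f ms\n",
    object@sourceId, object@gridShape[1], object@gridShape[2],
    min(object@gsValues), max(object@gsValues), object@extractionTimeMs))
})

#' @rdname BoundaryHistogram-class
#' @export
setMethod("histogramValues", "BoundaryHistogram", function(x) x@values)

#' @rdname BoundaryHistogram-class
#' @export
setMethod("rawCounts", "BoundaryHistogram", function(x) x@rawCounts)

setMethod("show", "BoundaryHistogram", function(object) {
  cat(sprintf("BoundaryHistogram (%s): %d bins, %d pixels, normalizer %.4g\n",
              object@side, length(object@rawCounts), sum(object@rawCounts),
              object@normalizer))
})

#' Construct an IntensityDistribution
#'
#' @param mu mean intensity on the 0-255 scale.
#' @param sigma intensity standard deviation (> 0).
#' @param fallback whether the whole-image fallback was used.
#' @param nPixels number of pixels summarised.
#' @return a validated [IntensityDistribution-class].
#' @examples
#' IntensityDistribution(215, 12.9)
#' @export
IntensityDistribution <- function(mu, sigma, fallback = FALSE, nPixels = NA_integer_) {
  new("IntensityDistribution", mu = as.numeric(mu), sigma = as.numeric(sigma),
      fallback = fallback, nPixels = as.integer(nPixels))
}

#' @rdname IntensityDistribution-class
#' @export
setMethod("intensityMean", "IntensityDistribution", function(x) x@mu)

#' @rdname IntensityDistribution-class
#' @export
setMethod("intensitySd", "IntensityDistribution", function(x) x@sigma)

setMethod("show", "IntensityDistribution", function(object) {
  cat(sprintf("IntensityDistribution: mu = %.3f, sigma = %.3f (n = %s%s)\n",
              object@mu, object@sigma,
              ifelse(is.na(object@nPixels), "?", object@nPixels),
              if (isTRUE(object@fallback)) ", whole-image fallback" else ""))
})

#' Construct a RankingConfig
#'
#' @param thresholds strictly increasing numeric vector in \[0, 1). The
#'   defaults define five grades (0-4). Thresholds are configuration, not
#'   science: they discretise the continuous severity distance.
#' @return a validated [RankingConfig-class].
#' @examples
#' RankingConfig()
#' @export
RankingConfig <- function(thresholds = c(0.1, 0.25, 0.45, 0.7)) {
  new("RankingConfig", thresholds = as.numeric(thresholds))
}

setMethod("show", "RankingConfig", function(object) {
  cat("RankingConfig: thresholds",
      paste(format(object@thresholds), collapse = ", "),
      sprintf("(grades 0..%d)\n", length(object@thresholds)))
})

setMethod("show", "SeverityScore", function(object) {
  cat(sprintf("SeverityScore: distance = %.6f, rank = %d\n",
              object@distance, object@rank))
})

setMethod("show", "SeverityModel", function(object) {
  cat(sprintf(
    "SeverityModel: %s kernel, grades {%s}, %d features, C = %g\n",
    object@kernel, paste(object@classes, collapse = ","),
    object@featureLength, object@cost))
})
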