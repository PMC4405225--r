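#' @import methods
NULL

#' FundusImage: an 8-bit retinal fundus intensity image
#'
#' The unit every pipeline stage consumes: a single-channel 8-bit intensity
#' grid (row-major, 0-based pixel coordinates in all block arithmetic) plus an
#' opaque provenance identifier. Colour photographs are reduced to one channel
#' at load time ([readFundusImage()]); by convention the green channel, where
#' exudates have the highest contrast.
#'
#' @slot pixels integer matrix, values in \[0, 255\].
#' @slot sourceId character(1), opaque provenance string.
#'
#' @seealso [FundusImage()], [readFundusImage()], [extractFeatures()]
#' @exportClass FundusImage
setClass("FundusImage",
  representation(pixels = "matrix", sourceId = "character"))

setValidity("FundusImage", function(object) {
  p <- object@pixels
  if (nrow(p) < 1L || ncol(p) < 1L)
    return("image must have height >= 1 and width >= 1")
  if (!is.numeric(p))
    return("pixels must be numeric")
  v <- as.vector(p)
  if (anyNA(v))
    return("pixels must not contain NA")
  if (any(v != floor(v)) || any(v < 0) || any(v > 255))
    return("pixel values must be integers in [0, 255]")
  if (length(object@sourceId) != 1L)
    return("sourceId must be a single string")
  TRUE
})

#' FundusDataset: labelled fundus images
#'
#' A list of [FundusImage] objects with per-image disease labels: a binary
#' diseased flag and an ordinal severity grade in `0..maxGrade`. Grade 0 is
#' synonymous with non-diseased (enforced by the validity method). Optionally
#' carries per-image lesion masks (logical matrices), as produced by the
#' synthetic generator.
#'
#' @slot images list of [FundusImage].
#' @slot labels data.frame with columns `source_id`, `diseased` (0/1),
#'   `severity_grade`.
#' @slot masks list of logical matrices (may be empty).
#' @slot maxGrade integer(1), the declared maximum grade R >= 1.
#'
#' @seealso [FundusDataset()], [generateDataset()], [readLabels()]
#' @exportClass FundusDataset
setClass("FundusDataset",
  representation(images = "list", labels = "data.frame", masks = "list",
                 maxGrade = "integer"))

setValidity("FundusDataset", function(object) {
  lab <- object@labels
  need <- c("source_id", "diseased", "severity_grade")
  if (!all(need %in% names(lab)))
    return(sprintf("labels must have columns %s", paste(need, collapse = ", ")))
  if (length(object@images) != nrow(lab))
    return("one label row per image required")
  if (!all(lab$diseased %in% c(0L, 1L)))
    return("diseased flags must be 0 or 1")
  if (length(object@maxGrade) != 1L || object@maxGrade < 1L)
    return("maxGrade must be a single integer >= 1")
  g <- lab$severity_grade
  if (any(g < 0L | g > object@maxGrade))
    return(sprintf("severity grades must lie in [0, %d]", object@maxGrade))
  if (any((g == 0L) != (lab$diseased == 0L)))
    return("severity_grade must be 0 if and only if diseased is 0")
  if (length(object@masks) && length(object@masks) != length(object@images))
    return("masks, when present, must have one entry per image")
  TRUE
})

#' WindowConfig: sliding-window and histogram parameters
#'
#' @slot windowSize integer(1) >= 1, pixels per block side; blocks tile the
#'   image without overlap and edge blocks are truncated.
#' @slot sMax integer(1) >= 2, number of equal-width intensity bins and the
#'   maximum group-sparsity value; both boundary normalisers
#'   (`N/(sMax + 1)` and `N/(sMax - 1)`) must be positive, hence the lower
#'   bound of 2.
#'
#' @seealso [WindowConfig()], [divideIntoBlocks()], [boundaryHistogram()]
#' @exportClass WindowConfig
setClass("WindowConfig",
  representation(windowSize = "integer", sMax = "integer"))

setValidity("WindowConfig", function(object) {
  if (length(object@windowSize) != 1L || object@windowSize < 1L)
    return("windowSize must be a single integer >= 1")
  if (length(object@sMax) != 1L || object@sMax < 2L)
    return("sMax must be a single integer >= 2 (the right-boundary normaliser divides by sMax - 1)")
  TRUE
})

#' BoundaryHistogram: one side's normalised block histogram
#'
#' Raw per-bin pixel counts of one block together with the side-specific
#' normalising constant: `fiCols * fiRows / (sMax + 1)` for the left-boundary
#' scan and `fiRows * fiCols / (sMax - 1)` for the right-boundary scan. The
#' scan direction fixes the accumulation order only; the counts themselves are
#' position-independent.
#'
#' @slot side "left" or "right".
#' @slot rawCounts integer vector of length sMax; sums to the block pixel count.
#' @slot normalizer positive numeric(1).
#' @slot values `rawCounts / normalizer`.
#'
#' @seealso [boundaryHistogram()], [combineHistograms()]
#' @exportClass BoundaryHistogram
setClass("BoundaryHistogram",
  representation(side = "character", rawCounts = "integer",
                 normalizer = "numeric", values = "numeric"))

setValidity("BoundaryHistogram", function(object) {
  if (!object@side %in% c("left", "right"))
    return("side must be 'left' or 'right'")
  if (any(object@rawCounts < 0L))
    return("raw counts must be nonnegative")
  if (object@normalizer <= 0)
    return("normalizer must be positive")
  if (length(object@values) != length(object@rawCounts))
    return("values and rawCounts must have equal length")
  TRUE
})

#' ImageFeatures: per-block group-sparsity feature vector of one image
#'
#' Output of [extractFeatures()]: the combined left+right boundary histogram of
#' every block (one row per block, row-major block order) and each block's
#' group-sparsity value (sum of squared combined-histogram entries), plus the
#' measured wall-clock extraction time. The time is informational only and is
#' never part of a correctness contract.
#'
#' @slot sourceId character(1).
#' @slot gridShape integer(2): block rows, block cols.
#' @slot gsValues numeric vector, one group-sparsity value per block.
#' @slot combinedHistograms numeric matrix, blocks x sMax.
#' @slot extractionTimeMs numeric(1) >= 0.
#'
#' @seealso [extractFeatures()], [groupSparsity()], [writeFeatures()]
#' @exportClass ImageFeatures
setClass("ImageFeatures",
  representation(sourceId = "character", gridShape = "integer",
                 gsValues = "numeric", combinedHistograms = "matrix",
                 extractionTimeMs = "numeric"))

setValidity("ImageFeatures", function(object) {
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    return("gridShape must be two positive integers")
  if (length(object@gsValues) != prod(object@gridShape))
    return("gsValues length must equal block rows x block cols")
  if (nrow(object@combinedHistograms) != length(object@gsValues))
    return("one combined histogram row per block required")
  if (object@extractionTimeMs < 0)
    return("extractionTimeMs must be nonnegative")
  TRUE
})

#' IntensityDistribution: (mu, sigma) summary of candidate-lesion intensities
#'
#' The Gaussian summary consumed by [gaussianDistance()]: mu is the mean
#' intensity (0-255 scale) of the candidate pixel set and sigma its
#' Bessel-corrected standard deviation. sigma is strictly positive by
#' construction (a configurable floor replaces degenerate zero spread). The
#' `fallback` flag records that too few candidate pixels were found and the
#' whole-image distribution was used instead.
#'
#' @slot mu numeric(1), mean intensity.
#' @slot sigma numeric(1) > 0, intensity standard deviation.
#' @slot fallback logical(1).
#' @slot nPixels integer(1), number of pixels summarised.
#'
#' @seealso [lesionDistribution()], [referenceDistribution()],
#'   [gaussianDistance()]
#' @exportClass IntensityDistribution
setClass("IntensityDistribution",
  representation(mu = "numeric", sigma = "numeric", fallback = "logical",
                 nPixels = "integer"))

setValidity("IntensityDistribution", function(object) {
  if (length(object@mu) != 1L || !is.finite(object@mu))
    return("mu must be a single finite number")
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0)
    return("sigma must be a single positive number (the distance divides by sigma1^2 + sigma2^2)")
  TRUE
})

#' RankingConfig: severity-rank thresholds on the distance scale
#'
#' A strictly increasing vector of thresholds in \[0, 1); a distance is
#' assigned rank equal to the number of thresholds it strictly exceeds, so R
#' thresholds define grades 0..R. Ties do not increment the rank.
#'
#' @slot thresholds strictly increasing numeric vector in \[0, 1).
#'
#' @seealso [assignRank()]
#' @exportClass RankingConfig
setClass("RankingConfig", representation(thresholds = "numeric"))

setValidity("RankingConfig", function(object) {
  t <- object@thresholds
  if (length(t) < 1L)
    return("at least one threshold required")
  if (any(t < 0) || any(t >= 1))
    return("thresholds must lie in [0, 1)")
  if (any(diff(t) <= 0))
    return("thresholds must be strictly increasing")
  TRUE
})

#' SeverityScore: distance and assigned rank for one image
#'
#' @slot distance numeric(1) in \[0, 1).
#' @slot rank integer(1) in 0..R.
#'
#' @seealso [assignRank()]
#' @exportClass SeverityScore
setClass("SeverityScore",
  representation(distance = "numeric", rank = "integer"))

#' SeverityModel: one-vs-rest support-vector severity ranker
#'
#' A multi-class soft-margin support-vector classifier over severity grades.
#' One binary machine is trained per grade (that grade against the rest); the
#' quadratic programs are solved by \pkg{kernlab}, after which the support
#' vectors, coefficients and intercepts are extracted so that the decision
#' function (and JSON persistence) are computed entirely by this package. A
#' new feature vector is assigned the grade whose machine gives the largest
#' decision value.
#'
#' @slot kernel "hellinger_affinity" or "rbf".
#' @slot classes integer vector of trained grade labels, ascending.
#' @slot featureLength integer(1), expected feature-vector length.
#' @slot machines list, one per class: support-vector matrix, coefficients,
#'   intercept, orientation sign.
#' @slot cost numeric(1), soft-margin cost C.
#' @slot gamma numeric(1), RBF bandwidth (NA for the affinity kernel).
#'
#' @seealso [trainSeverityModel()], [predictRank()], [writeSeverityModel()]
#' @exportClass SeverityModel
setClass("SeverityModel",
  representation(kernel = "character", classes = "integer",
                 featureLength = "integer", machines = "list",
                 cost = "numeric", gamma = "numeric"))

setValidity("SeverityModel", function(object) {
  if (!object@kernel %in% c("hellinger_affinity", "rbf"))
    return("kernel must be 'hellinger_affinity' or 'rbf'")
  if (length(object@classes) < 2L)
    return("a trained model must know at least two grades")
  if (length(object@machines) != length(object@classes))
    return("one binary machine per class required")
  TRUE
})
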