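## Severity scoring: a closed-form Gaussian overlap distance between the
## candidate-lesion intensity distribution of a test image and a healthy
## reference, thresholded into ordinal disease ranks.

#' Gaussian overlap distance between two intensity distributions
#'
#' The closed-form distance
#' \deqn{1 - \sqrt{\frac{2\sigma_1\sigma_2}{\sigma_1^2+\sigma_2^2}}
#'   \exp\!\left(-\frac{1}{4}\frac{(\mu_1-\mu_2)^2}{\sigma_1^2+\sigma_2^2}\right)}
#' i.e. one minus the Hellinger affinity \eqn{\int\sqrt{p\,q}} of two normal
#' densities (the squared Hellinger distance). It is symmetric, lies in
#' \[0, 1), equals 0 exactly when the two distributions coincide, and grows
#' both with the mean separation (how far the disease has spread) and with
#' the mismatch in spread (the depth of the affected portion).
#'
#' @param d1,d2 [IntensityDistribution-class] objects.
#' @return numeric(1) in \[0, 1).
#' @examples
#' gaussianDistance(IntensityDistribution(0, 1), IntensityDistribution(2, 1))
#' # 1 - exp(-0.5) = 0.3934693
#' @export
gaussianDistance <- function(d1, d2) {
  stopifnot(is(d1, "IntensityDistribution"), is(d2, "IntensityDistribution"))
  s1 <- d1@sigma; s2 <- d2@sigma
  if (s1 <= 0 || s2 <= 0) stop("sigma must be positive")
  ss <- s1^2 + s2^2
  1 - sqrt(2 * s1 * s2 / ss) * exp(-0.25 * (d1@mu - d2@mu)^2 / ss)
}

## Candidate-lesion pixel selection shared by lesionDistribution and
## referenceDistribution. Blocks darker than fovFloor on average are treated
## as outside the camera aperture (the black surround of a fundus photograph)
## and never contribute candidates. Among the remaining blocks the top
## `fraction` by group-sparsity value are kept (tie-inclusive: the most
## uniform blocks, where lesion and disc interiors live); their pixels in the
## top `topBins` occupied intensity bins are the candidates.
candidateLesionPixels <- function(image, features, config,
                                  fraction = 0.1, topBins = 1L,
                                  fovFloor = 32) {
  p <- pixels(image)
  stopifnot(length(gsValues(features)) >= 1L)
  blocks <- divideIntoBlocks(image, config)
  if (nrow(blocks) != length(gsValues(features)))
    stop("features were not computed from this image/config (block count mismatch)")
  gs <- gsValues(features)
  blockPix <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    as.vector(p[b$rowStart + seq_len(b$fiRows), b$colStart + seq_len(b$fiCols)])
  })
  inField <- vapply(blockPix, mean, numeric(1)) >= fovFloor
  if (!any(inField)) return(integer(0))
  cut <- stats::quantile(gs[inField], 1 - fraction, names = FALSE)
  sel <- inField & gs >= cut
  pool <- unlist(blockPix[sel], use.names = FALSE)
  occ <- sort(unique(intensityBin(pool, config@sMax)))
  keep <- occ[occ > max(occ) - topBins]
  pool[intensityBin(pool, config@sMax) %in% keep]
}

#' Candidate-lesion intensity distribution of an image
#'
#' Selects candidate-lesion pixels as the pixels in the top-intensity occupied
#' bins of the most uniform blocks (top `fraction` of group-sparsity values,
#' tie-inclusive, restricted to blocks inside the camera field of view) and
#' summarises them by their sample mean and Bessel-corrected standard
#' deviation. With fewer than 2 candidate pixels the whole-image distribution
#' is returned with the `fallback` flag set. A degenerate spread is clamped to
#' `sigmaFloor` with a warning so the distance stays defined.
#'
#' This selection is the package's explicit bridge from block features to the
#' (mu, sigma) pair the distance consumes; see the methods vignette for the
#' rationale.
#'
#' @param image a [FundusImage-class].
#' @param features the [ImageFeatures-class] extracted from `image` with
#'   `config`.
#' @param config the same [WindowConfig-class] used for extraction.
#' @param fraction fraction of in-field blocks kept by group-sparsity rank.
#' @param topBins number of top occupied intensity bins pooled.
#' @param fovFloor mean block intensity below which a block is considered
#'   outside the camera aperture.
#' @param sigmaFloor lower clamp for the standard deviation, in intensity
#'   units.
#' @return an [IntensityDistribution-class].
#' @export
lesionDistribution <- function(image, features, config,
                               fraction = 0.1, topBins = 1L, fovFloor = 32,
                               sigmaFloor = 0.5) {
  cand <- candidateLesionPixels(image, features, config, fraction, topBins,
                                fovFloor)
  fallback <- length(cand) < 2L
  if (fallback) cand <- as.vector(pixels(image))
  mu <- mean(cand)
  sg <- stats::sd(cand)
  if (!is.finite(sg) || sg < sigmaFloor) {
    warning("degenerate intensity spread; clamping sigma to ", sigmaFloor)
    sg <- sigmaFloor
  }
  IntensityDistribution(mu, sg, fallback = fallback, nPixels = length(cand))
}

#' Healthy reference intensity distribution
#'
#' Pools the candidate-lesion pixels of every non-diseased image in the
#' dataset and returns the pooled mean and Bessel-corrected standard
#' deviation. This is the second argument of [gaussianDistance()]: severity is
#' the departure of a test image's candidate distribution from this healthy
#' baseline.
#'
#' @param dataset a [FundusDataset-class] containing at least one
#'   non-diseased image.
#' @param config a [WindowConfig-class].
#' @param featuresList optional precomputed list of [ImageFeatures-class]
#'   (one per dataset image) to avoid re-extraction.
#' @inheritParams lesionDistribution
#' @return an [IntensityDistribution-class].
#' @export
referenceDistribution <- function(dataset, config, featuresList = NULL,
                                  fraction = 0.1, topBins = 1L, fovFloor = 32,
                                  sigmaFloor = 0.5) {
  stopifnot(is(dataset, "FundusDataset"))
  healthy <- which(labels(dataset)$diseased == 0L)
  if (!length(healthy))
    stop("reference distribution requires at least one non-diseased image")
  pool <- unlist(lapply(healthy, function(i) {
    img <- images(dataset)[[i]]
    f <- if (is.null(featuresList)) extractFeatures(img, config)
         else featuresList[[i]]
    cand <- candidateLesionPixels(img, f, config, fraction, topBins, fovFloor)
    if (length(cand) < 2L) cand <- as.vector(pixels(img))
    cand
  }), use.names = FALSE)
  mu <- mean(pool)
  sg <- stats::sd(pool)
  if (!is.finite(sg) || sg < sigmaFloor) {
    warning("degenerate reference spread; clamping sigma to ", sigmaFloor)
    sg <- sigmaFloor
  }
  IntensityDistribution(mu, sg, nPixels = length(pool))
}

#' Assign a severity rank from a distance
#'
#' The rank is the number of thresholds the distance strictly exceeds; a
#' distance exactly equal to a threshold does not increment the rank.
#' Monotone nondecreasing in the distance for fixed thresholds.
#'
#' @param distance numeric(1) in \[0, 1).
#' @param config a [RankingConfig-class].
#' @return a [SeverityScore-class].
#' @examples
#' assignRank(0.39, RankingConfig(c(0.1, 0.3, 0.5)))  # rank 2
#' @export
assignRank <- function(distance, config = RankingConfig()) {
  stopifnot(is(config, "RankingConfig"), length(distance) == 1L,
            is.finite(distance), distance >= 0, distance < 1)
  new("SeverityScore", distance = as.numeric(distance),
      rank = sum(distance > config@thresholds))
}

#' Distance-based severity report for a dataset
#'
#' Scores every image by its Gaussian overlap distance to the healthy
#' reference built from `reference` (or from the dataset's own non-diseased
#' images) and assigns ranks via `rankingConfig`.
#'
#' @param dataset a [FundusDataset-class].
#' @param config a [WindowConfig-class].
#' @param rankingConfig a [RankingConfig-class].
#' @param reference optional [IntensityDistribution-class] healthy baseline.
#' @param featuresList optional precomputed list of [ImageFeatures-class].
#' @inheritParams lesionDistribution
#' @return data.frame with columns `source_id`, `distance`, `rank`.
#' @export
severityReport <- function(dataset, config, rankingConfig = RankingConfig(),
                           reference = NULL, featuresList = NULL,
                           fraction = 0.1, topBins = 1L, fovFloor = 32,
                           sigmaFloor = 0.5) {
  stopifnot(is(dataset, "FundusDataset"))
  if (is.null(featuresList))
    featuresList <- lapply(images(dataset), extractFeatures, config = config)
  if (is.null(reference))
    reference <- referenceDistribution(dataset, config, featuresList,
                                       fraction, topBins, fovFloor, sigmaFloor)
  rows <- lapply(seq_along(images(dataset)), function(i) {
    d <- lesionDistribution(images(dataset)[[i]], featuresList[[i]], config,
                            fraction, topBins, fovFloor, sigmaFloor)
    dist <- gaussianDistance(d, reference)
    sc <- assignRank(dist, rankingConfig)
    data.frame(source_id = sourceId(images(dataset)[[i]]),
               distance = dist, rank = sc@rank)
  })
  do.call(rbind, rows)
}
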