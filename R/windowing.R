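## Sliding-window block division, boundary histograms and the group-sparsity
## feature. Blocks tile the image without overlap (stride = window size);
## edge blocks are truncated to the image rather than padded, so no fabricated
## intensities enter the histograms.

## Intensity bin index in 0..(sMax-1): sMax equal-width bins on [0, 256),
## final bin closed at 255. Exact in doubles for 8-bit inputs.
intensityBin <- function(p, sMax) floor(p * sMax / 256)

#' Divide an image into non-overlapping sliding-window blocks
#'
#' Enumerates a `ceiling(height / windowSize)` by `ceiling(width / windowSize)`
#' grid of blocks in row-major order. Edge blocks are truncated so that every
#' pixel belongs to exactly one block. Coordinates are 0-based and extents
#' half-open.
#'
#' @param image a [FundusImage-class].
#' @param config a [WindowConfig-class].
#' @return a data.frame with one row per block: `rowStart`, `colStart`
#'   (0-based), `fiRows`, `fiCols` (block height and width in pixels).
#' @examples
#' img <- FundusImage(matrix(0L, 25, 25))
#' nrow(divideIntoBlocks(img, WindowConfig(10, 4)))  # 3 x 3 grid
#' @export
divideIntoBlocks <- function(image, config) {
  stopifnot(is(image, "FundusImage"), is(config, "WindowConfig"))
  h <- nrow(pixels(image)); w <- ncol(pixels(image))
  ws <- config@windowSize
  rs <- seq.int(0L, h - 1L, by = ws)
  cs <- seq.int(0L, w - 1L, by = ws)
  grid <- expand.grid(colStart = cs, rowStart = rs)[, 2:1]  # row-major
  grid$fiRows <- pmin(ws, h - grid$rowStart)
  grid$fiCols <- pmin(ws, w - grid$colStart)
  rownames(grid) <- NULL
  grid
}

#' Boundary histogram of one block
#'
#' Partitions the 8-bit intensity range into `sMax` equal-width bins and
#' counts the block's pixels per bin, visiting columns left-to-right for the
#' left boundary and right-to-left for the right boundary (the scan order
#' fixes the accumulation direction only; it cannot change the counts). The
#' counts are divided by the side's normalising constant:
#' `fiCols * fiRows / (sMax + 1)` on the left and
#' `fiRows * fiCols / (sMax - 1)` on the right.
#'
#' @param image a [FundusImage-class].
#' @param block one row of [divideIntoBlocks()] output (data.frame or list).
#' @param config a [WindowConfig-class].
#' @param side `"left"` or `"right"`.
#' @return a [BoundaryHistogram-class].
#' @examples
#' img <- FundusImage(matrix(0L, 4, 4))
#' cfg <- WindowConfig(4, 4)
#' b <- divideIntoBlocks(img, cfg)[1, ]
#' histogramValues(boundaryHistogram(img, b, cfg, "left"))  # 5 0 0 0
#' @export
boundaryHistogram <- function(image, block, config, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(is(image, "FundusImage"), is(config, "WindowConfig"))
  p <- pixels(image)
  rows <- block$rowStart + seq_len(block$fiRows)
  colScan <- block$colStart + seq_len(block$fiCols)
  if (max(rows) > nrow(p) || max(colScan) > ncol(p) ||
      block$rowStart < 0L || block$colStart < 0L)
    stop("block lies outside its parent image")
  if (side == "right") colScan <- rev(colScan)
  sMax <- config@sMax
  counts <- integer(sMax)
  for (cc in colScan) {  # accumulate column by column in scan order
    bins <- intensityBin(p[rows, cc], sMax)
    counts <- counts + tabulate(bins + 1L, nbins = sMax)
  }
  n <- block$fiRows * block$fiCols
  normalizer <- if (side == "left") n / (sMax + 1) else n / (sMax - 1)
  new("BoundaryHistogram", side = side, rawCounts = counts,
      normalizer = normalizer, values = counts / normalizer)
}

#' Combine left and right boundary histograms
#'
#' Elementwise sum of the two normalised boundary histograms of one block,
#' yielding the combined per-bin feature the group-sparsity statistic is
#' computed from.
#'
#' @param left,right [BoundaryHistogram-class] objects for the same block.
#' @return numeric vector of length `sMax`.
#' @export
combineHistograms <- function(left, right) {
  stopifnot(is(left, "BoundaryHistogram"), is(right, "BoundaryHistogram"))
  if (left@side != "left" || right@side != "right")
    stop("arguments must be a left and a right boundary histogram, in that order")
  if (length(left@values) != length(right@values))
    stop("histograms have mismatched bin counts")
  if (sum(left@rawCounts) != sum(right@rawCounts))
    stop("histograms do not come from the same block (pixel counts differ)")
  left@values + right@values
}

#' Group-sparsity value of a combined histogram
#'
#' The sum of squared combined-histogram entries. It is maximal for a block
#' whose pixels all fall in one intensity bin and decreases as the block's
#' mass spreads over bins, so lesion and vessel boundaries depress it.
#' Strictly positive for any nonempty block.
#'
#' @param combined numeric vector of finite values.
#' @return nonnegative numeric(1).
#' @examples
#' groupSparsity(c(1, 2))  # 5
#' @export
groupSparsity <- function(combined) {
  if (!is.numeric(combined) || !all(is.finite(combined)))
    stop("combined histogram must be a vector of finite numbers")
  sum(combined^2)
}

#' Extract the per-block group-sparsity feature vector of an image
#'
#' Runs the full windowing stage: block division, left and right boundary
#' histograms per block, their combination, and the group-sparsity value,
#' in row-major block order. A single vectorised pass over the pixel grid is
#' used; it is bin-for-bin identical to the per-block operations. Wall-clock
#' time is recorded in `extractionTimeMs` (informational only).
#'
#' @param image a [FundusImage-class].
#' @param config a [WindowConfig-class].
#' @return an [ImageFeatures-class].
#' @examples
#' f <- extractFeatures(FundusImage(matrix(0L, 20, 20)), WindowConfig(10, 4))
#' gsValues(f)  # 64 for each of the 4 blocks
#' @export
extractFeatures <- function(image, config) {
  stopifnot(is(image, "FundusImage"), is(config, "WindowConfig"))
  t0 <- proc.time()[["elapsed"]]
  p <- pixels(image)
  h <- nrow(p); w <- ncol(p)
  ws <- config@windowSize; sMax <- config@sMax
  nbr <- ceiling(h / ws); nbc <- ceiling(w / ws)
  nBlocks <- nbr * nbc
  ## 0-based row-major block id of every pixel
  br <- (seq_len(h) - 1L) %/% ws
  bc <- (seq_len(w) - 1L) %/% ws
  gid <- outer(br, bc, function(r, c) r * nbc + c)
  bins <- intensityBin(p, sMax)
  counts <- tabulate(gid * sMax + bins + 1L, nbins = nBlocks * sMax)
  countsM <- t(matrix(counts, nrow = sMax))           # blocks x sMax
  n <- rowSums(countsM)                                # pixels per block
  leftM <- countsM / (n / (sMax + 1))
  rightM <- countsM / (n / (sMax - 1))
  combined <- leftM + rightM
  gs <- rowSums(combined^2)
  ms <- (proc.time()[["elapsed"]] - t0) * 1000
  new("ImageFeatures", sourceId = sourceId(image),
      gridShape = as.integer(c(nbr, nbc)), gsValues = gs,
      combinedHistograms = combined,
      extractionTimeMs = ms)
}
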