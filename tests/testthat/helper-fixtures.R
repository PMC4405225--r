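## Shared fixtures and the naive reference implementation of the windowing
## stage (independent double-loop oracle).

## Naive per-pixel reference for the whole windowing stage: enumerate the
## block grid, bin every pixel with an explicit double loop, normalise by the
## two boundary constants and square-sum the combined histogram.
naiveExtract <- function(mat, windowSize, sMax) {
  h <- nrow(mat); w <- ncol(mat)
  nbr <- ceiling(h / windowSize); nbc <- ceiling(w / windowSize)
  counts <- list(); combined <- list(); gs <- numeric(0)
  blk <- 0L
  for (bi in seq_len(nbr)) {
    for (bj in seq_len(nbc)) {
      blk <- blk + 1L
      r0 <- (bi - 1L) * windowSize
      c0 <- (bj - 1L) * windowSize
      nr <- min(windowSize, h - r0); nc <- min(windowSize, w - c0)
      cnt <- integer(sMax)
      for (i in seq_len(nr)) {
        for (j in seq_len(nc)) {
          v <- mat[r0 + i, c0 + j]
          k <- floor(v * sMax / 256) + 1  # bins on [0, 256), last bin closed
          cnt[k] <- cnt[k] + 1L
        }
      }
      n <- nr * nc
      lv <- cnt / (n / (sMax + 1))
      rv <- cnt / (n / (sMax - 1))
      counts[[blk]] <- cnt
      combined[[blk]] <- lv + rv
      gs[blk] <- sum((lv + rv)^2)
    }
  }
  list(counts = counts, combined = do.call(rbind, combined), gs = gs)
}

randomImage <- function(h, w) {
  FundusImage(matrix(sample(0:255, h * w, replace = TRUE), h, w),
              sprintf("rand_%dx%d", h, w))
}

## ASCII PGM (P2) writer, independent of the package's binary writer
writeAsciiPGM <- function(mat, path) {
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), "255",
               paste(as.vector(t(mat)), collapse = " ")), path)
}

## ASCII PPM (P3) writer for a h x w x 3 array
writeAsciiPPM <- function(arr, path) {
  vals <- as.vector(aperm(arr, c(3, 2, 1)))  # RGB interleaved, row-major
  writeLines(c("P3", paste(dim(arr)[2], dim(arr)[1]), "255",
               paste(vals, collapse = " ")), path)
}

## small labelled dataset for model tests (shared across files; generation is
## seeded, so repeated calls are identical)
smallBenchmark <- function(nPerGrade = 6, grades = 0:4, seed = 301,
                           spec = syntheticSpec(height = 128L, width = 128L)) {
  generateDataset(nPerGrade, grades, baseSpec = spec, seed = seed)
}
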