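test_that("block division tiles the image exactly, truncating edge blocks", {
  img <- FundusImage(matrix(0L, 100, 100))
  b <- divideIntoBlocks(img, WindowConfig(10, 4))
  expect_equal(nrow(b), 100L)
  expect_true(all(b$fiRows == 10L & b$fiCols == 10L))

  b <- divideIntoBlocks(FundusImage(matrix(0L, 25, 25)), WindowConfig(10, 4))
  expect_equal(nrow(b), 9L)
  expect_equal(unlist(b[9, ], use.names = FALSE), c(20L, 20L, 5L, 5L))

  b <- divideIntoBlocks(FundusImage(matrix(0L, 1, 1)), WindowConfig(7, 4))
  expect_equal(nrow(b), 1L)
  expect_equal(b$fiRows, 1L)
})

test_that("tiling partitions the pixel grid for random images and configs", {
  set.seed(42)
  for (rep in 1:25) {
    h <- sample(1:40, 1); w <- sample(1:40, 1)
    ws <- sample(1:12, 1)
    img <- randomImage(h, w)
    b <- divideIntoBlocks(img, WindowConfig(ws, 4))
    expect_equal(sum(b$fiRows * b$fiCols), h * w)
    seen <- matrix(0L, h, w)
    for (i in seq_len(nrow(b)))
      seen[b$rowStart[i] + seq_len(b$fiRows[i]),
           b$colStart[i] + seq_len(b$fiCols[i])] <-
        seen[b$rowStart[i] + seq_len(b$fiRows[i]),
             b$colStart[i] + seq_len(b$fiCols[i])] + 1L
    expect_true(all(seen == 1L))
  }
})

test_that("boundary histograms normalise counts by the side constants", {
  img <- FundusImage(matrix(0L, 4, 4))
  cfg <- WindowConfig(4, 4)
  b <- divideIntoBlocks(img, cfg)[1, ]
  lh <- boundaryHistogram(img, b, cfg, "left")
  expect_identical(rawCounts(lh), c(16L, 0L, 0L, 0L))
  expect_equal(lh@normalizer, 3.2)
  expect_equal(histogramValues(lh), c(5, 0, 0, 0))
  rh <- boundaryHistogram(img, b, cfg, "right")
  expect_equal(histogramValues(rh), c(3, 0, 0, 0))

  ## one pixel per bin by construction
  img2 <- FundusImage(matrix(c(0L, 64L, 128L, 192L), 2, 2))
  cfg2 <- WindowConfig(2, 4)
  b2 <- divideIntoBlocks(img2, cfg2)[1, ]
  expect_identical(rawCounts(boundaryHistogram(img2, b2, cfg2, "left")),
                   rep(1L, 4))

  ## combination is the elementwise sum, and the group sparsity its square sum
  expect_equal(combineHistograms(lh, rh), c(8, 0, 0, 0))
  expect_equal(groupSparsity(c(8, 0, 0, 0)), 64)
  expect_equal(groupSparsity(c(1, 2)), 5)
  expect_equal(groupSparsity(rep(0, 4)), 0)
  expect_error(combineHistograms(rh, lh), "left and a right")
})

test_that("raw counts are conserved and scan-direction invariant", {
  set.seed(7)
  for (rep in 1:20) {
    img <- randomImage(sample(3:30, 1), sample(3:30, 1))
    cfg <- WindowConfig(sample(2:9, 1), sample(c(2, 4, 8), 1))
    blocks <- divideIntoBlocks(img, cfg)
    for (i in sample(nrow(blocks), min(4, nrow(blocks)))) {
      lh <- boundaryHistogram(img, blocks[i, ], cfg, "left")
      rh <- boundaryHistogram(img, blocks[i, ], cfg, "right")
      expect_equal(sum(rawCounts(lh)), blocks$fiRows[i] * blocks$fiCols[i])
      expect_identical(rawCounts(lh), rawCounts(rh))
      expect_equal(groupSparsity(combineHistograms(lh, rh)) > 0, TRUE)
    }
  }
})

test_that("extractFeatures matches the naive per-pixel oracle", {
  ## frozen case from the oracle: 20x20 constant image, 4 blocks of 100 px,
  ## combined bin value 100/(100/5) + 100/(100/3) = 8, GS = 64
  f <- extractFeatures(FundusImage(matrix(0L, 20, 20)), WindowConfig(10, 4))
  expect_equal(gsValues(f), rep(64, 4))

  set.seed(99)
  for (rep in 1:10) {
    h <- sample(1:32, 1); w <- sample(1:32, 1)
    ws <- sample(1:9, 1); s <- sample(c(2, 4, 8), 1)
    img <- randomImage(h, w)
    f <- extractFeatures(img, WindowConfig(ws, s))
    ref <- naiveExtract(pixels(img), ws, s)
    expect_equal(gsValues(f), ref$gs, tolerance = 1e-9)
    expect_equal(unname(combinedHistograms(f)), unname(ref$combined),
                 tolerance = 1e-9)
  }
})

test_that("block features are local: permuting whole blocks permutes GS values", {
  set.seed(5)
  mat <- matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24)
  cfg <- WindowConfig(8, 4)
  ## swap two whole 8x8 blocks
  mat2 <- mat
  mat2[1:8, 1:8] <- mat[9:16, 9:16]
  mat2[9:16, 9:16] <- mat[1:8, 1:8]
  g1 <- sort(gsValues(extractFeatures(FundusImage(mat), cfg)))
  g2 <- sort(gsValues(extractFeatures(FundusImage(mat2), cfg)))
  expect_equal(g1, g2)
  ## determinism of the values (timing may differ)
  expect_identical(gsValues(extractFeatures(FundusImage(mat), cfg)),
                   gsValues(extractFeatures(FundusImage(mat), cfg)))
})

test_that("doubling both block dimensions scales counts by 4 on constant images", {
  cfg1 <- WindowConfig(6, 4); cfg2 <- WindowConfig(12, 4)
  i1 <- FundusImage(matrix(200L, 6, 6)); i2 <- FundusImage(matrix(200L, 12, 12))
  c1 <- rawCounts(boundaryHistogram(i1, divideIntoBlocks(i1, cfg1)[1, ], cfg1, "left"))
  c2 <- rawCounts(boundaryHistogram(i2, divideIntoBlocks(i2, cfg2)[1, ], cfg2, "left"))
  expect_identical(c2, 4L * c1)
  ## normalised values are scale-free, so GS is unchanged on constant images
  expect_equal(gsValues(extractFeatures(i1, cfg1)),
               gsValues(extractFeatures(i2, cfg2)))
})

test_that("degenerate configurations are rejected", {
  expect_error(WindowConfig(0, 4), "windowSize")
  expect_error(WindowConfig(4, 1), "sMax")
})
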