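test_that("the Gaussian overlap distance matches its closed-form examples", {
  d <- function(m1, s1, m2, s2)
    gaussianDistance(IntensityDistribution(m1, s1), IntensityDistribution(m2, s2))
  expect_equal(d(5, 2, 5, 2), 0)
  expect_equal(d(0, 1, 2, 1), 1 - exp(-0.5))
  expect_equal(d(0, 1, 0, 3), 1 - sqrt(6 / 10))
})

test_that("the distance is symmetric, bounded, zero only at identity and mean-monotone", {
  set.seed(21)
  for (rep in 1:50) {
    m1 <- runif(1, 0, 255); m2 <- runif(1, 0, 255)
    s1 <- runif(1, 0.5, 64); s2 <- runif(1, 0.5, 64)
    a <- gaussianDistance(IntensityDistribution(m1, s1), IntensityDistribution(m2, s2))
    b <- gaussianDistance(IntensityDistribution(m2, s2), IntensityDistribution(m1, s1))
    expect_equal(a, b)
    expect_true(a >= 0 && a < 1)
    if (abs(m1 - m2) > 1e-9 || abs(s1 - s2) > 1e-9) expect_gt(a, 0)
    ## strictly increasing in |mu1 - mu2| at fixed sigmas
    a2 <- gaussianDistance(IntensityDistribution(m1, s1),
                           IntensityDistribution(m2 + sign(m2 - m1 + 1e-12) * 5, s2))
    expect_gt(a2, a)
    ## equal-mean closed form
    expect_equal(gaussianDistance(IntensityDistribution(m1, s1),
                                  IntensityDistribution(m1, s2)),
                 1 - sqrt(2 * s1 * s2 / (s1^2 + s2^2)))
  }
  expect_error(IntensityDistribution(0, 0), "positive")
})

test_that("the closed form equals one minus the numerically integrated Hellinger affinity", {
  set.seed(33)
  for (rep in 1:30) {
    m1 <- runif(1, 0, 255); m2 <- runif(1, 0, 255)
    s1 <- runif(1, 0.5, 64); s2 <- runif(1, 0.5, 64)
    affinity <- stats::integrate(function(x)
      sqrt(stats::dnorm(x, m1, s1) * stats::dnorm(x, m2, s2)),
      lower = min(m1 - 15 * s1, m2 - 15 * s2),
      upper = max(m1 + 15 * s1, m2 + 15 * s2), rel.tol = 1e-10)$value
    expect_equal(gaussianDistance(IntensityDistribution(m1, s1),
                                  IntensityDistribution(m2, s2)),
                 1 - affinity, tolerance = 1e-6)
  }
})

test_that("candidate-lesion selection recovers a planted bright block", {
  ## one 2x2 block holds {200,210,220,230}; the rest of the image is dark
  ## surround (excluded by the field-of-view floor)
  mat <- matrix(10L, 4, 4)
  mat[1:2, 3:4] <- c(200L, 210L, 220L, 230L)
  img <- FundusImage(mat, "planted")
  cfg <- WindowConfig(2, 4)
  f <- extractFeatures(img, cfg)
  d <- lesionDistribution(img, f, cfg)
  expect_equal(intensityMean(d), 215)
  expect_equal(intensitySd(d), sqrt(500 / 3), tolerance = 1e-9)
  expect_false(d@fallback)
  expect_true(intensityMean(d) >= min(mat) && intensityMean(d) <= max(mat))
})

test_that("degenerate images fall back to the clamped whole-image summary", {
  img <- FundusImage(matrix(100L, 16, 16), "flat")
  cfg <- WindowConfig(8, 2)
  f <- extractFeatures(img, cfg)
  expect_warning(d <- lesionDistribution(img, f, cfg), "clamping")
  expect_equal(intensityMean(d), 100)
  expect_equal(intensitySd(d), 0.5)

  ## an all-dark image has no in-field blocks at all: whole-image fallback
  dark <- FundusImage(matrix(5L, 16, 16), "dark")
  fd <- extractFeatures(dark, cfg)
  expect_warning(dd <- lesionDistribution(dark, fd, cfg), "clamping")
  expect_true(dd@fallback)
  expect_equal(intensityMean(dd), 5)
})

test_that("the healthy reference pools candidate pixels across healthy images", {
  img <- FundusImage(matrix(100L, 16, 16), "h1")
  img2 <- FundusImage(matrix(100L, 16, 16), "h2")
  lab <- data.frame(source_id = c("h1", "h2"), diseased = c(0L, 0L),
                    severity_grade = c(0L, 0L))
  cfg <- WindowConfig(8, 2)
  ds1 <- FundusDataset(list(img), lab[1, ])
  ds2 <- FundusDataset(list(img, img2), lab)
  expect_warning(r1 <- referenceDistribution(ds1, cfg), "clamping")
  expect_warning(r2 <- referenceDistribution(ds2, cfg), "clamping")
  expect_equal(intensityMean(r1), 100)
  expect_equal(intensitySd(r1), 0.5)
  ## duplicated pixels change nothing
  expect_equal(intensityMean(r2), intensityMean(r1))
  expect_equal(intensitySd(r2), intensitySd(r1))
  sick <- FundusDataset(list(img), data.frame(source_id = "h1", diseased = 1L,
                                              severity_grade = 2L))
  expect_error(referenceDistribution(sick, cfg), "non-diseased")
})

test_that("rank assignment counts strictly exceeded thresholds", {
  rc <- RankingConfig(c(0.1, 0.3, 0.5))
  expect_equal(assignRank(0, rc)@rank, 0L)
  expect_equal(assignRank(0.393469, rc)@rank, 2L)
  expect_equal(assignRank(0.3, rc)@rank, 1L)  # tie does not increment
  ## monotone nondecreasing in distance
  ranks <- vapply(seq(0, 0.99, by = 0.01),
                  function(x) assignRank(x, rc)@rank, integer(1))
  expect_true(all(diff(ranks) >= 0))
  expect_error(RankingConfig(c(0.5, 0.3)), "increasing")
  expect_error(RankingConfig(c(0.5, 1.2)), "\\[0, 1\\)")
})
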