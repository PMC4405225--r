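test_that("confusion counts and the rate metrics match hand-computed cases", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cc), list(tp = 2L, fp = 0L, tn = 2L, fn = 0L),
               ignore_attr = TRUE)
  cc2 <- confusionCounts(c(1, 0), c(0, 1))
  expect_equal(c(cc2$tp, cc2$fp, cc2$tn, cc2$fn), c(0L, 1L, 0L, 1L))

  set.seed(6)
  for (rep in 1:10) {
    n <- sample(3:40, 1)
    p <- sample(0:1, n, replace = TRUE); t <- sample(0:1, n, replace = TRUE)
    cc <- confusionCounts(p, t)
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, n)
  }

  expect_equal(sensitivity(structure(list(tp = 9L, fp = 0L, tn = 0L, fn = 1L),
                                     class = "ConfusionCounts")), 90)
  expect_equal(specificity(structure(list(tp = 0L, fp = 2L, tn = 8L, fn = 0L),
                                     class = "ConfusionCounts")), 80)
  ## sensitivity ignores fp/tn, specificity ignores tp/fn
  expect_equal(sensitivity(structure(list(tp = 7L, fp = 5L, tn = 11L, fn = 3L),
                                     class = "ConfusionCounts")), 70)
  expect_error(sensitivity(confusionCounts(c(1, 0), c(0, 0))), "undefined")
  expect_error(specificity(confusionCounts(c(1, 0), c(1, 1))), "undefined")
})

test_that("a noise-free, widely separated dataset is classified perfectly", {
  spec <- syntheticSpec(height = 128L, width = 128L, noiseSd = 0)
  ds <- generateDataset(4, grades = c(0, 2, 4), baseSpec = spec, seed = 41)
  rep <- runExperiment(ds, WindowConfig(), sweep = "n_images", values = c(8, 12),
                       ranker = "svm", seed = 2)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$sensitivity == 100))
  expect_true(all(rep$specificity == 100))
  expect_true(all(rep$ranking_efficiency >= 0 & rep$ranking_efficiency <= 100))
})

test_that("experiment reports are deterministic and within bounds", {
  ds <- smallBenchmark()
  r1 <- runExperiment(ds, WindowConfig(), sweep = "n_images",
                      values = c(15, 30), ranker = "svm", seed = 5)
  r2 <- runExperiment(ds, WindowConfig(), sweep = "n_images",
                      values = c(15, 30), ranker = "svm", seed = 5)
  keep <- setdiff(names(r1), "mean_extraction_ms")  # wall time may differ
  expect_identical(r1[keep], r2[keep])
  expect_equal(nrow(r1), 2L)
  for (col in c("sensitivity", "specificity", "ranking_efficiency"))
    expect_true(all(r1[[col]] >= 0 & r1[[col]] <= 100))
  expect_true(all(r1$mean_extraction_ms >= 0))
  expect_error(runExperiment(ds, WindowConfig(), sweep = "n_images",
                             values = 10 * length(ds), seed = 5),
               "exceeds dataset size")
})

test_that("the window-size sweep runs both rankers over the block-size axis", {
  ds <- smallBenchmark()
  for (rk in c("svm", "distance")) {
    r <- runExperiment(ds, WindowConfig(), sweep = "window_size",
                       values = c(4, 8), ranker = rk, seed = 3)
    expect_equal(r$value, c(4, 8))
    expect_true(all(r$sensitivity >= 0 & r$sensitivity <= 100))
    expect_true(all(r$specificity >= 0 & r$specificity <= 100))
  }
})

test_that("pipeline configuration files round-trip through YAML", {
  cfgFile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("window_size: 4", "s_max: 4", "channel_policy: luminance",
               "thresholds: [0.2, 0.6]",
               "svm:", "  kernel: hellinger_affinity", "  cost: 2.5",
               "lesion:", "  fraction: 0.25", "  top_bins: 2"), cfgFile)
  cfg <- readPipelineConfig(cfgFile)
  expect_equal(cfg$window@windowSize, 4L)
  expect_equal(cfg$window@sMax, 4L)
  expect_equal(cfg$channelPolicy, "luminance")
  expect_equal(cfg$ranking@thresholds, c(0.2, 0.6))
  expect_equal(cfg$svm$kernel, "hellinger_affinity")
  expect_equal(cfg$svm$cost, 2.5)
  expect_equal(cfg$lesion$fraction, 0.25)
  expect_equal(cfg$lesion$topBins, 2L)
  ## defaults when no file is given
  def <- readPipelineConfig()
  expect_equal(def$window@windowSize, 8L)
  expect_equal(def$window@sMax, 2L)
  expect_equal(def$svm$kernel, "rbf")
})
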