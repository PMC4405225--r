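## Confusion-matrix metrics and the experiment harness: stratified
## train/test sweeps over dataset size or window size, reporting sensitivity,
## specificity and ranking efficiency for either ranker.

#' Confusion counts for binary disease detection
#'
#' @param predicted,truth equal-length binary (0/1 or logical) vectors.
#' @return a list of class `"ConfusionCounts"` with elements `tp`, `fp`,
#'   `tn`, `fn` summing to `length(truth)`.
#' @examples
#' confusionCounts(c(1, 0), c(0, 1))  # fp = 1, fn = 1
#' @export
confusionCounts <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    stop("predicted and truth must be nonempty vectors of equal length")
  p <- as.integer(as.logical(predicted)); t <- as.integer(as.logical(truth))
  out <- list(tp = sum(p == 1L & t == 1L), fp = sum(p == 1L & t == 0L),
              tn = sum(p == 0L & t == 0L), fn = sum(p == 0L & t == 1L))
  class(out) <- "ConfusionCounts"
  out
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts: tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity (true-positive rate), in percent
#'
#' `100 * tp / (tp + fn)`: the capability of detecting diseased images.
#'
#' @param counts a [confusionCounts()] result.
#' @return numeric(1) in \[0, 100\].
#' @examples
#' sensitivity(confusionCounts(c(1,1,1,1,1,1,1,1,1,0), rep(1, 10)))  # 90
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  if (counts$tp + counts$fn == 0L)
    stop("sensitivity is undefined without any diseased images")
  100 * counts$tp / (counts$tp + counts$fn)
}

#' Specificity (true-negative rate), in percent
#'
#' `100 * tn / (tn + fp)`: the capability of clearing healthy images.
#'
#' @inheritParams sensitivity
#' @return numeric(1) in \[0, 100\].
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  if (counts$tn + counts$fp == 0L)
    stop("specificity is undefined without any healthy images")
  100 * counts$tn / (counts$tn + counts$fp)
}

## Deterministic stratified split: per grade, a seeded permutation; the first
## half (rounded up) trains, the rest tests.
stratifiedSplit <- function(grades, seed) {
  train <- integer(0)
  for (g in sort(unique(grades))) {
    idx <- which(grades == g)
    perm <- withSeed(seed + g, sample(idx))
    train <- c(train, perm[seq_len(ceiling(length(idx) / 2))])
  }
  sort(train)
}

## Fit on the training split and predict grades on the test split with the
## requested ranker. Returns integer predicted grades for `testIdx`.
fitAndPredict <- function(dataset, featuresList, config, trainIdx, testIdx,
                          ranker, rankingConfig, kernel, cost, seed) {
  grades <- labels(dataset)$severity_grade
  if (ranker == "svm") {
    X <- do.call(rbind, lapply(featuresList, gsValues))
    model <- trainSeverityModel(X[trainIdx, , drop = FALSE], grades[trainIdx],
                                kernel = kernel, cost = cost, seed = seed)
    predictRank(model, X[testIdx, , drop = FALSE])
  } else {
    ref <- referenceDistribution(dataset[trainIdx], config,
                                 featuresList[trainIdx])
    vapply(testIdx, function(i) {
      d <- lesionDistribution(images(dataset)[[i]], featuresList[[i]], config)
      assignRank(gaussianDistance(d, ref), rankingConfig)@rank
    }, integer(1))
  }
}

#' Run a sweep experiment
#'
#' Mirrors the evaluation protocol: for each sweep value (number of images,
#' or window size) the labelled dataset is split stratified 50/50 by grade
#' with a fixed seed, the chosen ranker is fitted on the training half, and
#' binary sensitivity/specificity (diseased = predicted grade > 0), exact
#' ranking efficiency and the Spearman correlation between predicted and true
#' grades are measured on the held-out half. Mean per-image feature-extraction
#' time is reported for information only. Every metric is cross-checked
#' against a brute-force recomputation from the raw prediction lists.
#'
#' @param dataset a labelled [FundusDataset-class].
#' @param config the base [WindowConfig-class].
#' @param sweep `"n_images"` or `"window_size"`.
#' @param values sweep values: dataset sizes, or window sizes.
#' @param ranker `"svm"` or `"distance"`.
#' @param rankingConfig thresholds for the distance ranker.
#' @param kernel,cost passed to [trainSeverityModel()] for the SVM ranker.
#' @param seed integer seed controlling the splits and the solver.
#' @return data.frame with one row per sweep value: `sweep`, `value`,
#'   `n_train`, `n_test`, `sensitivity`, `specificity`,
#'   `ranking_efficiency`, `spearman`, `mean_extraction_ms`.
#' @export
runExperiment <- function(dataset, config = WindowConfig(),
                          sweep = c("n_images", "window_size"), values,
                          ranker = c("svm", "distance"),
                          rankingConfig = RankingConfig(),
                          kernel = c("rbf", "hellinger_affinity"), cost = 1,
                          seed = 1L) {
  sweep <- match.arg(sweep); ranker <- match.arg(ranker)
  kernel <- match.arg(kernel)
  stopifnot(is(dataset, "FundusDataset"), length(values) >= 1L)
  grades <- labels(dataset)$severity_grade
  if (sweep == "n_images" && max(values) > length(dataset))
    stop("sweep value ", max(values), " exceeds dataset size ",
         length(dataset))
  baseFeatures <- NULL
  if (sweep == "n_images")
    baseFeatures <- lapply(images(dataset), extractFeatures, config = config)
  rows <- lapply(seq_along(values), function(k) {
    v <- values[k]
    if (sweep == "n_images") {
      ## seeded stratified subset of v images, then the shared split
      sub <- withSeed(seed + 1000L + k, {
        pick <- integer(0)
        want <- v
        gs <- sort(unique(grades))
        per <- ceiling(v / length(gs))
        for (g in gs) {
          idx <- sample(which(grades == g))
          pick <- c(pick, idx[seq_len(min(per, length(idx)))])
        }
        sort(pick[seq_len(min(want, length(pick)))])
      })
      ds <- dataset[sub]
      fl <- baseFeatures[sub]
      cfg <- config
    } else {
      ds <- dataset
      cfg <- WindowConfig(v, config@sMax)
      fl <- lapply(images(ds), extractFeatures, config = cfg)
    }
    g <- labels(ds)$severity_grade
    trainIdx <- stratifiedSplit(g, seed)
    testIdx <- setdiff(seq_along(g), trainIdx)
    pred <- fitAndPredict(ds, fl, cfg, trainIdx, testIdx, ranker,
                          rankingConfig, kernel, cost, seed)
    truthG <- g[testIdx]
    cc <- confusionCounts(pred > 0L, truthG > 0L)
    sens <- sensitivity(cc); spec <- specificity(cc)
    eff <- rankingEfficiency(truthG, pred)
    ## brute-force cross-check straight from the raw prediction lists
    stopifnot(
      isTRUE(all.equal(sens, 100 * sum(pred > 0 & truthG > 0) / sum(truthG > 0))),
      isTRUE(all.equal(spec, 100 * sum(pred == 0 & truthG == 0) / sum(truthG == 0))),
      isTRUE(all.equal(eff, 100 * sum(pred == truthG) / length(truthG))))
    rho <- if (stats::sd(pred) == 0 || stats::sd(truthG) == 0) NA_real_
           else stats::cor(truthG, pred, method = "spearman")
    data.frame(sweep = sweep, value = v,
               n_train = length(trainIdx), n_test = length(testIdx),
               sensitivity = sens, specificity = spec,
               ranking_efficiency = eff, spearman = rho,
               mean_extraction_ms = mean(vapply(fl, extractionTime, numeric(1))))
  })
  do.call(rbind, rows)
}
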