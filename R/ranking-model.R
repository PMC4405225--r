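## Support-vector severity ranking over per-block group-sparsity features.
## kernlab solves the binary soft-margin quadratic programs; the one-vs-rest
## wrapper, kernel matrices, decision function and JSON persistence live here.

#' Hellinger affinity kernel
#'
#' Treats two nonnegative feature vectors as discrete distributions
#' (normalising each to unit sum) and returns their Hellinger/Bhattacharyya
#' affinity \eqn{\sum_i \sqrt{\hat x_i \hat y_i}}. Values lie in \[0, 1\],
#' with \eqn{K(x, x) = 1} for any nonzero x; the kernel against an all-zero
#' vector is defined as 0. Equivalent to a linear kernel on the
#' square-root-transformed normalised features, hence positive semidefinite.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return numeric(1) in \[0, 1\].
#' @examples
#' hellingerAffinityKernel(c(1, 1), c(1, 0))  # sqrt(0.5)
#' @export
hellingerAffinityKernel <- function(x, y) {
  if (length(x) != length(y)) stop("feature vectors must have equal length")
  if (any(x < 0) || any(y < 0))
    stop("Hellinger affinity requires nonnegative entries")
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 || sy == 0) return(0)
  sum(sqrt((x / sx) * (y / sy)))
}

## ascending sort within each row (lesion position carries no grade
## information; only the multiset of block features does)
sortRows <- function(X) {
  if (ncol(X) <= 1L) return(X)
  t(apply(X, 1, sort, method = "radix"))
}

## sqrt of unit-sum-normalised rows; all-zero rows stay zero.
sqrtNormalise <- function(X) {
  s <- rowSums(X)
  s[s == 0] <- 1
  sqrt(X / s)
}

## Kernel matrix between rows of A and rows of B.
kernelCross <- function(A, B, kernel, gamma = NA_real_) {
  if (kernel == "hellinger_affinity") {
    if (any(A < 0) || any(B < 0))
      stop("Hellinger affinity requires nonnegative entries")
    sqrtNormalise(A) %*% t(sqrtNormalise(B))
  } else {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-gamma * pmax(d2, 0))
  }
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Train the one-vs-rest support-vector severity model
#'
#' Fits one binary soft-margin support-vector machine per severity grade
#' (that grade against all others) on per-block group-sparsity feature
#' vectors, using a Gaussian RBF kernel (default) or the Hellinger affinity
#' kernel. Because lesions occur at arbitrary retinal positions, the block
#' features are exchangeable: both kernels therefore act on the sorted
#' feature vector (the block multiset), which makes images with similar
#' lesion burden close regardless of where their lesions sit. Training is
#' deterministic for a fixed seed and input order.
#'
#' @param features numeric matrix, one row per image (e.g. stacked
#'   [gsValues()]), or a list of equal-length vectors.
#' @param grades integer severity grades, one per row; at least two distinct
#'   grades required.
#' @param kernel `"rbf"` or `"hellinger_affinity"`.
#' @param cost soft-margin cost C (> 0).
#' @param gamma RBF bandwidth; default `1 / (ncol * var(features))`
#'   (ignored by the affinity kernel).
#' @param seed integer seed for the solver.
#' @return a [SeverityModel-class].
#' @examples
#' X <- matrix(c(rnorm(20, 1, 0.01), rnorm(20, 9, 0.01)), ncol = 1)
#' m <- trainSeverityModel(X, rep(0:1, each = 20))
#' predictRank(m, 9)
#' @export
trainSeverityModel <- function(features, grades,
                               kernel = c("rbf", "hellinger_affinity"),
                               cost = 1, gamma = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  if (is.list(features)) features <- do.call(rbind, features)
  features <- as.matrix(features)
  ## block features are exchangeable: the kernels see the sorted multiset
  features <- sortRows(features)
  grades <- as.integer(grades)
  if (nrow(features) != length(grades))
    stop("one grade per feature row required")
  classes <- sort(unique(grades))
  if (length(classes) < 2L)
    stop("training requires at least two distinct grades")
  if (kernel == "rbf" && is.null(gamma)) {
    v <- stats::var(as.vector(features))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(features) * v) else 1
  }
  if (kernel == "hellinger_affinity") gamma <- NA_real_
  K <- kernelCross(features, features, kernel, gamma)
  machines <- lapply(classes, function(g) {
    y <- factor(ifelse(grades == g, "pos", "neg"), levels = c("neg", "pos"))
    m <- withSeed(seed, kernlab::ksvm(kernlab::as.kernelMatrix(K), y,
                                      type = "C-svc", C = cost))
    ai <- kernlab::alphaindex(m)[[1]]
    co <- as.numeric(kernlab::coef(m)[[1]])
    b <- as.numeric(kernlab::b(m))
    dtr <- as.numeric(K[, ai, drop = FALSE] %*% co) - b
    ## orient the decision so positive means "this grade"
    sgn <- if (mean(dtr[y == "pos"]) >= mean(dtr[y == "neg"])) 1 else -1
    list(sv = features[ai, , drop = FALSE], coef = co, b = b, sign = sgn)
  })
  new("SeverityModel", kernel = kernel, classes = classes,
      featureLength = ncol(features), machines = machines,
      cost = as.numeric(cost), gamma = as.numeric(gamma))
}

## Decision values, one column per class, computed from the stored support
## vectors -- independent of kernlab's predict path.
decisionValues <- function(model, X) {
  vapply(model@machines, function(m) {
    kx <- kernelCross(X, m$sv, model@kernel, model@gamma)
    m$sign * (as.numeric(kx %*% m$coef) - m$b)
  }, numeric(nrow(X)))
}

#' Predict severity grades with a trained model
#'
#' Each feature vector receives the grade whose one-vs-rest machine yields
#' the largest decision value (ties resolve to the lower grade).
#'
#' @param model a [SeverityModel-class].
#' @param features numeric vector of length `featureLength`, or a matrix with
#'   one such row per image.
#' @return integer vector of predicted grades.
#' @export
predictRank <- function(model, features) {
  stopifnot(is(model, "SeverityModel"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != model@featureLength)
    stop("feature length ", ncol(features), " does not match the model's ",
         model@featureLength)
  dv <- decisionValues(model, sortRows(features))
  if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1)
  model@classes[apply(dv, 1, which.max)]
}

#' Ranking efficiency
#'
#' Percent exact agreement between predicted and true severity grades.
#'
#' @param truth,predicted equal-length nonempty integer vectors.
#' @return numeric(1) in \[0, 100\].
#' @examples
#' rankingEfficiency(c(1, 2, 3, 4), c(1, 2, 0, 0))  # 50
#' @export
rankingEfficiency <- function(truth, predicted) {
  if (length(truth) == 0L || length(truth) != length(predicted))
    stop("truth and predicted must be nonempty vectors of equal length")
  100 * mean(truth == predicted)
}

#' Persist / restore a severity model as versioned JSON
#'
#' The stored support vectors and coefficients are written as full-precision
#' JSON numbers; because prediction is computed from these coefficients, a
#' round-tripped model reproduces decisions exactly.
#'
#' @param model a [SeverityModel-class].
#' @param path JSON file path.
#' @return `writeSeverityModel` returns `path` invisibly; `readSeverityModel`
#'   returns the restored [SeverityModel-class].
#' @export
writeSeverityModel <- function(model, path) {
  stopifnot(is(model, "SeverityModel"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("model persistence requires the jsonlite package")
  obj <- list(format = "FundusRank-severity-model", version = 1L,
              kernel = model@kernel, classes = model@classes,
              featureLength = model@featureLength, cost = model@cost,
              gamma = model@gamma,
              machines = lapply(model@machines, function(m)
                list(sv = m$sv, coef = m$coef, b = m$b, sign = m$sign)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname writeSeverityModel
#' @export
readSeverityModel <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("model persistence requires the jsonlite package")
  if (!file.exists(path)) stop("cannot read model file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "FundusRank-severity-model"))
    stop("not a FundusRank severity model file: ", path)
  machines <- lapply(seq_along(obj$machines$sign), function(i)
    list(sv = matrix(unlist(obj$machines$sv[[i]]), ncol = obj$featureLength,
                     byrow = FALSE),
         coef = as.numeric(obj$machines$coef[[i]]),
         b = as.numeric(obj$machines$b[[i]]),
         sign = as.numeric(obj$machines$sign[[i]])))
  new("SeverityModel", kernel = obj$kernel, classes = as.integer(obj$classes),
      featureLength = as.integer(obj$featureLength), machines = machines,
      cost = as.numeric(obj$cost), gamma = as.numeric(obj$gamma))
}
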