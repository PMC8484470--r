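## Min-max normalization, class-weighted SVM training/prediction, and the
## 108-configuration cross-validated hyperparameter grid search.

## the svm import also registers e1071's predict.svm S3 method, which a
## deserialized model needs even when nothing else touches e1071
#' @importFrom e1071 svm
NULL

#' Construct an SVM configuration
#'
#' Defaults to the configuration selected by the grid search on real
#' smear data: polynomial kernel of degree 3, C = 6, neutrophil weight 10.
#'
#' @param kernel "linear", "rbf" or "poly3".
#' @param C positive regularization parameter.
#' @param neutWeight positive neutrophil class weight (all other classes
#'   have weight 1).
#' @return a \linkS4class{SvmConfig}.
#' @export
svmConfig <- function(kernel = "poly3", C = 6, neutWeight = 10) {
  new("SvmConfig", kernel = kernel, cost = as.numeric(C),
      neutWeight = as.numeric(neutWeight))
}

#' The hyperparameter grid
#'
#' All combinations of kernel (linear, rbf, poly3), neutrophil weight
#' (1, 2, 5, 10, 15, 20) and C (1, 2, 4, 6, 8, 10): 108 configurations.
#'
#' @return data.frame with columns kernel, neutWeight, C (108 rows).
#' @export
gridConfigs <- function() {
  g <- expand.grid(C = c(1, 2, 4, 6, 8, 10),
                   neutWeight = c(1, 2, 5, 10, 15, 20),
                   kernel = c("linear", "rbf", "poly3"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("kernel", "neutWeight", "C")]
}

#' Learn min-max normalization statistics
#'
#' Per-feature minima and maxima over the training rows. Applying them
#' ([applyNorm()]) maps the training features into [0, 1]; a constant
#' feature maps to 0 and out-of-range test values are clamped into [0, 1].
#'
#' @param x numeric matrix (rows = samples).
#' @return list with numeric vectors \code{min} and \code{max}.
#' @export
fitNorm <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("invalid input: need at least 2 feature vectors", call. = FALSE)
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' Apply min-max normalization
#'
#' @param x numeric matrix.
#' @param norm statistics from [fitNorm()].
#' @return matrix with values in [0, 1].
#' @export
applyNorm <- function(x, norm) {
  x <- as.matrix(x)
  rng <- norm$max - norm$min
  out <- sweep(x, 2, norm$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, 0), 1)
}

.kernelArgs <- function(config, xn) {
  v <- stats::var(as.vector(xn))
  gamma <- if (is.finite(v) && v > 0) 1 / (ncol(xn) * v) else 1 / ncol(xn)
  switch(config@kernel,
         linear = list(kernel = "linear"),
         rbf = list(kernel = "radial", gamma = gamma),
         poly3 = list(kernel = "polynomial", degree = 3, coef0 = 0,
                      gamma = gamma))
}

#' Train the class-weighted SVM
#'
#' Normalizes the 51-dimensional features with min-max statistics learned
#' here, then fits a C-classification SVM (one-vs-one multi-class) with
#' per-class weights 1 except for the neutrophil class. Kernel
#' auxiliaries: gamma = 1 / (51 * var(normalized features)), coef0 = 0.
#'
#' @param x numeric matrix, n x 51.
#' @param y class labels (character or factor), at least two classes.
#' @param config a \linkS4class{SvmConfig}.
#' @param seed integer; training is deterministic, the seed guards any
#'   library-internal randomness.
#' @return a \linkS4class{WBCModel}.
#' @export
trainWBC <- function(x, y, config = svmConfig(), seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y))
    stop("invalid input: features and labels differ in length",
         call. = FALSE)
  if (ncol(x) != 51L)
    stop("invalid input: feature vectors must have length 51",
         call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("invalid input: training needs at least two classes",
         call. = FALSE)
  norm <- fitNorm(x)
  xn <- applyNorm(x, norm)
  w <- stats::setNames(rep(1, length(classes)), classes)
  if ("neutrophil" %in% classes) w[["neutrophil"]] <- config@neutWeight
  args <- .kernelArgs(config, xn)
  set.seed(seed)
  fit <- do.call(e1071::svm,
                 c(list(x = xn, y = factor(y, levels = classes),
                        type = "C-classification", cost = config@cost,
                        class.weights = w, scale = FALSE), args))
  fo <- colnames(x)
  if (is.null(fo)) fo <- featureNames()
  new("WBCModel", fit = fit, featMin = norm$min, featMax = norm$max,
      config = config, classes = classes, featureOrder = fo)
}

#' Predict leukocyte classes
#'
#' @param object a \linkS4class{WBCModel}.
#' @param newdata numeric matrix or vector of 51-dimensional features; if
#'   column names are present they must match the model's feature order.
#' @return character vector of predicted class labels.
#' @export
setMethod("predict", "WBCModel", function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@featureOrder))
    stop("invalid input: expected ", length(object@featureOrder),
         " features, got ", ncol(newdata), call. = FALSE)
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object@featureOrder))
    stop("invalid input: feature order fingerprint mismatch",
         call. = FALSE)
  xn <- applyNorm(newdata, list(min = object@featMin, max = object@featMax))
  as.character(predict(object@fit, xn))
})

#' Save / load a trained model
#'
#' The model file is a serialized \linkS4class{WBCModel} with its
#' normalization statistics and feature-order fingerprint embedded;
#' reloading reproduces predictions exactly.
#'
#' @param model a \linkS4class{WBCModel}.
#' @param path file path.
#' @return \code{loadModel} returns the model; \code{saveModel} its path,
#'   invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "WBCModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "WBCModel"))
    stop("invalid input: not a saved WBCModel", call. = FALSE)
  validObject(model)
  model
}

.stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated grid search over the 108 configurations
#'
#' Stratified 5-fold cross-validation on the training set. Normalization
#' statistics are refit on each training fold, so no information leaks
#' from the validation fold. The result table holds the mean and sample
#' standard deviation of the fold accuracies for every configuration; the
#' best configuration maximizes the mean accuracy, with ties broken by
#' smaller C, then smaller neutrophil weight, then kernel order
#' linear < rbf < poly3.
#'
#' @param x numeric matrix, n x 51.
#' @param y class labels; every class needs at least \code{folds} samples.
#' @param seed integer controlling the fold assignment.
#' @param folds number of folds (default 5).
#' @return list with elements \code{best} (a \linkS4class{SvmConfig}) and
#'   \code{table} (data.frame of 108 rows: kernel, neutWeight, C,
#'   meanAcc, sdAcc).
#' @export
gridSearchWBC <- function(x, y, seed = 1L, folds = 5L) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y))
    stop("invalid input: features and labels differ in length",
         call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("invalid input: grid search needs at least two classes",
         call. = FALSE)
  if (min(table(y)) < folds)
    stop("invalid input: every class needs at least ", folds, " samples",
         call. = FALSE)
  fold <- .stratifiedFolds(y, folds, seed)
  grid <- gridConfigs()
  acc <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (i in seq_len(nrow(grid))) {
      cfg <- svmConfig(grid$kernel[i], grid$C[i], grid$neutWeight[i])
      model <- trainWBC(x[tr, , drop = FALSE], y[tr], cfg, seed = seed)
      pred <- predict(model, x[!tr, , drop = FALSE])
      acc[i, f] <- mean(pred == y[!tr])
    }
  }
  tab <- cbind(grid,
               meanAcc = rowMeans(acc),
               sdAcc = apply(acc, 1, stats::sd))
  kernelRank <- match(tab$kernel, c("linear", "rbf", "poly3"))
  bestIdx <- order(-tab$meanAcc, tab$C, tab$neutWeight, kernelRank)[1L]
  list(best = svmConfig(tab$kernel[bestIdx], tab$C[bestIdx],
                        tab$neutWeight[bestIdx]),
       table = tab)
}
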