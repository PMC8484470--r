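#' @import methods
#' @importFrom stats predict sd var
NULL

## Images are plain numeric arrays dim c(height, width, 3) holding 8-bit
## values 0..255; binary masks are logical matrices dim c(height, width).
## This mirrors how EBImage keeps raster data as bare arrays; the S4 layer
## below is reserved for the composite objects of the pipeline.

#' Soft map of nucleus evidence
#'
#' Single-channel evidence image \code{min(M, S) - (K - M)} (clipped below
#' at 0) combining the K and M planes of CMYK with the S plane of HLS,
#' computed on the colour-balanced crop. High values mark nucleus pixels.
#' The two intermediate planes are retained for inspection.
#'
#' @slot values numeric matrix in [0, 1]; the map Otsu's method runs on.
#' @slot km numeric matrix; \code{pmax(K - M, 0)}.
#' @slot ms numeric matrix; \code{pmin(M, S)}.
#' @export
setClass("SoftMap",
  representation(values = "matrix", km = "matrix", ms = "matrix"),
  validity = function(object) {
    msgs <- character()
    for (nm in c("values", "km", "ms")) {
      v <- slot(object, nm)
      if (!is.numeric(v)) msgs <- c(msgs, sprintf("'%s' must be numeric", nm))
      else if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
        msgs <- c(msgs, sprintf("'%s' must be finite and in [0, 1]", nm))
    }
    if (!identical(dim(object@km), dim(object@values)) ||
        !identical(dim(object@ms), dim(object@values)))
      msgs <- c(msgs, "all planes must share one shape")
    if (length(msgs)) msgs else TRUE
  })

#' Nucleus, convex hull and ROC masks of one cell
#'
#' The cytoplasm is never segmented directly: the region of the crop inside
#' the convex hull of the nucleus but outside the nucleus itself serves as
#' the representative of the cytoplasm (ROC). The less convex the nucleus,
#' the larger the ROC.
#'
#' @slot nucleus logical matrix, the segmented nucleus.
#' @slot hull logical matrix, filled convex hull of the nucleus.
#' @slot roc logical matrix, \code{hull & !nucleus}.
#' @export
setClass("CellRegions",
  representation(nucleus = "matrix", hull = "matrix", roc = "matrix"),
  validity = function(object) {
    msgs <- character()
    for (nm in c("nucleus", "hull", "roc"))
      if (!is.logical(slot(object, nm)))
        msgs <- c(msgs, sprintf("'%s' must be a logical matrix", nm))
    if (!length(msgs)) {
      if (!identical(dim(object@nucleus), dim(object@hull)) ||
          !identical(dim(object@nucleus), dim(object@roc)))
        msgs <- c(msgs, "all three masks must share one shape")
      else {
        if (any(object@nucleus & !object@hull))
          msgs <- c(msgs, "nucleus must be a subset of hull")
        if (!identical(object@roc, object@hull & !object@nucleus))
          msgs <- c(msgs, "roc must equal hull & !nucleus")
      }
    }
    if (length(msgs)) msgs else TRUE
  })

#' SVM hyperparameter configuration
#'
#' One point of the hyperparameter grid: kernel, regularization C, and the
#' misclassification weight of the neutrophil class (all other classes have
#' weight 1). The default is the configuration selected by cross-validated
#' grid search on real smear data: polynomial degree 3, C = 6, weight 10.
#'
#' @slot kernel one of "linear", "rbf", "poly3".
#' @slot cost positive regularization parameter (the SVM "C").
#' @slot neutWeight positive neutrophil class weight.
#' @export
setClass("SvmConfig",
  representation(kernel = "character", cost = "numeric",
                 neutWeight = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@kernel) != 1L ||
        !object@kernel %in% c("linear", "rbf", "poly3"))
      msgs <- c(msgs, "kernel must be one of 'linear', 'rbf', 'poly3'")
    if (length(object@cost) != 1L || !is.finite(object@cost) ||
        object@cost <= 0)
      msgs <- c(msgs, "cost must be a positive number")
    if (length(object@neutWeight) != 1L || !is.finite(object@neutWeight) ||
        object@neutWeight <= 0)
      msgs <- c(msgs, "neutWeight must be a positive number")
    if (length(msgs)) msgs else TRUE
  })

#' Trained leukocyte classifier
#'
#' Bundles the fitted SVM with everything prediction needs: the per-feature
#' training minima/maxima of the min-max normalizer, the hyperparameter
#' configuration, the class list, and the feature-order fingerprint.
#' Predictions depend only on this persisted state.
#'
#' @slot fit fitted \code{e1071::svm} object.
#' @slot featMin,featMax numeric vectors, per-feature training extremes.
#' @slot config a \linkS4class{SvmConfig}.
#' @slot classes character, class labels seen in training.
#' @slot featureOrder character, column names in canonical order.
#' @export
setClass("WBCModel",
  representation(fit = "ANY", featMin = "numeric", featMax = "numeric",
                 config = "SvmConfig", classes = "character",
                 featureOrder = "character"),
  validity = function(object) {
    msgs <- character()
    if (length(object@featMin) != length(object@featMax))
      msgs <- c(msgs, "featMin and featMax must have equal length")
    else if (any(object@featMax < object@featMin))
      msgs <- c(msgs, "featMax must be >= featMin for every feature")
    if (length(object@featureOrder) != length(object@featMin))
      msgs <- c(msgs, "featureOrder must name every feature")
    if (length(object@classes) < 2L)
      msgs <- c(msgs, "a model must know at least two classes")
    if (length(msgs)) msgs else TRUE
  })

#' Synthetic labelled cell crop
#'
#' A generated smear-like crop together with its exact ground-truth nucleus
#' mask (whole-cell mask for basophils, whose granules obscure the nucleus)
#' and the class label and generator parameters that produced it.
#'
#' @slot image numeric array h x w x 3, 8-bit values.
#' @slot truth logical matrix, exact ground truth.
#' @slot label one of the five leukocyte classes.
#' @slot spec list of generator parameters.
#' @export
setClass("LabeledCrop",
  representation(image = "array", truth = "matrix", label = "character",
                 spec = "list"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@image)) != 3L || dim(object@image)[3] != 3L)
      msgs <- c(msgs, "image must be an h x w x 3 array")
    if (!is.logical(object@truth))
      msgs <- c(msgs, "truth must be a logical matrix")
    else if (!identical(dim(object@truth), dim(object@image)[1:2]))
      msgs <- c(msgs, "truth must share the image shape")
    else if (!any(object@truth))
      msgs <- c(msgs, "truth must be non-empty")
    if (length(object@label) != 1L || !object@label %in% wbcClasses())
      msgs <- c(msgs, "label must be one of the five leukocyte classes")
    if (length(msgs)) msgs else TRUE
  })

#' The five peripheral-blood leukocyte classes
#'
#' @return character vector of the five class names, in canonical order.
#' @export
wbcClasses <- function() {
  c("lymphocyte", "monocyte", "neutrophil", "eosinophil", "basophil")
}

## ---- accessors ----

#' @describeIn SoftMap-class the soft-map values matrix.
#' @param x object.
#' @export
softValues <- function(x) { stopifnot(is(x, "SoftMap")); x@values }

#' @describeIn SoftMap-class the clipped K - M plane.
#' @export
kmPlane <- function(x) { stopifnot(is(x, "SoftMap")); x@km }

#' @describeIn SoftMap-class the min(M, S) plane.
#' @export
msPlane <- function(x) { stopifnot(is(x, "SoftMap")); x@ms }

#' @describeIn CellRegions-class the nucleus mask.
#' @param x object.
#' @export
nucleus <- function(x) { stopifnot(is(x, "CellRegions")); x@nucleus }

#' @describeIn CellRegions-class the convex-hull mask.
#' @export
hull <- function(x) { stopifnot(is(x, "CellRegions")); x@hull }

#' @describeIn CellRegions-class the ROC (hull minus nucleus) mask.
#' @export
roc <- function(x) { stopifnot(is(x, "CellRegions")); x@roc }

setMethod("show", "SoftMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("SoftMap %d x %d, values in [%.3f, %.3f]\n",
              d[1], d[2], min(object@values), max(object@values)))
})

setMethod("show", "CellRegions", function(object) {
  cat(sprintf("CellRegions %d x %d: nucleus %d px, hull %d px, roc %d px\n",
              nrow(object@nucleus), ncol(object@nucleus),
              sum(object@nucleus), sum(object@hull), sum(object@roc)))
})

setMethod("show", "SvmConfig", function(object) {
  cat(sprintf("SvmConfig: kernel=%s, C=%g, neutrophil weight=%g\n",
              object@kernel, object@cost, object@neutWeight))
})

setMethod("show", "WBCModel", function(object) {
  cat(sprintf("WBCModel (%s, C=%g, neut-W=%g): %d features, classes: %s\n",
              object@config@kernel, object@config@cost,
              object@config@neutWeight,
              length(object@featureOrder),
              paste(object@classes, collapse = ", ")))
})

setMethod("show", "LabeledCrop", function(object) {
  d <- dim(object@image)
  cat(sprintf("LabeledCrop %d x %d [%s], truth %d px\n",
              d[1], d[2], object@label, sum(object@truth)))
})
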