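## File IO: 8-bit cell-crop rasters, binary masks as {0, 255} PNG, feature
## tables as CSV, and the end-to-end directory pipeline.

#' Read a cell-crop image
#'
#' Reads an 8-bit RGB raster (PNG/JPEG/TIFF/BMP as supported by EBImage).
#' Grayscale images are expanded to three equal channels; an alpha channel
#' is stripped with a warning. Images are processed at native resolution
#' -- the pipeline never resizes its inputs.
#'
#' @param path image file.
#' @return h x w x 3 array of 8-bit values.
#' @export
readCellImage <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) {
    warning("alpha channel stripped from ", basename(path))
    a <- a[, , 1:3, drop = FALSE]
  }
  out <- aperm(a, c(2, 1, 3))
  array(pmin(pmax(round(out * 255), 0), 255), dim = dim(out))
}

#' Read / write a binary mask PNG
#'
#' Masks are single-channel 8-bit PNGs; any nonzero pixel is mask. Writing
#' emits {0, 255}; a write/read round trip is lossless. Multi-channel mask
#' files are collapsed by any-nonzero with a warning.
#'
#' @param path PNG file.
#' @return \code{readMask}: logical matrix.
#' @export
readMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) {
    warning("multi-channel mask collapsed by any-nonzero: ", basename(path))
    m <- apply(m, c(1, 2), max)
  }
  m > 0
}

#' @rdname readMask
#' @param mask logical matrix.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a soft map as an 8-bit PNG
#'
#' Values are scaled by 255 and rounded; useful for inspecting the
#' segmentation intermediates.
#'
#' @param map a \linkS4class{SoftMap}.
#' @param path PNG file.
#' @export
writeSoftMap <- function(map, path) {
  stopifnot(is(map, "SoftMap"))
  png::writePNG(round(map@values * 255) / 255, path)
  invisible(path)
}

#' Write / read a feature table CSV
#'
#' Columns: \code{image}, optional \code{label}, then f01..f51 in the
#' canonical [featureNames()] order (the header carries the names).
#'
#' @param features numeric matrix with 51 named columns.
#' @param ids image identifiers, one per row.
#' @param path CSV file.
#' @param labels optional class labels.
#' @export
writeFeatures <- function(features, ids, path, labels = NULL) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == 51L, nrow(features) == length(ids))
  df <- data.frame(image = ids, stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  df <- cbind(df, as.data.frame(features))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @return \code{readFeatures}: list with \code{features}, \code{ids},
#'   and \code{labels} (\code{NULL} when absent).
#' @export
readFeatures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hasLabel <- "label" %in% names(df)
  featCols <- setdiff(names(df), c("image", "label"))
  if (!identical(featCols, featureNames()))
    stop("invalid input: feature order fingerprint mismatch in ", path,
         call. = FALSE)
  list(features = as.matrix(df[, featCols]), ids = df$image,
       labels = if (hasLabel) df$label else NULL)
}

#' Run the full pipeline on a directory of crops
#'
#' Segments, extracts features and classifies every readable image in
#' \code{inputDir}, writing \code{predictions.csv} (and per-image nucleus
#' masks when \code{saveMasks}) to \code{outDir}. Per-image failures are
#' logged and skipped; the run fails only if no image can be processed.
#' Deterministic for fixed inputs.
#'
#' @param inputDir directory of crop images.
#' @param model a \linkS4class{WBCModel} or path to a saved model.
#' @param outDir output directory (created if needed).
#' @param saveMasks also write the nucleus masks as PNGs?
#' @param keepAll passed to [segmentNucleus()].
#' @return data.frame of predictions, invisibly.
#' @export
runPipeline <- function(inputDir, model, outDir, saveMasks = FALSE,
                        keepAll = FALSE) {
  if (is.character(model)) model <- loadModel(model)
  stopifnot(is(model, "WBCModel"))
  files <- list.files(inputDir, "\\.(png|jpg|jpeg|tif|tiff|bmp)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files))
    stop("no input images found in ", inputDir, call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  skipped <- 0L
  for (f in files) {
    res <- tryCatch({
      img <- readCellImage(f)
      feats <- extractFeatures(img, keepAll = keepAll)
      if (saveMasks)
        writeMask(segmentNucleus(img, keepAll = keepAll),
                  file.path(outDir, paste0(tools::file_path_sans_ext(
                    basename(f)), "_nucleus.png")))
      data.frame(image = basename(f),
                 label = predict(model, matrix(feats, nrow = 1,
                                               dimnames = list(NULL,
                                                 names(feats)))),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) skipped <- skipped + 1L else rows[[f]] <- res
  }
  if (!length(rows))
    stop("pipeline failed: no image could be processed", call. = FALSE)
  pred <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(pred, file.path(outDir, "predictions.csv"),
                   row.names = FALSE)
  if (skipped) message(skipped, " image(s) skipped")
  invisible(pred)
}
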