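## Geometric training-set augmentation: horizontal/vertical flips, random
## rotation in [-90, 90] degrees, random rescale in [0.8, 1.2], and
## compositions. Canvas size is always preserved (rotation about the crop
## centre; rescale followed by centre crop or padding), with the
## background filled by the per-channel median of the border pixels.
## Interpolation is bilinear. Labels never change under any transform.

.borderMedian <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  vapply(1:3, function(c) {
    ch <- image[, , c]
    stats::median(c(ch[1, ], ch[h, ], ch[, 1], ch[, w]))
  }, numeric(1))
}

.toEB <- function(image) {
  EBImage::Image(aperm(image / 255, c(2, 1, 3)), colormode = "Color")
}

.fromEB <- function(img) {
  a <- aperm(EBImage::imageData(img), c(2, 1, 3))
  array(pmin(pmax(round(a * 255), 0), 255), dim = dim(a))
}

#' Flip a crop horizontally or vertically
#'
#' Exact (lossless) mirror; flips are involutions.
#'
#' @param image h x w x 3 array of 8-bit values.
#' @return flipped image of the same shape.
#' @export
hflipCrop <- function(image) image[, dim(image)[2]:1, , drop = FALSE]

#' @rdname hflipCrop
#' @export
vflipCrop <- function(image) image[dim(image)[1]:1, , , drop = FALSE]

#' Rotate a crop about its centre, keeping the canvas
#'
#' @param image h x w x 3 array of 8-bit values.
#' @param angle degrees.
#' @return rotated image of the same shape, background filled with the
#'   border median colour.
#' @export
rotateCrop <- function(image, angle) {
  bg <- .borderMedian(image) / 255
  img <- EBImage::rotate(.toEB(image), angle, filter = "bilinear",
                         output.dim = dim(image)[2:1],
                         bg.col = grDevices::rgb(bg[1], bg[2], bg[3]))
  .fromEB(img)
}

#' Rescale a crop, keeping the canvas
#'
#' Bilinear resample by \code{scale}, then centre-crop (scale > 1) or
#' centre-pad with the border-median colour (scale < 1).
#'
#' @param image h x w x 3 array of 8-bit values.
#' @param scale positive scale factor.
#' @return rescaled image on the original canvas.
#' @export
scaleCrop <- function(image, scale) {
  stopifnot(scale > 0)
  h <- dim(image)[1]; w <- dim(image)[2]
  nh <- max(1L, round(h * scale)); nw <- max(1L, round(w * scale))
  rs <- .fromEB(EBImage::resize(.toEB(image), w = nw, h = nh,
                                filter = "bilinear"))
  bg <- .borderMedian(image)
  out <- array(rep(bg, each = h * w), dim = c(h, w, 3))
  ro <- max(0L, (nh - h) %/% 2L); co <- max(0L, (nw - w) %/% 2L)
  rt <- max(0L, (h - nh) %/% 2L); ct <- max(0L, (w - nw) %/% 2L)
  ch <- min(h, nh); cw <- min(w, nw)
  out[rt + seq_len(ch), ct + seq_len(cw), ] <-
    rs[ro + seq_len(ch), co + seq_len(cw), , drop = FALSE]
  out
}

.applyTransform <- function(image, kind) {
  switch(kind,
         hflip = list(image = hflipCrop(image), chain = "hflip"),
         vflip = list(image = vflipCrop(image), chain = "vflip"),
         rotate = {
           a <- stats::runif(1, -90, 90)
           list(image = rotateCrop(image, a),
                chain = sprintf("rotate(%.1f)", a))
         },
         scale = {
           s <- stats::runif(1, 0.8, 1.2)
           list(image = scaleCrop(image, s),
                chain = sprintf("scale(%.3f)", s))
         },
         compose = {
           chain <- character(0)
           if (stats::runif(1) < 0.5) {
             image <- hflipCrop(image); chain <- c(chain, "hflip")
           }
           if (stats::runif(1) < 0.5) {
             image <- vflipCrop(image); chain <- c(chain, "vflip")
           }
           a <- stats::runif(1, -90, 90)
           image <- rotateCrop(image, a)
           s <- stats::runif(1, 0.8, 1.2)
           image <- scaleCrop(image, s)
           list(image = image,
                chain = paste(c(chain, sprintf("rotate(%.1f)", a),
                                sprintf("scale(%.3f)", s)),
                              collapse = "+"))
         })
}

#' Balance a training set by geometric augmentation
#'
#' Augments every class up to exactly \code{target} images. Originals are
#' retained; each synthetic image records its source index and transform
#' chain. Sources are cycled in shuffled order and transforms drawn from
#' \code{transforms}; fully reproducible for a fixed seed.
#'
#' @param images list of h x w x 3 arrays.
#' @param labels class label per image.
#' @param target desired per-class count, at least the largest class.
#' @param seed integer.
#' @param transforms subset of hflip, vflip, rotate, scale, compose.
#' @return list with \code{images}, \code{labels}, and \code{info}
#'   (data.frame with source index and transform chain per output image).
#' @export
augmentToBalance <- function(images, labels, target, seed = 1L,
                             transforms = c("hflip", "vflip", "rotate",
                                            "scale", "compose")) {
  labels <- as.character(labels)
  if (length(images) != length(labels))
    stop("invalid input: images and labels differ in length", call. = FALSE)
  counts <- table(labels)
  if (any(counts == 0) || length(images) == 0L)
    stop("invalid input: every class needs at least one image",
         call. = FALSE)
  if (target < max(counts))
    stop("invalid input: target below the largest class count",
         call. = FALSE)
  transforms <- match.arg(transforms, several.ok = TRUE)
  set.seed(seed)
  outImages <- images
  outLabels <- labels
  info <- data.frame(source = seq_along(images),
                     chain = rep("original", length(images)),
                     stringsAsFactors = FALSE)
  for (cl in names(counts)) {
    deficit <- target - counts[[cl]]
    if (deficit == 0L) next
    pool <- sample(which(labels == cl))
    src <- rep_len(pool, deficit)
    for (i in src) {
      kind <- sample(transforms, 1L)
      tr <- .applyTransform(images[[i]], kind)
      outImages[[length(outImages) + 1L]] <- tr$image
      outLabels <- c(outLabels, cl)
      info <- rbind(info, data.frame(source = i, chain = tr$chain,
                                     stringsAsFactors = FALSE))
    }
  }
  list(images = outImages, labels = outLabels, info = info)
}
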