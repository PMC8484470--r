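## Colour-plane computations: channel balancing, the CMYK K/M and HLS S
## planes feeding the soft map, and the 12 feature channels.
##
## Conventions, fixed for reproducibility:
##  * images are h x w x 3 arrays of 8-bit values (0..255, integer-valued);
##  * every derived plane is a [0, 1] float matrix so CMYK and HLS
##    components can be mixed arithmetically on one scale;
##  * grayscale means the BT.601 luma 0.299 R + 0.587 G + 0.114 B;
##  * CIELAB uses the sRGB companding of grDevices::convertColor with a
##    D65 white point, rescaled 8-bit style (L*/100, (a*+128)/255,
##    (b*+128)/255);
##  * YCbCr uses BT.601 full-range: Y = luma, Cr = 0.713 (R - Y) + 1/2,
##    Cb = 0.564 (B - Y) + 1/2.

.lumaWeights <- c(0.299, 0.587, 0.114)

assertRgbImage <- function(image, minSide = 8L) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("invalid input: expected an h x w x 3 array", call. = FALSE)
  d <- dim(image)
  if (d[1] < minSide || d[2] < minSide)
    stop(sprintf("invalid input: image must be at least %d x %d pixels",
                 minSide, minSide), call. = FALSE)
  if (any(!is.finite(image)) || any(image < 0) || any(image > 255))
    stop("invalid input: channel values must lie in [0, 255]", call. = FALSE)
  if (any(image != round(image)))
    stop("invalid input: channel values must be integer-valued", call. = FALSE)
  invisible(image)
}

#' Canonical order of the 12 colour feature channels
#'
#' @return character vector naming the planes of [featureChannels()]:
#'   R, G, B, H, S_hsv, V, L_lab, a_lab, b_lab, Y, Cr, Cb.
#' @export
channelNames <- function() {
  c("R", "G", "B", "H", "S_hsv", "V", "L_lab", "a_lab", "b_lab",
    "Y", "Cr", "Cb")
}

#' Balance the colour cast of a smear crop
#'
#' Rescales each channel so that its mean equals the mean of the luma
#' grayscale representation:
#' \code{new = round(old * mean(gray) / mean(old))}, clipped to [0, 255].
#' A channel with zero mean is returned unchanged. This removes global
#' stain/illumination casts before the soft map is computed.
#'
#' @param image h x w x 3 array of 8-bit values.
#' @return balanced image, same shape and 8-bit range.
#' @examples
#' img <- array(100, dim = c(8, 8, 3))
#' identical(balanceColors(img), img)  # already balanced
#' @export
balanceColors <- function(image) {
  assertRgbImage(image)
  gray <- .lumaWeights[1] * image[, , 1] + .lumaWeights[2] * image[, , 2] +
    .lumaWeights[3] * image[, , 3]
  mg <- mean(gray)
  out <- image
  for (c in 1:3) {
    mc <- mean(image[, , c])
    if (mc > 0) out[, , c] <- round(pmin(pmax(image[, , c] * mg / mc, 0), 255))
  }
  out
}

#' K and M planes of the CMYK decomposition
#'
#' With R', G', B' the channels on [0, 1]: \code{K = 1 - max(R', G', B')}
#' and \code{M = (1 - G' - K) / (1 - K)} where K < 1; M is defined as 0 on
#' pure black pixels (K = 1). Naive device-independent conversion with
#' full black generation.
#'
#' @param image h x w x 3 array of 8-bit values.
#' @return list with matrices \code{K} and \code{M}, both in [0, 1].
#' @export
cmykPlanes <- function(image) {
  assertRgbImage(image)
  r <- image[, , 1] / 255; g <- image[, , 2] / 255; b <- image[, , 3] / 255
  mx <- pmax(r, g, b)
  k <- 1 - mx
  m <- ifelse(mx > 0, (mx - g) / mx, 0)  # (1 - G' - K)/(1 - K), 1 - K = mx
  list(K = k, M = pmin(pmax(m, 0), 1))
}

#' Saturation plane of the HLS (HSL) decomposition
#'
#' Standard hexcone HSL saturation: with mx/mn the channel max/min and
#' L = (mx + mn)/2, \code{S = (mx - mn) / (1 - |2L - 1|)} and 0 on gray
#' pixels (mx = mn). Distinct from HSV saturation.
#'
#' @param image h x w x 3 array of 8-bit values.
#' @return matrix in [0, 1].
#' @export
hlsSaturation <- function(image) {
  assertRgbImage(image)
  r <- image[, , 1] / 255; g <- image[, , 2] / 255; b <- image[, , 3] / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  denom <- 1 - abs(2 * l - 1)
  s <- ifelse(mx > mn & denom > 0, (mx - mn) / denom, 0)
  pmin(pmax(s, 0), 1)
}

#' The 12 colour planes used for feature extraction
#'
#' Returns the channels of the RGB, HSV, CIELAB and YCbCr representations
#' of the crop, each rescaled to [0, 1], in the canonical order of
#' [channelNames()]. Conversion conventions are documented in the package
#' source header of this file.
#'
#' @param image h x w x 3 array of 8-bit values.
#' @return named list of 12 matrices, all in [0, 1].
#' @export
featureChannels <- function(image) {
  assertRgbImage(image)
  d <- dim(image)[1:2]
  r <- image[, , 1] / 255; g <- image[, , 2] / 255; b <- image[, , 3] / 255

  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 1)
  H <- matrix(hsv[1, ], d[1], d[2])
  S_hsv <- matrix(hsv[2, ], d[1], d[2])
  V <- matrix(hsv[3, ], d[1], d[2])

  lab <- grDevices::convertColor(cbind(as.vector(r), as.vector(g),
                                       as.vector(b)),
                                 from = "sRGB", to = "Lab")
  L_lab <- matrix(pmin(pmax(lab[, 1] / 100, 0), 1), d[1], d[2])
  a_lab <- matrix(pmin(pmax((lab[, 2] + 128) / 255, 0), 1), d[1], d[2])
  b_lab <- matrix(pmin(pmax((lab[, 3] + 128) / 255, 0), 1), d[1], d[2])

  Y <- .lumaWeights[1] * r + .lumaWeights[2] * g + .lumaWeights[3] * b
  Cr <- pmin(pmax(0.713 * (r - Y) + 0.5, 0), 1)
  Cb <- pmin(pmax(0.564 * (b - Y) + 0.5, 0), 1)

  list(R = r, G = g, B = b, H = H, S_hsv = S_hsv, V = V,
       L_lab = L_lab, a_lab = a_lab, b_lab = b_lab,
       Y = Y, Cr = Cr, Cb = Cb)
}
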