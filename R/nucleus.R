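## Nucleus segmentation: soft map -> Otsu threshold -> post-processing.

#' Compute the nucleus soft map of a crop
#'
#' Applies colour balancing, then combines the CMYK K and M planes with
#' the HLS saturation plane:
#' \code{KM = clip(K - M, 0, 1)}, \code{MS = min(M, S)}, and the map is
#' \code{clip(MS - KM, 0, 1)}. On stained smears K - M is high on red
#' blood cells and cytoplasm and near zero on the nucleus, while min(M, S)
#' is near zero on background and red cells, so the difference isolates
#' nucleus evidence. Negative differences carry no nucleus evidence and
#' are clipped at zero, keeping the map well-posed for Otsu thresholding.
#'
#' @param image h x w x 3 array of 8-bit values.
#' @return a \linkS4class{SoftMap}.
#' @export
softMap <- function(image) {
  assertRgbImage(image)
  bal <- balanceColors(image)
  km <- cmykPlanes(bal)
  s <- hlsSaturation(bal)
  kmPlane <- pmin(pmax(km$K - km$M, 0), 1)
  msPlane <- pmin(km$M, s)
  vals <- pmin(pmax(msPlane - kmPlane, 0), 1)
  new("SoftMap", values = vals, km = kmPlane, ms = msPlane)
}

.quantize255 <- function(values) as.integer(round(values * 255))

#' Otsu threshold of a soft map
#'
#' Quantizes the map to 256 uniform bins over [0, 1] (8-bit convention)
#' and returns the threshold maximizing the between-class variance; ties
#' are broken by the lowest qualifying threshold. Foreground is defined as
#' the pixels strictly above the returned threshold. A constant map (a
#' single occupied bin) admits no separating threshold and yields
#' \code{NA} (the degenerate-map signal; callers return an empty mask).
#'
#' @param map a \linkS4class{SoftMap} or a numeric matrix with values in
#'   [0, 1].
#' @return threshold on the [0, 1] scale (a multiple of 1/255), or
#'   \code{NA_real_} for a degenerate map.
#' @export
otsuThreshold <- function(map) {
  values <- if (is(map, "SoftMap")) map@values else map
  if (!is.numeric(values) || any(!is.finite(values)) ||
      any(values < 0) || any(values > 1))
    stop("invalid input: map values must be finite and in [0, 1]",
         call. = FALSE)
  lev <- .quantize255(values)
  cnt <- tabulate(lev + 1L, nbins = 256L)
  if (sum(cnt > 0L) < 2L) return(NA_real_)
  p <- cnt / sum(cnt)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  muT <- mu[256L]
  w0 <- omega[1:255]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma <- rep(-Inf, 255L)
  sigma[valid] <- (muT * w0[valid] - mu[1:255][valid])^2 /
    (w0[valid] * w1[valid])
  (which.max(sigma) - 1L) / 255
}

#' Clean a raw thresholded mask into the final nucleus mask
#'
#' Fills interior holes, removes connected components smaller than 1% of
#' the image area, and (unless \code{keepAll}) keeps the single surviving
#' component whose centroid lies nearest the image centre -- the target
#' cell of a single-cell crop. Returns an empty mask if nothing survives.
#' \code{keepAll = TRUE} retains every surviving component, which can be
#' preferable when the lobes of a multi-lobed nucleus disconnect.
#'
#' @param raw logical matrix.
#' @param keepAll keep all components passing the area filter?
#' @return logical matrix.
#' @export
postprocessMask <- function(raw, keepAll = FALSE) {
  if (!is.logical(raw) || !is.matrix(raw))
    stop("invalid input: mask must be a logical matrix", call. = FALSE)
  if (!any(raw)) return(raw)
  filled <- EBImage::fillHull(matrix(as.integer(raw), nrow(raw), ncol(raw)))
  lab <- EBImage::bwlabel(filled)
  n <- max(lab)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= 0.01 * length(raw))
  if (!length(keep)) return(matrix(FALSE, nrow(raw), ncol(raw)))
  if (!keepAll && length(keep) > 1L) {
    ctr <- c((nrow(raw) + 1) / 2, (ncol(raw) + 1) / 2)
    d2 <- vapply(keep, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      (mean(idx[, 1]) - ctr[1])^2 + (mean(idx[, 2]) - ctr[2])^2
    }, numeric(1))
    keep <- keep[which.min(d2)]  # ties resolve to the smallest label
  }
  matrix(lab %in% keep, nrow(raw), ncol(raw))
}

#' Segment the nucleus of a single-cell crop
#'
#' Full deterministic chain: soft map, Otsu threshold (foreground strictly
#' above), post-processing. A degenerate soft map (for example a blank
#' image) produces an empty mask with a warning.
#'
#' @param image h x w x 3 array of 8-bit values.
#' @param keepAll passed to [postprocessMask()].
#' @return logical matrix, the nucleus mask (at most one connected
#'   component unless \code{keepAll}).
#' @export
segmentNucleus <- function(image, keepAll = FALSE) {
  sm <- softMap(image)
  th <- otsuThreshold(sm)
  if (is.na(th)) {
    warning("degenerate soft map: no separating threshold; returning an ",
            "empty mask")
    return(matrix(FALSE, nrow(sm@values), ncol(sm@values)))
  }
  lev <- .quantize255(sm@values)
  raw <- matrix(lev > as.integer(round(th * 255)),
                nrow(sm@values), ncol(sm@values))
  postprocessMask(raw, keepAll = keepAll)
}
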