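## Cytoplasm proxy: convex hull of the nucleus and the ROC region.

#' Rasterized convex hull of a binary mask
#'
#' Computes the convex hull polygon of all nucleus pixel centres
#' (\code{grDevices::chull}) and rasterizes it: a pixel belongs to the
#' hull if its centre lies inside or on the polygon. The hull is taken
#' over the union of all pixels, not per component, so the hull of a
#' multi-lobed nucleus spans the inter-lobe cytoplasm -- the region the
#' ROC features exploit. Degenerate inputs (fewer than three pixels, or
#' all pixels collinear) are their own hull.
#'
#' @param mask non-empty logical matrix.
#' @return logical matrix containing \code{mask}.
#' @export
convexHullMask <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("invalid input: mask must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("empty region: mask has no pixels", call. = FALSE)
  pts <- which(mask, arr.ind = TRUE)  # (row, col) pixel centres
  hIdx <- grDevices::chull(pts[, 2], pts[, 1])
  vx <- pts[hIdx, 2]; vy <- pts[hIdx, 1]
  nv <- length(hIdx)
  if (nv < 3L) return(mask)
  ## orientation via the shoelace signed area
  area2 <- sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)
  if (abs(area2) < 1e-9) return(mask)  # collinear hull
  orient <- sign(area2)
  X <- col(mask); Y <- row(mask)
  inside <- matrix(TRUE, nrow(mask), ncol(mask))
  tol <- 1e-9
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (vx[j] - vx[i]) * (Y - vy[i]) - (vy[j] - vy[i]) * (X - vx[i])
    inside <- inside & (orient * cross >= -tol)
  }
  inside | mask
}

#' ROC mask: hull minus nucleus
#'
#' The representative of the cytoplasm: every pixel inside the convex
#' hull of the nucleus that is not nucleus. Empty when the rasterized
#' nucleus is convex; the more convex the nucleus, the smaller the ROC.
#'
#' @param nucleus logical matrix.
#' @param hull logical matrix covering \code{nucleus}.
#' @return logical matrix.
#' @export
rocMask <- function(nucleus, hull) {
  if (!identical(dim(nucleus), dim(hull)))
    stop("inconsistent regions: masks differ in shape", call. = FALSE)
  if (any(nucleus & !hull))
    stop("inconsistent regions: nucleus is not contained in hull",
         call. = FALSE)
  hull & !nucleus
}

#' Build the nucleus / hull / ROC region triplet
#'
#' @param nucleusMask non-empty logical matrix, a segmented nucleus.
#' @return a \linkS4class{CellRegions}.
#' @export
cellRegions <- function(nucleusMask) {
  h <- convexHullMask(nucleusMask)
  new("CellRegions", nucleus = nucleusMask, hull = h,
      roc = rocMask(nucleusMask, h))
}
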