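## The 51-dimensional feature vector: 3 nucleus shape descriptors plus
## 4 colour ratios on each of the 12 canonical channels.
##
## Fixed measurement conventions:
##  * area is the pixel count of the mask;
##  * perimeter is the length of the closed polygon traced through the
##    centres of the boundary pixels (Moore contour, as returned by
##    EBImage::ocontour), summed over connected components. A 10 x 10
##    filled square therefore has perimeter 36 (four 9-unit sides);
##  * region statistics are population statistics (divide by n, not n-1);
##  * features are computed on the ORIGINAL crop -- colour balancing
##    lives inside segmentation only.

#' Canonical names of the 51 features
#'
#' Order: solidity, convexity, circularity, then for each of the 12
#' channels of [channelNames()] the four ratios mean(nucleus)/mean(hull),
#' sd(nucleus)/sd(hull), mean(ROC)/mean(hull), sd(ROC)/sd(hull).
#'
#' @return character vector of length 51.
#' @export
featureNames <- function() {
  ratios <- c("meanNucOverHull", "sdNucOverHull",
              "meanRocOverHull", "sdRocOverHull")
  c("solidity", "convexity", "circularity",
    as.vector(t(outer(channelNames(), ratios, paste, sep = "_"))))
}

.contourPerimeter <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  sum(vapply(EBImage::ocontour(lab), function(oc) {
    if (nrow(oc) < 2L) return(0)
    d <- rbind(diff(oc), oc[1L, ] - oc[nrow(oc), ])
    sum(sqrt(rowSums(d^2)))
  }, numeric(1)))
}

#' Area and perimeter of the nucleus and its convex hull
#'
#' @param regions a \linkS4class{CellRegions} with a non-empty nucleus of
#'   at least 16 pixels (smaller regions are artefacts and rejected).
#' @return named numeric: \code{areaNucleus}, \code{perimNucleus},
#'   \code{areaHull}, \code{perimHull}.
#' @export
shapeMeasures <- function(regions) {
  stopifnot(is(regions, "CellRegions"))
  a <- sum(regions@nucleus)
  if (a == 0L) stop("empty region: nucleus has no pixels", call. = FALSE)
  if (a < 16L)
    stop("invalid input: nucleus below the minimum region size (16 px)",
         call. = FALSE)
  c(areaNucleus = a,
    perimNucleus = .contourPerimeter(regions@nucleus),
    areaHull = sum(regions@hull),
    perimHull = .contourPerimeter(regions@hull))
}

#' Nucleus shape descriptors
#'
#' \code{solidity = areaNucleus / areaHull},
#' \code{convexity = perimHull / perimNucleus},
#' \code{circularity = perimNucleus^2 / (4 pi areaNucleus)}
#' (the isoperimetric quotient; 1 for an analytic circle).
#'
#' @param m measures as returned by [shapeMeasures()].
#' @return named numeric: solidity, convexity, circularity.
#' @export
shapeFeatures <- function(m) {
  req <- c("areaNucleus", "perimNucleus", "areaHull", "perimHull")
  if (!all(req %in% names(m)) || any(m[req] <= 0))
    stop("invalid input: incomplete or non-positive shape measures",
         call. = FALSE)
  c(solidity = unname(m["areaNucleus"] / m["areaHull"]),
    convexity = unname(m["perimHull"] / m["perimNucleus"]),
    circularity = unname(m["perimNucleus"]^2 / (4 * pi * m["areaNucleus"])))
}

.popStats <- function(values) {
  n <- length(values)
  if (n == 0L) return(c(mean = NA_real_, sd = NA_real_))
  mu <- mean(values)
  c(mean = mu, sd = sqrt(sum((values - mu)^2) / n))
}

#' Per-region statistics of one colour plane
#'
#' Population mean and standard deviation of the plane over the nucleus,
#' hull and ROC masks. ROC statistics are \code{NA} when the ROC is empty
#' (a perfectly convex nucleus).
#'
#' @param plane numeric matrix in [0, 1].
#' @param regions a \linkS4class{CellRegions} with non-empty nucleus.
#' @return list with numeric vectors \code{mean} and \code{sd}, each
#'   named nucleus / hull / roc.
#' @export
regionStats <- function(plane, regions) {
  stopifnot(is(regions, "CellRegions"))
  if (!identical(dim(plane), dim(regions@nucleus)))
    stop("invalid input: plane and regions differ in shape", call. = FALSE)
  sn <- .popStats(plane[regions@nucleus])
  sh <- .popStats(plane[regions@hull])
  sr <- .popStats(plane[regions@roc])
  list(mean = c(nucleus = sn[["mean"]], hull = sh[["mean"]],
                roc = sr[["mean"]]),
       sd = c(nucleus = sn[["sd"]], hull = sh[["sd"]], roc = sr[["sd"]]))
}

#' The 48 colour-ratio features
#'
#' For each channel, the four ratios in documented order. Guards keep the
#' vector finite: a hull statistic below 1e-6 zeroes that ratio, and an
#' empty ROC zeroes the two ROC ratios of every channel (a perfectly
#' convex nucleus genuinely has no ROC signal).
#'
#' @param stack list of 12 planes as from [featureChannels()].
#' @param regions a \linkS4class{CellRegions}.
#' @return named numeric of length 48.
#' @export
colorFeatures <- function(stack, regions) {
  stopifnot(is(regions, "CellRegions"))
  if (!identical(names(stack), channelNames()))
    stop("invalid input: stack must hold the 12 canonical channels",
         call. = FALSE)
  rocEmpty <- !any(regions@roc)
  ratio <- function(num, den) if (is.na(den) || den < 1e-6) 0 else num / den
  out <- numeric(0)
  for (ch in channelNames()) {
    st <- regionStats(stack[[ch]], regions)
    out <- c(out,
             ratio(st$mean[["nucleus"]], st$mean[["hull"]]),
             ratio(st$sd[["nucleus"]], st$sd[["hull"]]),
             if (rocEmpty) 0 else ratio(st$mean[["roc"]], st$mean[["hull"]]),
             if (rocEmpty) 0 else ratio(st$sd[["roc"]], st$sd[["hull"]]))
  }
  names(out) <- featureNames()[-(1:3)]
  out
}

#' Extract the full 51-feature vector from a crop
#'
#' Segments the nucleus, builds the region triplet, and concatenates the
#' three shape features with the 48 colour ratios computed on the original
#' (non-balanced) crop.
#'
#' @param image h x w x 3 array of 8-bit values.
#' @param keepAll passed to [segmentNucleus()].
#' @return named numeric of length 51, all finite.
#' @export
extractFeatures <- function(image, keepAll = FALSE) {
  mask <- segmentNucleus(image, keepAll = keepAll)
  if (!any(mask))
    stop("feature extraction failed: no nucleus found in image",
         call. = FALSE)
  regions <- cellRegions(mask)
  v <- c(shapeFeatures(shapeMeasures(regions)),
         colorFeatures(featureChannels(image), regions))
  names(v) <- featureNames()
  v
}
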