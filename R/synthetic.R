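## Parametric generator of Giemsa-like single-cell smear crops with exact
## ground truth, plus a separable Gaussian feature-space generator for
## classifier tests. The renderer emulates the colour relationships the
## segmentation method relies on: a dark low-G purple nucleus (high M),
## a pale low-chroma cytoplasm (small min(M, S)), salmon red-cell disks
## that never touch the target cell, a pale background, a mild per-channel
## illumination cast and uniform pixel noise. It does not model staining
## artefacts, occlusion, focus blur or camera response.

.defaultPalette <- function() {
  list(background = c(235, 230, 225),
       rbc = c(230, 140, 130),
       granule = c(70, 40, 110),
       nucleus = list(lymphocyte = c(90, 50, 140),
                      monocyte = c(110, 75, 150),
                      neutrophil = c(100, 60, 135),
                      eosinophil = c(105, 65, 130),
                      basophil = c(95, 60, 135)),
       cytoplasm = list(lymphocyte = c(205, 190, 215),
                        monocyte = c(200, 200, 220),
                        neutrophil = c(210, 195, 205),
                        eosinophil = c(220, 190, 195),
                        basophil = c(205, 190, 215)))
}

#' Parameters of one synthetic crop
#'
#' @param wbcClass one of the five leukocyte classes.
#' @param seed integer driving every random draw of [makeCrop()].
#' @param canvas square canvas side in pixels (at least 64; the default
#'   96 px holds a full cell with room for red-cell disks).
#' @param noise amplitude of the uniform pixel noise in intensity levels.
#' @param rbcCount number of red-cell disks; \code{NULL} draws 4..7.
#' @param palette colour centres; see the package vignette.
#' @return list of generator parameters.
#' @export
syntheticSpec <- function(wbcClass, seed = 1L, canvas = 96L, noise = 2,
                          rbcCount = NULL, palette = .defaultPalette()) {
  if (!wbcClass %in% wbcClasses())
    stop("invalid spec: unknown class '", wbcClass, "'", call. = FALSE)
  if (canvas < 64L)
    stop("invalid spec: geometry cannot fit a canvas below 64 px",
         call. = FALSE)
  list(wbcClass = wbcClass, seed = as.integer(seed),
       canvas = as.integer(canvas), noise = noise, rbcCount = rbcCount,
       palette = palette)
}

.ellipseMask <- function(n, cy, cx, a, b, theta) {
  dy <- row(matrix(0, n, n)) - cy
  dx <- col(matrix(0, n, n)) - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

.barMask <- function(n, y1, x1, y2, x2, hw) {
  py <- row(matrix(0, n, n)); px <- col(matrix(0, n, n))
  vy <- y2 - y1; vx <- x2 - x1
  len2 <- vy^2 + vx^2
  t <- pmin(pmax(((py - y1) * vy + (px - x1) * vx) / len2, 0), 1)
  (py - (y1 + t * vy))^2 + (px - (x1 + t * vx))^2 <= hw^2
}

## nucleus geometry per class; returns list(mask, extent) -- extent is the
## radius of the smallest centred disk containing the nucleus
.nucleusGeometry <- function(cls, n, cy, cx) {
  if (cls == "lymphocyte") {
    a <- stats::runif(1, 13, 16); b <- a * stats::runif(1, 0.88, 1)
    th <- stats::runif(1, 0, pi)
    m <- .ellipseMask(n, cy, cx, a, b, th)
    ## two shallow bumps keep the outline near-convex but not exactly so
    for (i in 1:2) {
      phi <- stats::runif(1, 0, 2 * pi)
      rb <- a * stats::runif(1, 0.16, 0.22)
      m <- m | .ellipseMask(n, cy + (b - rb / 2) * sin(phi),
                            cx + (a - rb / 2) * cos(phi), rb, rb, 0)
    }
    list(mask = m, extent = a * 1.25)
  } else if (cls == "monocyte") {
    a <- stats::runif(1, 17, 20); b <- a * stats::runif(1, 0.8, 0.95)
    th <- stats::runif(1, 0, pi)
    m <- .ellipseMask(n, cy, cx, a, b, th)
    phi <- stats::runif(1, 0, 2 * pi)
    ri <- a * stats::runif(1, 0.45, 0.55)
    bite <- .ellipseMask(n, cy + (b + ri * 0.1) * sin(phi),
                         cx + (a + ri * 0.1) * cos(phi), ri, ri, 0)
    list(mask = m & !bite, extent = a * 1.1)
  } else if (cls %in% c("neutrophil", "eosinophil")) {
    L <- if (cls == "neutrophil") sample(3:4, 1) else 2L
    r <- if (cls == "neutrophil") stats::runif(1, 7.5, 9.5)
         else stats::runif(1, 9, 11)
    gap <- if (cls == "neutrophil") 1.9 else 2.3  # chord between lobes / r
    span <- switch(as.character(L), "2" = pi, "3" = 2.3, "4" = pi)
    A <- gap * r / (2 * sin(span / (L - 1) / 2))
    rot <- stats::runif(1, 0, 2 * pi)
    ang <- rot + seq(-span / 2, span / 2, length.out = L)
    ys <- cy + A * sin(ang); xs <- cx + A * cos(ang)
    m <- matrix(FALSE, n, n)
    for (i in seq_len(L)) {
      ri <- r * stats::runif(1, 0.9, 1.05)
      m <- m | .ellipseMask(n, ys[i], xs[i], ri,
                            ri * stats::runif(1, 0.85, 1),
                            stats::runif(1, 0, pi))
    }
    for (i in seq_len(L - 1))  # chromatin bridges keep the lobes connected
      m <- m | .barMask(n, ys[i], xs[i], ys[i + 1], xs[i + 1], 0.3 * r)
    list(mask = m, extent = A + r * 1.1)
  } else {  # basophil: the whole granulated cell is the target region
    a <- stats::runif(1, 16, 19); b <- a * stats::runif(1, 0.9, 1)
    th <- stats::runif(1, 0, pi)
    m <- .ellipseMask(n, cy, cx, a, b, th)
    for (i in 1:3) {
      phi <- stats::runif(1, 0, 2 * pi)
      rb <- a * stats::runif(1, 0.15, 0.2)
      m <- m | .ellipseMask(n, cy + (b - rb / 2) * sin(phi),
                            cx + (a - rb / 2) * cos(phi), rb, rb, 0)
    }
    list(mask = m, extent = a * 1.25)
  }
}

.jitterColor <- function(center, amount = 6) {
  pmin(pmax(center + stats::runif(3, -amount, amount), 0), 255)
}

#' Render one synthetic labelled crop
#'
#' Deterministic for a fixed spec (byte-identical across runs). The
#' ground-truth mask equals the rasterized nucleus geometry exactly; for
#' basophils, whose granules obscure the nucleus, it is the whole cell.
#'
#' @param spec from [syntheticSpec()].
#' @return a \linkS4class{LabeledCrop}.
#' @export
makeCrop <- function(spec) {
  n <- spec$canvas
  set.seed(spec$seed)
  cls <- spec$wbcClass
  pal <- spec$palette
  cy <- n / 2 + stats::runif(1, -3, 3)
  cx <- n / 2 + stats::runif(1, -3, 3)

  geo <- .nucleusGeometry(cls, n, cy, cx)
  if (geo$extent * 1.3 > n / 2)
    stop("invalid spec: cell geometry cannot fit the canvas", call. = FALSE)
  nucMask <- geo$mask

  cytExtent <- geo$extent * stats::runif(1, 1.25, 1.45)
  cytMask <- if (cls == "basophil") nucMask else
    .ellipseMask(n, cy, cx, cytExtent,
                 cytExtent * stats::runif(1, 0.9, 1),
                 stats::runif(1, 0, pi)) | nucMask

  img <- array(rep(.jitterColor(pal$background, 4), each = n * n),
               dim = c(n, n, 3))

  rbcN <- if (is.null(spec$rbcCount)) sample(4:7, 1) else spec$rbcCount
  rbcCol <- .jitterColor(pal$rbc)
  placed <- 0L; tries <- 0L
  while (placed < rbcN && tries < 200L) {
    tries <- tries + 1L
    r <- stats::runif(1, 7, 9)
    ry <- stats::runif(1, r * 0.5, n - r * 0.5)
    rx <- stats::runif(1, r * 0.5, n - r * 0.5)
    if (sqrt((ry - cy)^2 + (rx - cx)^2) < cytExtent + r + 2) next
    d <- .ellipseMask(n, ry, rx, r, r * stats::runif(1, 0.9, 1),
                      stats::runif(1, 0, pi))
    for (c in 1:3) { ch <- img[, , c]; ch[d] <- rbcCol[c]; img[, , c] <- ch }
    placed <- placed + 1L
  }

  cytCol <- .jitterColor(pal$cytoplasm[[cls]])
  nucCol <- .jitterColor(pal$nucleus[[cls]])
  for (c in 1:3) {
    ch <- img[, , c]
    if (cls != "basophil") ch[cytMask] <- cytCol[c]
    ch[nucMask] <- nucCol[c]
    img[, , c] <- ch
  }
  if (cls == "basophil") {  # dark granules speckling the whole cell
    inCell <- which(nucMask)
    gr <- inCell[stats::runif(length(inCell)) < 0.3]
    grCol <- .jitterColor(pal$granule)
    for (c in 1:3) { ch <- img[, , c]; ch[gr] <- grCol[c]; img[, , c] <- ch }
  }

  gain <- stats::runif(3, 0.95, 1.05)
  for (c in 1:3) img[, , c] <- img[, , c] * gain[c]
  nz <- spec$noise
  if (nz > 0)
    img <- img + array(stats::runif(length(img), -nz, nz), dim = dim(img))
  img <- array(pmin(pmax(round(img), 0), 255), dim = dim(img))

  new("LabeledCrop", image = img, truth = nucMask, label = cls, spec = spec)
}

#' Generate a balanced synthetic dataset
#'
#' Exactly \code{nPerClass} crops of each of the five classes, with
#' per-crop parameters drawn from the documented ranges. Reproducible:
#' the per-crop seeds derive from \code{seed}.
#'
#' @param nPerClass crops per class (at least 1).
#' @param seed integer.
#' @param canvas canvas side in pixels.
#' @return list of \linkS4class{LabeledCrop}, length \code{5 * nPerClass}.
#' @export
makeDataset <- function(nPerClass, seed = 1L, canvas = 96L) {
  stopifnot(nPerClass >= 1L)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 5L * nPerClass)
  crops <- vector("list", 5L * nPerClass)
  i <- 0L
  for (cls in wbcClasses()) {
    for (j in seq_len(nPerClass)) {
      i <- i + 1L
      crops[[i]] <- makeCrop(syntheticSpec(cls, seed = seeds[i],
                                           canvas = canvas))
    }
  }
  crops
}

#' Separable Gaussian feature-space dataset
#'
#' Five 51-dimensional Gaussian clusters, one per class, with
#' inter-mean distance \code{separation} times the per-dimension
#' within-class standard deviation (class means sit on orthonormal
#' directions). Values are clamped into plausible feature ranges (shape
#' entries [0, 2], ratios [0, 3]).
#'
#' @param nPerClass samples per class.
#' @param separation non-negative separation multiplier.
#' @param seed integer.
#' @return list with \code{features} (matrix, named columns in
#'   [featureNames()] order) and \code{labels}.
#' @export
makeFeatureDataset <- function(nPerClass, separation = 10, seed = 1L) {
  stopifnot(nPerClass >= 1L, separation >= 0)
  set.seed(seed)
  p <- 51L
  sigma <- 0.05
  base <- c(0.9, 0.95, 1.2, rep(1, 48))
  Q <- qr.Q(qr(matrix(stats::rnorm(p * 5L), p, 5L)))
  offsets <- Q * separation * sigma / sqrt(2)
  classes <- wbcClasses()
  X <- matrix(NA_real_, 5L * nPerClass, p)
  labels <- character(5L * nPerClass)
  for (ci in seq_along(classes)) {
    rows <- (ci - 1L) * nPerClass + seq_len(nPerClass)
    mu <- base + offsets[, ci]
    X[rows, ] <- matrix(mu, nPerClass, p, byrow = TRUE) +
      matrix(stats::rnorm(nPerClass * p, 0, sigma), nPerClass, p)
    labels[rows] <- classes[ci]
  }
  X[, 1:3] <- pmin(pmax(X[, 1:3], 0), 2)
  X[, 4:51] <- pmin(pmax(X[, 4:51], 0), 3)
  colnames(X) <- featureNames()
  list(features = X, labels = labels)
}
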