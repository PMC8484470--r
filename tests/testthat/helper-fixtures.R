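# Shared in-code fixtures: tiny images, masks and exact transforms.

flatImage <- function(r, g, b, h = 16, w = 16) {
  a <- array(0, dim = c(h, w, 3))
  a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
  a
}

# exact 90-degree rotations (no resampling)
rot90Matrix <- function(m) {
  b <- t(m)
  b[nrow(b):1, , drop = FALSE]
}

rot90Image <- function(a) {
  b <- aperm(a, c(2, 1, 3))
  b[dim(b)[1]:1, , , drop = FALSE]
}

diskMask <- function(n, cy, cx, r) {
  m <- matrix(FALSE, n, n)
  m[(row(m) - cy)^2 + (col(m) - cx)^2 <= r^2] <- TRUE
  m
}

# independent scalar (per-pixel loop) oracle for the soft-map planes
scalarPlanesOracle <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  K <- M <- S <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r <- image[i, j, 1] / 255; g <- image[i, j, 2] / 255
    b <- image[i, j, 3] / 255
    mx <- max(r, g, b); mn <- min(r, g, b)
    K[i, j] <- 1 - mx
    M[i, j] <- if (mx > 0) (1 - g - (1 - mx)) / mx else 0
    l <- (mx + mn) / 2
    S[i, j] <- if (mx == mn) 0 else (mx - mn) / (1 - abs(2 * l - 1))
  }
  list(K = K, M = M, S = S)
}

randomRgbImage <- function(h = 16, w = 16, lo = 0, hi = 255) {
  array(sample(lo:hi, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# brute-force Otsu: exhaustive scan of the 255 candidate thresholds
otsuBruteForce <- function(values) {
  lev <- as.integer(round(values * 255))
  cnt <- tabulate(lev + 1L, 256L)
  if (sum(cnt > 0L) < 2L) return(NA_real_)
  p <- cnt / sum(cnt)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:(t + 1)] * (0:t)) / w0
    mu1 <- sum(p[(t + 2):256] * ((t + 1):255)) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best) { best <- s; bt <- t }
  }
  bt / 255
}
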