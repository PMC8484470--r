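# Soft map, Otsu thresholding and the post-processing chain.

test_that("soft map vanishes on achromatic images", {
  sm <- softMap(flatImage(255, 255, 255))
  expect_true(all(softValues(sm) == 0))
  sm <- softMap(flatImage(120, 120, 120))  # S = 0 so MS = 0; clip at 0
  expect_true(all(softValues(sm) == 0))
})

test_that("soft map is higher on a purple disk than on the background", {
  crop <- makeCrop(syntheticSpec("lymphocyte", seed = 401))
  sm <- softMap(crop@image)
  v <- softValues(sm)
  expect_gt(mean(v[crop@truth]), mean(v[!crop@truth]))
  # independent per-pixel recomputation of the map from the balanced crop
  bal <- balanceColors(crop@image)
  o <- scalarPlanesOracle(bal)
  M <- pmin(pmax(o$M, 0), 1); S <- pmin(pmax(o$S, 0), 1)
  ref <- pmin(pmax(pmin(M, S) - pmin(pmax(o$K - M, 0), 1), 0), 1)
  expect_lt(max(abs(v - ref)), 1e-9)
})

test_that("Otsu separates a perfectly bimodal map and flags constants", {
  v <- matrix(rep(c(0, 1), each = 128), 16, 16)
  th <- otsuThreshold(v)
  expect_true(all((v > th) == (v == 1)))
  expect_true(is.na(otsuThreshold(matrix(0.4, 8, 8))))
})

test_that("Otsu equals the exhaustive between-class variance argmax", {
  set.seed(402)
  for (i in 1:30) {
    v <- matrix(runif(32 * 32)^runif(1, 0.3, 3), 32, 32)
    expect_identical(otsuThreshold(v), otsuBruteForce(v))
  }
})

test_that("post-processing fills holes, drops specks, keeps the centre", {
  # hole filling
  m <- diskMask(40, 20, 20, 10); m[20, 20] <- FALSE
  expect_true(all(postprocessMask(m) == diskMask(40, 20, 20, 10)))
  # a 0.2% corner speck disappears, the centred blob stays
  m <- diskMask(64, 32, 32, 12)
  m[2:3, 2:2] <- TRUE
  out <- postprocessMask(m)
  expect_true(all(out == diskMask(64, 32, 32, 12)))
  # two large blobs: the centred one wins; keepAll retains both
  m <- diskMask(64, 32, 32, 10) | diskMask(64, 8, 8, 8)
  expect_true(all(postprocessMask(m) == diskMask(64, 32, 32, 10)))
  expect_true(all(postprocessMask(m, keepAll = TRUE) == m))
  # empty input stays empty
  expect_false(any(postprocessMask(matrix(FALSE, 16, 16))))
})

test_that("segmentNucleus recovers synthetic ground truth", {
  crop <- makeCrop(syntheticSpec("monocyte", seed = 403))
  mask <- segmentNucleus(crop@image)
  expect_gte(segmentationMetrics(mask, crop@truth)[["dsc"]], 0.90)
  lab <- EBImage::bwlabel(matrix(as.integer(mask), nrow(mask)))
  expect_lte(max(lab), 1)
})

test_that("segmentation warns and returns empty on a blank crop", {
  expect_warning(m <- segmentNucleus(flatImage(255, 255, 255)),
                 "degenerate")
  expect_false(any(m))
})

test_that("segmentation commutes with exact 90-degree rotation", {
  crop <- makeCrop(syntheticSpec("neutrophil", seed = 404))
  m1 <- segmentNucleus(crop@image)
  m2 <- segmentNucleus(rot90Image(crop@image))
  expect_gte(segmentationMetrics(m2, rot90Matrix(m1))[["dsc"]], 0.98)
})

test_that("segmentation is robust to small pixel noise", {
  for (s in c(405, 406)) {
    crop <- makeCrop(syntheticSpec("eosinophil", seed = s))
    d0 <- segmentationMetrics(segmentNucleus(crop@image),
                              crop@truth)[["dsc"]]
    set.seed(s)
    noisy <- pmin(pmax(crop@image +
      array(sample(-2:2, length(crop@image), TRUE),
            dim = dim(crop@image)), 0), 255)
    d1 <- segmentationMetrics(segmentNucleus(noisy), crop@truth)[["dsc"]]
    expect_lt(abs(d1 - d0), 0.05)
  }
})

test_that("segmentation is byte-identical across runs", {
  crop <- makeCrop(syntheticSpec("basophil", seed = 407))
  expect_identical(segmentNucleus(crop@image), segmentNucleus(crop@image))
})
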