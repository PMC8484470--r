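# Shape measures, shape features, region statistics, colour ratios and
# the assembled 51-feature vector.

test_that("perimeter follows the traced pixel-centre polygon", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE  # 10 x 10 block
  m <- shapeMeasures(cellRegions(sq))
  expect_equal(m[["areaNucleus"]], 100)
  expect_equal(m[["perimNucleus"]], 36)  # four 9-unit sides
  # convex mask: hull measures equal nucleus measures
  expect_equal(m[["areaHull"]], m[["areaNucleus"]])
  expect_equal(m[["perimHull"]], m[["perimNucleus"]])
})

test_that("tiny regions are rejected by the minimum-size guard", {
  m <- matrix(FALSE, 16, 16); m[8, 8] <- TRUE
  expect_error(shapeMeasures(cellRegions(m)), "minimum region size")
})

test_that("shape features compute the documented closed forms", {
  f <- shapeFeatures(c(areaNucleus = 100, perimNucleus = 40,
                       areaHull = 100, perimHull = 40))
  expect_equal(f[["solidity"]], 1)
  expect_equal(f[["convexity"]], 1)
  expect_equal(f[["circularity"]], 1600 / (400 * pi))
  # analytic circle: isoperimetric identity
  r <- 10
  f <- shapeFeatures(c(areaNucleus = pi * r^2, perimNucleus = 2 * pi * r,
                       areaHull = pi * r^2, perimHull = 2 * pi * r))
  expect_equal(f[["circularity"]], 1)
  f <- shapeFeatures(c(areaNucleus = 50, perimNucleus = 30,
                       areaHull = 100, perimHull = 28))
  expect_equal(f[["solidity"]], 0.5)
})

test_that("shape features of raster shapes track analytic values", {
  # digital disk: solidity and convexity within raster tolerance of 1;
  # circularity carries the documented chain-code perimeter bias (< 12%)
  d <- diskMask(61, 31, 31, 22)
  f <- shapeFeatures(shapeMeasures(cellRegions(d)))
  expect_equal(f[["solidity"]], 1, tolerance = 0.03)
  expect_equal(f[["convexity"]], 1, tolerance = 0.03)
  expect_equal(f[["circularity"]], 1, tolerance = 0.12)
  expect_gte(f[["circularity"]], 0.95)
  # square
  sq <- matrix(FALSE, 24, 24); sq[5:20, 5:20] <- TRUE
  f <- shapeFeatures(shapeMeasures(cellRegions(sq)))
  expect_equal(f[["solidity"]], 1, tolerance = 0.03)
  expect_equal(f[["convexity"]], 1, tolerance = 0.03)
})

test_that("region statistics are population statistics per mask", {
  rg <- cellRegions(diskMask(30, 15, 15, 8) & !diskMask(30, 15, 20, 5))
  # constant plane
  st <- regionStats(matrix(0.4, 30, 30), rg)
  expect_true(all(abs(st$mean - 0.4) < 1e-12))
  expect_true(all(st$sd < 1e-12))
  # indicator plane: 1 on nucleus, 0 elsewhere
  ind <- matrix(0, 30, 30); ind[nucleus(rg)] <- 1
  st <- regionStats(ind, rg)
  expect_equal(st$mean[["nucleus"]], 1)
  expect_equal(st$mean[["roc"]], 0)
  # brute-force per-pixel accumulation oracle
  set.seed(601)
  pl <- matrix(runif(900), 30, 30)
  st <- regionStats(pl, rg)
  for (nm in c("nucleus", "hull", "roc")) {
    px <- pl[slot(rg, nm)]
    expect_equal(st$mean[[nm]], sum(px) / length(px), tolerance = 1e-12)
    expect_equal(st$sd[[nm]],
                 sqrt(sum((px - mean(px))^2) / length(px)),
                 tolerance = 1e-12)
  }
})

test_that("colour ratios honour the guard semantics", {
  rg <- cellRegions(diskMask(30, 15, 15, 8) & !diskMask(30, 15, 20, 5))
  img <- flatImage(120, 120, 120, 30, 30)
  cf <- colorFeatures(featureChannels(img), rg)
  expect_length(cf, 48)
  # constant image: mean ratios 1, sd ratios 0 (zero-denominator guard)
  expect_true(all(abs(cf[grep("meanNucOverHull", names(cf))] - 1) < 1e-9 |
                  cf[grep("meanNucOverHull", names(cf))] == 0))
  expect_true(all(cf[grep("sdNucOverHull", names(cf))] == 0))
  # convex nucleus: every ROC-based entry is 0
  rgc <- cellRegions(diskMask(30, 15, 15, 8))
  cfc <- colorFeatures(featureChannels(randomRgbImage(30, 30)), rgc)
  expect_true(all(cfc[grep("RocOverHull", names(cfc))] == 0))
})

test_that("colour ratios equal an independent channel-by-channel script", {
  crop <- makeCrop(syntheticSpec("monocyte", seed = 602))
  rg <- cellRegions(crop@truth)
  st <- featureChannels(crop@image)
  cf <- colorFeatures(st, rg)
  popsd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
  for (ch in channelNames()) {
    pl <- st[[ch]]
    nv <- pl[nucleus(rg)]; hv <- pl[hull(rg)]; rv <- pl[roc(rg)]
    expected <- c(mean(nv) / mean(hv), popsd(nv) / popsd(hv),
                  mean(rv) / mean(hv), popsd(rv) / popsd(hv))
    got <- cf[paste(ch, c("meanNucOverHull", "sdNucOverHull",
                          "meanRocOverHull", "sdRocOverHull"),
                    sep = "_")]
    expect_equal(unname(got), expected, tolerance = 1e-12)
  }
})

test_that("extractFeatures yields 51 finite values in stable order", {
  crop <- makeCrop(syntheticSpec("lymphocyte", seed = 603))
  v <- extractFeatures(crop@image)
  expect_length(v, 51)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), featureNames())
  expect_length(featureNames(), 51)
  # near-convex round nucleus
  expect_equal(v[["solidity"]], 1, tolerance = 0.02)
  expect_error(extractFeatures(flatImage(200, 200, 200)) |>
                 suppressWarnings(), "extraction failed")
})

test_that("features are invariant to flips and exact 90-degree rotation", {
  crop <- makeCrop(syntheticSpec("neutrophil", seed = 604))
  v0 <- extractFeatures(crop@image)
  expect_lt(max(abs(extractFeatures(hflipCrop(crop@image)) - v0)), 1e-6)
  expect_lt(max(abs(extractFeatures(vflipCrop(crop@image)) - v0)), 1e-6)
  expect_lt(max(abs(extractFeatures(rot90Image(crop@image)) - v0)), 1e-3)
})

test_that("lymphocyte fixtures are more solid than neutrophil fixtures", {
  sol <- function(cls, seeds) mean(sapply(seeds, function(s)
    extractFeatures(makeCrop(syntheticSpec(cls, seed = s))@image)[["solidity"]]))
  seeds <- 605:609
  expect_gt(sol("lymphocyte", seeds), sol("neutrophil", seeds))
})
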