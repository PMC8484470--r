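# Min-max normalization, weighted SVM training/prediction and the grid
# search.

test_that("min-max normalization maps training features into [0, 1]", {
  x <- cbind(a = c(0, 5, 10), b = c(3, 3, 3))
  norm <- fitNorm(x)
  xn <- applyNorm(x, norm)
  expect_equal(xn[, "a"], c(0, 0.5, 1))
  expect_equal(xn[, "b"], c(0, 0, 0))  # constant feature maps to 0
  # out-of-range test values are clamped
  xt <- applyNorm(cbind(a = c(-5, 20), b = c(9, 9)), norm)
  expect_equal(xt[, "a"], c(0, 1))
  expect_error(fitNorm(matrix(1, 1, 3)), "at least 2")
})

test_that("the paper-default config trains and separable data classify", {
  d <- makeFeatureDataset(10, separation = 10, seed = 701)
  model <- trainWBC(d$features, d$labels, svmConfig(), seed = 1)
  expect_s4_class(model, "WBCModel")
  expect_identical(model@config@kernel, "poly3")
  # training points of a separable set get their own labels back
  expect_identical(predict(model, d$features), d$labels)
  # permuting input order permutes output identically
  perm <- sample(nrow(d$features))
  expect_identical(predict(model, d$features[perm, ]), d$labels[perm])
})

test_that("training input guards fire", {
  d <- makeFeatureDataset(5, separation = 5, seed = 702)
  one <- d$labels == "monocyte"
  expect_error(trainWBC(d$features[one, ], d$labels[one]), "two classes")
  expect_error(trainWBC(d$features[, 1:10], d$labels), "length 51")
  model <- trainWBC(d$features, d$labels)
  expect_error(predict(model, matrix(0, 2, 10)), "features")
  bad <- d$features
  colnames(bad) <- rev(colnames(bad))
  expect_error(predict(model, bad), "fingerprint")
})

test_that("a saved and reloaded model predicts identically", {
  d <- makeFeatureDataset(8, separation = 6, seed = 703)
  model <- trainWBC(d$features, d$labels)
  p0 <- predict(model, d$features)
  f <- tempfile(fileext = ".rds")
  saveModel(model, f)
  expect_identical(predict(loadModel(f), d$features), p0)
  unlink(f)
})

test_that("the hyperparameter grid enumerates 108 configurations", {
  g <- gridConfigs()
  expect_equal(nrow(g), 108)
  expect_setequal(unique(g$kernel), c("linear", "rbf", "poly3"))
  expect_setequal(unique(g$neutWeight), c(1, 2, 5, 10, 15, 20))
  expect_setequal(unique(g$C), c(1, 2, 4, 6, 8, 10))
  expect_equal(nrow(unique(g)), 108)
})

test_that("grid search cross-validates all configs and is reproducible", {
  d <- makeFeatureDataset(10, separation = 10, seed = 704)
  gs1 <- gridSearchWBC(d$features, d$labels, seed = 2)
  expect_equal(nrow(gs1$table), 108)
  # a strongly separable set succeeds under every configuration
  expect_true(all(gs1$table$meanAcc >= 0.9))
  expect_true(all(gs1$table$meanAcc <= 1))
  gs2 <- gridSearchWBC(d$features, d$labels, seed = 2)
  expect_identical(gs1$table, gs2$table)
  expect_identical(gs1$best@kernel, gs2$best@kernel)
  few <- c(1:10, 11:13)  # 10 lymphocytes but only 3 monocytes
  expect_error(gridSearchWBC(d$features[few, ], d$labels[few]),
               "at least 5")
})

test_that("fold-wise normalization is refit inside cross-validation", {
  d <- makeFeatureDataset(6, separation = 8, seed = 705)
  fold <- wbcseg:::.stratifiedFolds(d$labels, 5L, seed = 2)
  # replicate one fold of one config by hand and match the table entry
  cfg <- svmConfig("linear", C = 1, neutWeight = 1)
  accs <- sapply(1:5, function(f) {
    tr <- fold != f
    model <- trainWBC(d$features[tr, ], d$labels[tr], cfg, seed = 2)
    mean(predict(model, d$features[!tr, ]) == d$labels[!tr])
  })
  gs <- gridSearchWBC(d$features, d$labels, seed = 2)
  row <- gs$table[gs$table$kernel == "linear" & gs$table$C == 1 &
                    gs$table$neutWeight == 1, ]
  expect_equal(row$meanAcc, mean(accs), tolerance = 1e-12)
  expect_equal(row$sdAcc, sd(accs), tolerance = 1e-12)
})

test_that("raising the neutrophil weight does not hurt its sensitivity", {
  sens <- function(w, seed) {
    d <- makeFeatureDataset(14, separation = 1.2, seed = seed)
    tr <- rep(c(TRUE, FALSE), length.out = nrow(d$features))
    # under-represent neutrophils in training to create the imbalance
    drop <- which(d$labels == "neutrophil" & tr)
    drop <- drop[seq_len(floor(length(drop) * 0.5))]
    tr[drop] <- FALSE
    model <- trainWBC(d$features[tr, ], d$labels[tr],
                      svmConfig("rbf", C = 4, neutWeight = w), seed = 1)
    pred <- predict(model, d$features[!tr, ])
    truth <- d$labels[!tr]
    sum(pred == "neutrophil" & truth == "neutrophil") /
      sum(truth == "neutrophil")
  }
  lo <- sapply(706:710, function(s) sens(1, s))
  hi <- sapply(706:710, function(s) sens(20, s))
  expect_gte(mean(hi), mean(lo) - 0.02)
})
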