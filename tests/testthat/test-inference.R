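toyData <- function(n = 900L, p = 10L, seed = 123L) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- 3 * X[, 4L] + rnorm(n, sd = 0.05)
  list(X = X, y = y,
       tr = 1:600, va = 601:750, te = 751:900)
}

test_that("the standardizer follows the population-sd convention", {
  X <- cbind(a = c(0, 2), b = c(5, 5))
  std <- fitStandardizer(X)
  Xs <- applyStandardizer(std, X)
  expect_equal(Xs[, "a"], c(-1, 1))          # population sd of {0,2} is 1
  expect_equal(Xs[, "b"], c(0, 0))           # constant column -> zeros
  expect_equal(applyStandardizer(std, Xs, revert = TRUE), X,
               tolerance = 1e-12)

  set.seed(1)
  M <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, letters[1:10]))
  Ms <- applyStandardizer(fitStandardizer(M), M)
  expect_true(all(abs(colMeans(Ms)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(Ms^2)) - 1) < 1e-9))
})

test_that("a constant target is recovered by all methods", {
  d <- toyData()
  yc <- rep(42, length(d$tr))
  for (m in c("rf", "xgb", "mlp")) {
    cfg <- regressorConfig(m)
    if (m == "mlp") cfg <- regressorConfig(m, hidden = c(16L, 8L),
                                           maxEpochs = 60L)
    reg <- trainRegressor(cfg, d$X[d$tr, ], yc,
                          d$X[d$va, ], rep(42, length(d$va)),
                          target = "const", bounds = c(0, 100), seed = 2L)
    pred <- predictParams(reg, d$X[d$te, ])
    expect_equal(pred, rep(42, length(d$te)), tolerance = 0.02)
  }
})

test_that("all three methods learn a noisy linear signal below the midpoint baseline", {
  d <- toyData()
  prior <- c(0, 3)
  for (m in c("rf", "xgb", "mlp")) {
    cfg <- regressorConfig(m)
    if (m == "mlp") cfg <- regressorConfig(m, hidden = c(64L, 32L),
                                           maxEpochs = 150L)
    reg <- trainRegressor(cfg, d$X[d$tr, ], d$y[d$tr],
                          d$X[d$va, ], d$y[d$va],
                          target = "toy", bounds = prior, seed = 3L)
    nmae <- computeMetrics(d$y[d$te], predictParams(reg, d$X[d$te, ]),
                           prior)$NMAE
    expect_lt(nmae, midpointBaselineNMAE())
  }
})

test_that("tree-method training is deterministic given the seed", {
  d <- toyData(n = 300L)
  fit2 <- function() {
    reg <- trainRegressor("rf", d$X[1:200, ], d$y[1:200],
                          target = "toy", bounds = c(0, 3), seed = 7L)
    predictParams(reg, d$X[251:300, ])
  }
  expect_identical(fit2(), fit2())
})

test_that("MLP predictions are clipped to the prior bounds", {
  d <- toyData(n = 400L)
  reg <- trainRegressor(regressorConfig("mlp", hidden = c(16L, 8L),
                                        maxEpochs = 40L),
                        d$X[1:250, ], d$y[1:250], d$X[251:320, ],
                        d$y[251:320], target = "toy", bounds = c(0, 3),
                        seed = 4L)
  # shrink the bounds after training: every prediction must respect them
  reg@bounds <- c(1.2, 1.8)
  pred <- predictParams(reg, d$X[321:400, ])
  expect_true(all(pred >= 1.2 & pred <= 1.8))
  expect_true(any(pred == 1.2) || any(pred == 1.8))  # clipping engaged
})

test_that("prediction validates and aligns the feature schema", {
  d <- toyData(n = 300L)
  reg <- trainRegressor("xgb", d$X[1:200, ], d$y[1:200], target = "toy",
                        bounds = c(0, 3), seed = 1L)
  Xte <- d$X[201:300, ]
  # reordered columns are aligned by name, not misread
  shuffled <- Xte[, rev(colnames(Xte))]
  expect_equal(predictParams(reg, shuffled), predictParams(reg, Xte))
  expect_error(predictParams(reg, Xte[, -3]), "mismatch")
  bad <- cbind(Xte, extra = 1)
  expect_error(predictParams(reg, bad), "extra")
})

test_that("non-finite features are rejected before fitting", {
  d <- toyData(n = 100L)
  Xb <- d$X[1:50, ]; Xb[3, 3] <- NA
  expect_error(trainRegressor("rf", Xb, d$y[1:50], target = "t",
                              bounds = c(0, 3)), "non-finite")
})
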