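test_that("permutation importance recovers the closed-form degradation", {
  set.seed(11)
  n <- 5000L
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- X[, 1]
  model <- function(M) M[, "x1"]           # the model IS x1
  imp <- permutationImportance(model, X, y, nRepeats = 5L, seed = 12L,
                               metric = "mse")
  # shuffling x1 raises the MSE by E(x1 - x1')^2 = 2 Var(x1)
  expect_equal(imp$perFeature$importance[1L], 2 * var(y), tolerance = 0.1)
  # features the model ignores have importance within noise of zero
  for (j in 2:3)
    expect_lt(abs(imp$perFeature$importance[j]),
              3 * max(imp$perFeature$sd[j], 1e-12))
})

test_that("a planted pure-noise feature gets zero importance from a real model", {
  set.seed(13)
  n <- 600L
  X <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * X[, 1] - X[, 2] + rnorm(n, sd = 0.1)
  reg <- trainRegressor("xgb", X[1:400, ], y[1:400], target = "t",
                        bounds = c(-2, 3), seed = 1L)
  imp <- permutationImportance(reg, X[401:600, ], y[401:600],
                               nRepeats = 10L, seed = 14L)
  noise <- imp$perFeature[imp$perFeature$feature == "f5", ]
  expect_lt(abs(noise$importance), 3 * noise$sd)
  # informative features dominate
  expect_gt(imp$perFeature$importance[1L], 10 * abs(noise$importance))
})

test_that("class importances are floored, normalized fractions", {
  sch <- buildSchema(sampleDesign(nDiploidPerPop = 4L, nLoci = 2L,
                                  locusLength = 1e5))
  feats <- featNames(sch)
  fstFeat <- feats[grepl("^Fst_", feats)][1L]
  dxyFeat <- feats[grepl("^Dxy_", feats)][1L]
  sfsFeat <- feats[grepl("^SFS_1_p1_", feats)][1L]
  report <- list(perFeature = data.frame(
    feature = c(fstFeat, dxyFeat, sfsFeat),
    importance = c(3, 1, -0.5), sd = c(0, 0, 0)))
  cls <- classImportance(report, sch)
  expect_equal(cls[["Fst"]], 0.75)
  expect_equal(cls[["Dxy"]], 0.25)
  expect_equal(cls[["SFS"]], 0)            # negative floored at zero
  expect_equal(sum(cls), 1, tolerance = 1e-12)

  # invariant to feature order
  report2 <- list(perFeature = report$perFeature[c(3, 1, 2), ])
  expect_equal(classImportance(report2, sch), cls)

  bad <- list(perFeature = data.frame(feature = "nope", importance = 1,
                                      sd = 0))
  expect_error(classImportance(bad, sch), "class")
})

test_that("tree-path Shapley values satisfy local accuracy", {
  set.seed(15)
  n <- 500L
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  # unit-scale target: the local-accuracy identity is exact up to the
  # booster's own single-precision arithmetic, which scales with |y|
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(n, sd = 0.1)
  y <- y / sd(y)
  reg <- trainRegressor("xgb", X[1:400, ], y[1:400], target = "t",
                        bounds = range(y), seed = 2L)
  sh <- shapleyValues(reg, X[1:100, ], X[401:500, ])
  expect_equal(sh$method, "treepath")
  resid <- rowSums(sh$phi) + sh$base - predictParams(reg, X[401:500, ])
  expect_lt(max(abs(resid)), 1e-6)
  # the informative features lead the mean-|phi| ranking
  expect_setequal(names(sh$meanAbs)[1:2], c("f1", "f3"))
})

test_that("the sampling estimator matches the linear closed form", {
  set.seed(16)
  Xb <- matrix(rnorm(4000 * 3), ncol = 3,
               dimnames = list(NULL, c("a", "b", "c")))
  f <- function(M) 2 * M[, "a"] + 1 * M[, "b"]
  sh <- shapleyValues(f, Xb, Xb[1:8, , drop = FALSE], seed = 17L,
                      nPerm = 400L)
  expect_equal(sh$method, "sampling")
  # linear model with independent features: phi_a = 2 (a - E[a])
  expect_equal(unname(sh$phi[, "a"]), 2 * (Xb[1:8, "a"] - mean(Xb[, "a"])),
               tolerance = 0.15)
  expect_equal(unname(sh$phi[, "c"]), rep(0, 8), tolerance = 0.1)
  # local accuracy w.r.t. the estimated base value is exact by construction
  resid <- rowSums(sh$phi) + sh$base - f(Xb[1:8, , drop = FALSE])
  expect_lt(max(abs(resid)), 1e-10)

  # constant model: all contributions vanish
  shc <- shapleyValues(function(M) rep(3, nrow(M)), Xb,
                       Xb[1:4, , drop = FALSE], seed = 1L, nPerm = 10L)
  expect_true(all(shc$phi == 0))
  expect_equal(unname(shc$base), rep(3, 4))
})

test_that("duplicated features share their Shapley credit", {
  set.seed(18)
  Xb <- matrix(rnorm(3000), ncol = 3,
               dimnames = list(NULL, c("a", "a2", "z")))
  Xb[, "a2"] <- Xb[, "a"]
  f <- function(M) M[, "a"] + M[, "a2"]
  sh <- shapleyValues(f, Xb, Xb[1:6, , drop = FALSE], seed = 19L,
                      nPerm = 600L)
  expect_equal(unname(sh$phi[, "a"]), unname(sh$phi[, "a2"]),
               tolerance = 0.15)
})

test_that("beeswarm data expose the top features with normalized values", {
  set.seed(20)
  Xb <- matrix(rnorm(500), ncol = 5, dimnames = list(NULL, paste0("f", 1:5)))
  f <- function(M) 3 * M[, 1]
  sh <- shapleyValues(f, Xb, Xb[1:20, ], seed = 2L, nPerm = 50L)
  bd <- shapBeeswarmData(sh, nTop = 3L)
  expect_equal(unique(bd$feature)[1L], "f1")
  expect_true(all(bd$value >= 0 & bd$value <= 1))
  expect_equal(nrow(bd), 3L * 20L)
})
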