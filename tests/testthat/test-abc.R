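abcToy <- function(n = 200L, p = 4L, seed = 5L, noise = 0.05) {
  set.seed(seed)
  S <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("s", 1:p)))
  theta <- 2 * S[, 1] - S[, 2] + rnorm(n, sd = noise)
  list(S = S, params = data.frame(theta = theta))
}

test_that("rejection keeps the nearest simulations under MAD scaling", {
  d <- abcToy()
  target <- d$S[13, ]
  res <- abcRejection(target, d$S, d$params, tolerance = 0.1)
  expect_equal(nrow(res@accepted), 20L)   # round(0.1 * 200)

  # brute-force nearest-neighbour enumeration with the same scaling rule
  mads <- apply(d$S, 2, mad)
  dist <- sqrt(colSums(((t(d$S) - target) / mads)^2))
  expect_equal(sort(res@acceptedIdx), sort(order(dist)[1:20]))
  expect_true(13L %in% res@acceptedIdx)   # zero-distance row always accepted

  # tolerance 1 reproduces the full prior sample
  all <- abcRejection(target, d$S, d$params, tolerance = 1)
  expect_equal(nrow(all@accepted), 200L)
  expect_equal(pointEstimate(all, "mean")[["theta"]], mean(d$params$theta))
})

test_that("local-linear adjustment collapses to truth under exact linearity", {
  d <- abcToy(noise = 0)           # theta is an exact linear function
  target <- d$S[7, ]
  res <- abcLoclinear(target, d$S, d$params, tolerance = 0.2)
  truth <- d$params$theta[7]
  expect_true(all(abs(res@adjusted$theta - truth) < 1e-6))
  expect_equal(pointEstimate(res, "median")[["theta"]], truth,
               tolerance = 1e-6)
})

test_that("a parameter unrelated to the statistics is left unadjusted", {
  d <- abcToy()
  d$params$theta <- rep(3.5, nrow(d$S))   # constant: zero regression signal
  res <- abcLoclinear(d$S[2, ], d$S, d$params, tolerance = 0.1)
  expect_equal(res@adjusted$theta, res@accepted$theta)
})

test_that("the weighted least-squares adjustment matches the normal equations", {
  set.seed(8)
  n <- 6L
  S <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("s1", "s2")))
  theta <- data.frame(theta = rnorm(n))
  target <- c(s1 = 0.1, s2 = -0.2)
  res <- abcLoclinear(target, S, theta, tolerance = 1, maxStats = 2L)

  # hand-computed: Epanechnikov weights on MAD-scaled distances, then
  # solve (Z' W Z) b = Z' W y with Z = [1, s - s_target]
  mads <- apply(S, 2, mad)
  d <- sqrt(colSums(((t(S) - target) / mads)^2))
  ord <- order(d)
  w <- 1 - (d[ord] / (max(d[ord]) * (1 + 1e-12)))^2
  Sc <- sweep(S[ord, , drop = FALSE], 2, target, "-")
  Z <- cbind(1, Sc)
  beta <- solve(t(Z) %*% diag(w) %*% Z, t(Z) %*% diag(w) %*%
                  theta$theta[ord])
  adj <- theta$theta[ord] - Sc %*% beta[-1]
  expect_equal(res@adjusted$theta, as.vector(adj), tolerance = 1e-9)
})

test_that("the neural-network adjustment improves on rejection for linear truth", {
  d <- abcToy(n = 500L, seed = 9L, noise = 0.02)
  truth <- 2 * 0.3 - (-0.1)                # theta at the target statistics
  target <- c(s1 = 0.3, s2 = -0.1, s3 = 0, s4 = 0)
  rej <- abcRejection(target, d$S, d$params, tolerance = 0.1)
  nn <- abcNeuralnet(target, d$S, d$params, tolerance = 0.1, seed = 2L)
  errRej <- abs(pointEstimate(rej, "mean")[["theta"]] - truth)
  errNN <- abs(pointEstimate(nn, "mean")[["theta"]] - truth)
  expect_lte(errNN, errRej)
  expect_error(abcNeuralnet(target, d$S, d$params, 0.1, hidden = 0L),
               "hidden")
})

test_that("acceptance counts follow the tolerance", {
  d <- abcToy(n = 2000L, seed = 3L)
  target <- d$S[1, ]
  counts <- vapply(c(5e-4, 5e-3, 5e-2), function(tol)
    nrow(abcRejection(target, d$S, d$params, tol)@accepted), integer(1))
  expect_equal(counts, c(1L, 10L, 100L))   # round(tol * n), floored at 1
  expect_true(all(diff(counts) > 0))
})

test_that("point estimates are the mean or median of the draws", {
  res <- new("ABCResult", algorithm = "rejection",
             accepted = data.frame(theta = c(1, 2, 9)), adjusted = NULL,
             acceptedIdx = 1:3, distances = c(0, 1, 2), tolerance = 0.5,
             selectedStats = character(), notes = character())
  expect_equal(pointEstimate(res, "mean")[["theta"]], 4)
  expect_equal(pointEstimate(res, "median")[["theta"]], 2)
  one <- new("ABCResult", algorithm = "rejection",
             accepted = data.frame(theta = 7), adjusted = NULL,
             acceptedIdx = 1L, distances = 0, tolerance = 0.01,
             selectedStats = character(), notes = character())
  expect_equal(pointEstimate(one, "mean"), pointEstimate(one, "median"))
})
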