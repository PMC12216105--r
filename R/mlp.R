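## Multilayer perceptron for regression, implemented in plain matrix
## algebra: fully connected ReLU layers, linear output, mean-squared-error
## loss, Adam updates, mini-batches, and early stopping on a validation
## set.  Written for moderate problem sizes (thousands of rows, a few
## thousand features) where BLAS matrix products carry the cost.

.mlpInit <- function(nIn, hidden, rng) {
  sizes <- c(nIn, hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    ## He initialization for ReLU layers
    sdv <- sqrt(2 / sizes[l])
    W[[l]] <- matrix(rng$rnorm(sizes[l] * sizes[l + 1L], sd = sdv),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

.mlpForward <- function(par, X) {
  nl <- length(par$W)
  A <- X
  for (l in seq_len(nl - 1L)) {
    A <- A %*% par$W[[l]]
    A <- sweep(A, 2L, par$b[[l]], "+")
    A[A < 0] <- 0
  }
  drop(A %*% par$W[[nl]] + par$b[[nl]])
}

## forward pass keeping activations, then backpropagation of the MSE
## gradient; returns the per-parameter gradients
.mlpGrad <- function(par, X, y, l1 = 0) {
  nl <- length(par$W)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- X
  A <- X
  for (l in seq_len(nl - 1L)) {
    A <- sweep(A %*% par$W[[l]], 2L, par$b[[l]], "+")
    A[A < 0] <- 0
    acts[[l + 1L]] <- A
  }
  pred <- drop(A %*% par$W[[nl]] + par$b[[nl]])
  n <- length(y)
  delta <- matrix(2 * (pred - y) / n, ncol = 1L)
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l1 > 0) gW[[l]] <- gW[[l]] + l1 * sign(par$W[[l]])
    if (l > 1L) {
      delta <- delta %*% t(par$W[[l]])
      delta[acts[[l]] <= 0] <- 0
    }
  }
  list(W = gW, b = gb)
}

#' Fit a multilayer perceptron regressor
#'
#' Trains a fully connected ReLU network with a linear output unit by
#' minibatch Adam on the mean squared error, monitoring a validation set
#' after every epoch and keeping the parameters of the best validation
#' epoch (early stopping after `patience` epochs without improvement).
#' Inputs and the target are expected pre-standardized by the caller.
#'
#' @param X,y training inputs (matrix) and target.
#' @param Xval,yval validation inputs and target (never used in the
#'   gradient).
#' @param hidden integer vector of hidden-layer widths.
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param maxEpochs epoch budget.
#' @param patience early-stopping patience (epochs).
#' @param l1 optional L1 penalty coefficient on the weights (0 = off).
#' @param seed integer seed controlling initialization and shuffling.
#' @return list with the fitted parameters (`par`), the validation curve
#'   and the stopping epoch; predict with [mlpPredict()].
#' @export
mlpFit <- function(X, y, Xval, yval, hidden = c(512L, 256L, 128L, 64L, 32L, 16L),
                   lr = 1e-3, batchSize = 128L, maxEpochs = 500L,
                   patience = 20L, l1 = 0, seed = 1L) {
  stopifnot(nrow(X) == length(y), nrow(Xval) == length(yval))
  rng <- localRNG(seed)
  par <- .mlpInit(ncol(X), hidden, rng)
  m <- rapply(par, function(p) p * 0, how = "replace")
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  best <- list(par = par, mse = Inf, epoch = 0L)
  curve <- numeric(0)
  n <- nrow(X)
  for (epoch in seq_len(maxEpochs)) {
    ord <- rng$sample(n, n)
    for (s in seq(1L, n, by = batchSize)) {
      idx <- ord[s:min(s + batchSize - 1L, n)]
      g <- .mlpGrad(par, X[idx, , drop = FALSE], y[idx], l1 = l1)
      t <- t + 1L
      corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
      for (l in seq_along(par$W)) {
        m$W[[l]] <- beta1 * m$W[[l]] + (1 - beta1) * g$W[[l]]
        v$W[[l]] <- beta2 * v$W[[l]] + (1 - beta2) * g$W[[l]]^2
        par$W[[l]] <- par$W[[l]] -
          lr * (m$W[[l]] / corr1) / (sqrt(v$W[[l]] / corr2) + eps)
        m$b[[l]] <- beta1 * m$b[[l]] + (1 - beta1) * g$b[[l]]
        v$b[[l]] <- beta2 * v$b[[l]] + (1 - beta2) * g$b[[l]]^2
        par$b[[l]] <- par$b[[l]] -
          lr * (m$b[[l]] / corr1) / (sqrt(v$b[[l]] / corr2) + eps)
      }
    }
    mse <- mean((.mlpForward(par, Xval) - yval)^2)
    curve <- c(curve, mse)
    if (mse < best$mse - 1e-12) {
      best <- list(par = par, mse = mse, epoch = epoch)
    } else if (epoch - best$epoch >= patience) break
  }
  list(par = best$par, valMSE = best$mse, epoch = best$epoch,
       curve = curve, hidden = hidden)
}

#' Predict from a fitted MLP
#'
#' @param fit result of [mlpFit()].
#' @param X input matrix (standardized like the training inputs).
#' @return numeric predictions (on the standardized target scale).
#' @export
mlpPredict <- function(fit, X) .mlpForward(fit$par, X)
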