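## Approximate Bayesian computation baselines: rejection sampling on
## MAD-scaled Euclidean distances, with optional local-linear or
## single-hidden-layer neural-network regression adjustment of the
## accepted draws (Epanechnikov kernel weights, correlation-based
## pre-selection of up to `maxStats` statistics per target parameter).

.abcScale <- function(refStats) {
  mads <- apply(refStats, 2L, stats::mad)
  keep <- which(is.finite(mads) & mads > 0)
  list(keep = keep, mad = mads[keep])
}

.abcDistances <- function(targetStats, refStats, scale) {
  R <- sweep(refStats[, scale$keep, drop = FALSE], 2L, scale$mad, "/")
  tg <- targetStats[scale$keep] / scale$mad
  sqrt(rowSums(sweep(R, 2L, tg, "-")^2))
}

.acceptCount <- function(tolerance, n) {
  if (tolerance <= 0 || tolerance > 1)
    stop("tolerance must be in (0, 1]")
  max(1L, round(tolerance * n))
}

#' ABC rejection sampling
#'
#' Accepts the `round(tolerance * n)` reference simulations closest to the
#' target in Euclidean distance over per-statistic MAD-scaled features
#' (statistics with zero MAD are dropped from the distance); the accepted
#' parameter draws form the posterior sample.  Distance ties are broken by
#' row index, so results are deterministic.
#'
#' @param targetStats named numeric vector of the target's statistics.
#' @param refStats reference statistic matrix (simulations x statistics).
#' @param refParams data.frame (or vector) of reference parameter draws.
#' @param tolerance proportion of reference simulations to accept.
#' @return an [ABCResult-class].
#' @export
abcRejection <- function(targetStats, refStats, refParams, tolerance) {
  refParams <- as.data.frame(refParams)
  n <- nrow(refStats)
  k <- .acceptCount(tolerance, n)
  scale <- .abcScale(refStats)
  d <- .abcDistances(targetStats, refStats, scale)
  idx <- order(d)[seq_len(k)]
  new("ABCResult", algorithm = "rejection",
      accepted = refParams[idx, , drop = FALSE],
      adjusted = NULL, acceptedIdx = as.integer(idx), distances = d[idx],
      tolerance = tolerance,
      selectedStats = colnames(refStats)[scale$keep] %||% character(),
      notes = character())
}

## Statistics most correlated (in absolute value) with the parameter.
.selectStats <- function(refStats, y, maxStats) {
  cors <- suppressWarnings(abs(stats::cor(refStats, y)))
  cors[!is.finite(cors)] <- 0
  ord <- order(cors, decreasing = TRUE)
  ord[seq_len(min(maxStats, sum(cors > 0), ncol(refStats)))]
}

.epanechnikov <- function(d) {
  dmax <- max(d)
  if (dmax == 0) return(rep(1, length(d)))
  u <- d / (dmax * (1 + 1e-12))
  1 - u^2
}

## Weighted linear solve with ridge fallback on singularity.
.wlsSolve <- function(Z, y, w) {
  fit <- stats::lm.wfit(Z, y, w)
  notes <- character()
  beta <- fit$coefficients
  if (any(is.na(beta))) {
    lambda <- 1e-8 * sum(diag(crossprod(Z * sqrt(w)))) / ncol(Z)
    A <- crossprod(Z * sqrt(w)) + diag(lambda, ncol(Z))
    beta <- drop(solve(A, crossprod(Z * sqrt(w), y * sqrt(w))))
    notes <- "singular weighted regression; ridge fallback used"
  }
  list(beta = beta, notes = notes)
}

#' ABC with local-linear regression adjustment
#'
#' Pre-selects up to `maxStats` statistics with the highest absolute
#' correlation with the target parameter over the reference table, runs
#' rejection in that statistic subspace, then fits an
#' Epanechnikov-weighted linear regression of the parameter on the
#' selected statistics over the accepted rows and adjusts each accepted
#' draw by `theta* = theta - b (s - s_target)`.
#'
#' @inheritParams abcRejection
#' @param maxStats statistic budget for the regression.
#' @return an [ABCResult-class] with one adjusted column per parameter.
#' @export
abcLoclinear <- function(targetStats, refStats, refParams, tolerance,
                         maxStats = 300L) {
  refParams <- as.data.frame(refParams)
  n <- nrow(refStats)
  k <- .acceptCount(tolerance, n)
  notes <- character()
  adj <- NULL; acceptedAll <- NULL; idxAll <- NULL; dAll <- NULL
  selNames <- character()
  for (pn in names(refParams)) {
    y <- refParams[[pn]]
    sel <- .selectStats(refStats, y, maxStats)
    sub <- refStats[, sel, drop = FALSE]
    scale <- .abcScale(sub)
    d <- .abcDistances(targetStats[sel], sub, scale)
    idx <- order(d)[seq_len(k)]
    w <- .epanechnikov(d[idx])
    S <- sweep(sub[idx, scale$keep, drop = FALSE], 2L,
               targetStats[sel][scale$keep], "-")
    Z <- cbind(1, S)
    sol <- .wlsSolve(Z, y[idx], w)
    notes <- union(notes, sol$notes)
    adjCol <- y[idx] - drop(S %*% sol$beta[-1L])
    if (is.null(adj)) {
      adj <- data.frame(row.names = seq_len(k))
      acceptedAll <- refParams[idx, , drop = FALSE]
      idxAll <- idx; dAll <- d[idx]
      selNames <- colnames(refStats)[sel] %||% as.character(sel)
    }
    adj[[pn]] <- adjCol
  }
  new("ABCResult", algorithm = "loclinear", accepted = acceptedAll,
      adjusted = adj, acceptedIdx = as.integer(idxAll), distances = dAll,
      tolerance = tolerance, selectedStats = selNames, notes = notes)
}

#' ABC with neural-network regression adjustment
#'
#' Like [abcLoclinear()], but the conditional mean of the parameter given
#' the statistics is fitted on the accepted rows with a single-hidden-layer
#' feed-forward network (default 3 hidden neurons) using the same kernel
#' weights; draws are adjusted by the fitted conditional-mean shift
#' `theta* = theta - m(s) + m(s_target)`.
#'
#' @inheritParams abcLoclinear
#' @param hidden hidden-layer size (>= 1).
#' @param seed seed for the network initialization.
#' @param decay weight decay of the network fit.
#' @return an [ABCResult-class].
#' @export
abcNeuralnet <- function(targetStats, refStats, refParams, tolerance,
                         maxStats = 300L, hidden = 3L, seed = 1L,
                         decay = 1e-2) {
  if (hidden < 1L) stop("hidden must be >= 1")
  refParams <- as.data.frame(refParams)
  n <- nrow(refStats)
  k <- .acceptCount(tolerance, n)
  notes <- character()
  adj <- NULL; acceptedAll <- NULL; idxAll <- NULL; dAll <- NULL
  selNames <- character()
  parSeeds <- deriveSeeds(seed, ncol(refParams))
  for (pi in seq_along(refParams)) {
    pn <- names(refParams)[pi]
    y <- refParams[[pn]]
    sel <- .selectStats(refStats, y, maxStats)
    sub <- refStats[, sel, drop = FALSE]
    scale <- .abcScale(sub)
    d <- .abcDistances(targetStats[sel], sub, scale)
    idx <- order(d)[seq_len(k)]
    w <- .epanechnikov(d[idx])
    Ssc <- sweep(sub[idx, scale$keep, drop = FALSE], 2L, scale$mad, "/")
    tsc <- targetStats[sel][scale$keep] / scale$mad
    yc <- mean(y[idx]); ysc <- stats::sd(y[idx])
    if (!is.finite(ysc) || ysc == 0) ysc <- 1
    fit <- tryCatch({
      caller <- .getRNGState()
      set.seed(parSeeds[pi])
      on.exit(.setRNGState(caller), add = TRUE)
      nnet::nnet(x = Ssc, y = (y[idx] - yc) / ysc, weights = w,
                 size = hidden, linout = TRUE, trace = FALSE,
                 maxit = 500L, decay = decay, MaxNWts = 100000L)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      notes <- union(notes, paste0("network fit failed for ", pn,
                                   "; raw accepted draws returned"))
      adjCol <- y[idx]
    } else {
      mAcc <- drop(stats::predict(fit, Ssc)) * ysc + yc
      mTar <- drop(stats::predict(fit, matrix(tsc, nrow = 1L))) * ysc + yc
      adjCol <- y[idx] - mAcc + mTar
    }
    if (is.null(adj)) {
      adj <- data.frame(row.names = seq_len(k))
      acceptedAll <- refParams[idx, , drop = FALSE]
      idxAll <- idx; dAll <- d[idx]
      selNames <- colnames(refStats)[sel] %||% as.character(sel)
    }
    adj[[pn]] <- adjCol
  }
  new("ABCResult", algorithm = "neuralnet", accepted = acceptedAll,
      adjusted = adj, acceptedIdx = as.integer(idxAll), distances = dAll,
      tolerance = tolerance, selectedStats = selNames, notes = notes)
}

#' Posterior point estimate from an ABC result
#'
#' @param result an [ABCResult-class].
#' @param mode `"mean"` or `"median"` of the posterior draws (adjusted
#'   draws when the algorithm produced them, raw otherwise).
#' @return named numeric, one value per parameter.
#' @export
pointEstimate <- function(result, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  draws <- if (!is.null(result@adjusted)) result@adjusted else result@accepted
  f <- if (mode == "mean") mean else stats::median
  vapply(draws, f, numeric(1L))
}
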