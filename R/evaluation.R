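## Accuracy metrics (RMSE, MAE with standard error, NMAE) and
## error-heterogeneity analysis across the parameter space.

#' Prediction-error metrics for one parameter
#'
#' Computes the root mean square error, the mean absolute error with its
#' standard error (`sd(|error|)/sqrt(n)`), and the normalized MAE (MAE
#' divided by the prior range, making parameters of different scales
#' comparable).
#'
#' @param yTrue,yPred numeric vectors of equal length (>= 2).
#' @param prior numeric(2) `(low, high)` prior bounds, or a one-row
#'   data.frame with `low`/`high`.
#' @return list with `RMSE`, `MAE`, `seMAE`, `NMAE`.
#' @export
computeMetrics <- function(yTrue, yPred, prior) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) >= 2L)
  pr <- .priorBounds(prior)
  err <- yPred - yTrue
  ae <- abs(err)
  list(RMSE = sqrt(mean(err^2)),
       MAE = mean(ae),
       seMAE = stats::sd(ae) / sqrt(length(ae)),
       NMAE = mean(ae) / (pr[2L] - pr[1L]))
}

.priorBounds <- function(prior) {
  if (is.data.frame(prior)) prior <- c(prior$low[1L], prior$high[1L])
  prior <- as.numeric(prior)
  stopifnot(length(prior) == 2L, prior[2L] > prior[1L])
  prior
}

#' Signed standardized prediction errors
#'
#' `(yPred - yTrue) / (high - low)` per test row.
#'
#' @inheritParams computeMetrics
#' @return numeric vector of signed standardized errors.
#' @export
standardizedErrors <- function(yTrue, yPred, prior) {
  stopifnot(length(yTrue) == length(yPred))
  pr <- .priorBounds(prior)
  (yPred - yTrue) / (pr[2L] - pr[1L])
}

#' Evaluation report over methods and parameters
#'
#' Convenience wrapper assembling a tidy metric table from a named list of
#' prediction vectors.
#'
#' @param predictions named list (method -> named list (parameter ->
#'   predictions)).
#' @param truth data.frame of true parameter values on the same rows.
#' @param priors prior data.frame (columns `name`, `low`, `high`).
#' @return data.frame with columns `parameter`, `method`, `RMSE`, `MAE`,
#'   `seMAE`, `NMAE`.
#' @export
evalReport <- function(predictions, truth, priors) {
  rows <- list()
  for (method in names(predictions)) {
    for (pn in names(predictions[[method]])) {
      pr <- priors[priors$name == pn, ]
      m <- computeMetrics(truth[[pn]], predictions[[method]][[pn]],
                          c(pr$low, pr$high))
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = pn, method = method, RMSE = m$RMSE,
                   MAE = m$MAE, seMAE = m$seMAE, NMAE = m$NMAE)
    }
  }
  do.call(rbind, rows)
}

#' Error surface over the two most explanatory parameters
#'
#' Fits a random-forest regression of the absolute standardized error on
#' all true parameter values, ranks the parameters by permutation
#' importance of that error model, and averages the absolute standardized
#' error over a `grid x grid` binning of the two top-ranked parameters
#' (empty cells are `NA`).
#'
#' @param stdErrors signed standardized errors (see
#'   [standardizedErrors()]).
#' @param trueParams data.frame of the true parameter values per test row.
#' @param nTop number of explanatory parameters to select.
#' @param grid number of bins per axis.
#' @param seed seed for the forest and the permutation importance.
#' @return list with `ranking` (data.frame of parameter importances),
#'   `top` (selected parameter names), `surface` (grid x grid matrix of
#'   mean absolute standardized errors), and the bin `breaks` per axis.
#' @export
errorSurface <- function(stdErrors, trueParams, nTop = 2L, grid = 20L,
                         seed = 1L) {
  stopifnot(length(stdErrors) >= 50L, nrow(trueParams) == length(stdErrors))
  absErr <- abs(stdErrors)
  X <- as.matrix(trueParams)
  fit <- ranger::ranger(x = X, y = absErr, num.trees = 300L, seed = seed,
                        num.threads = 1L, verbose = FALSE)
  predictFun <- function(Xn) {
    colnames(Xn) <- colnames(X)
    stats::predict(fit, data = Xn, num.threads = 1L)$predictions
  }
  imp <- permutationImportance(predictFun, X, absErr, nRepeats = 5L,
                               seed = seed, metric = "mse")
  ranking <- imp$perFeature[order(imp$perFeature$importance,
                                  decreasing = TRUE), ]
  top <- utils::head(ranking$feature, nTop)
  b1 <- seq(min(trueParams[[top[1L]]]), max(trueParams[[top[1L]]]),
            length.out = grid + 1L)
  b2 <- seq(min(trueParams[[top[2L]]]), max(trueParams[[top[2L]]]),
            length.out = grid + 1L)
  i1 <- pmin(pmax(findInterval(trueParams[[top[1L]]], b1,
                               rightmost.closed = TRUE), 1L), grid)
  i2 <- pmin(pmax(findInterval(trueParams[[top[2L]]], b2,
                               rightmost.closed = TRUE), 1L), grid)
  surface <- matrix(NA_real_, grid, grid)
  agg <- tapply(absErr, list(factor(i1, levels = seq_len(grid)),
                             factor(i2, levels = seq_len(grid))), mean)
  surface[] <- agg
  list(ranking = ranking, top = top, surface = surface,
       breaks = list(b1, b2))
}

#' Predicted-versus-observed scatter plot
#'
#' @param yTrue,yPred numeric vectors.
#' @param parameter,method labels for the title.
#' @return a ggplot object.
#' @export
plotPredictedVsObserved <- function(yTrue, yPred, parameter = "parameter",
                                    method = "method") {
  df <- data.frame(observed = yTrue, predicted = yPred)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(title = paste(method, "-", parameter),
                  x = "observed", y = "predicted") +
    ggplot2::theme_minimal()
}

#' Heat map of an error surface
#'
#' @param surf result of [errorSurface()].
#' @return a ggplot object.
#' @export
plotErrorSurface <- function(surf) {
  g <- nrow(surf$surface)
  mid <- function(b) (b[-1] + b[-length(b)]) / 2
  df <- expand.grid(x = mid(surf$breaks[[1L]]), y = mid(surf$breaks[[2L]]))
  df$err <- as.vector(surf$surface)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$err)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "plasma", na.value = "grey90") +
    ggplot2::labs(x = surf$top[1L], y = surf$top[2L],
                  fill = "|std. error|") +
    ggplot2::theme_minimal()
}
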