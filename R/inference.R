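## Per-parameter regression: feature standardization, the three supervised
## methods (random forest via ranger, gradient-boosted trees via xgboost,
## and the package's multilayer perceptron), and prediction with
## prior-bound clipping for the MLP.

#' Fit a feature standardizer on training rows
#'
#' Computes per-feature mean and standard deviation (population
#' convention, i.e. divide-by-n) on the training rows only.  Features with
#' zero standard deviation are centred but not scaled.
#'
#' @param X numeric training matrix with column names.
#' @return list with `mean`, `sd` (0 entries replaced by 1 for the
#'   transform) and `names`.
#' @export
fitStandardizer <- function(X) {
  stopifnot(nrow(X) >= 2L)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu, "-")^2))
  list(mean = mu, sd = ifelse(sdv > 0, sdv, 1), names = colnames(X))
}

#' Apply (or revert) a standardizer
#'
#' @param std standardizer from [fitStandardizer()].
#' @param X matrix aligned to the training schema.
#' @param revert if `TRUE`, undo the transform.
#' @return transformed matrix.
#' @export
applyStandardizer <- function(std, X, revert = FALSE) {
  if (!is.null(std$names) && !is.null(colnames(X)) &&
      !identical(colnames(X), std$names))
    stop("feature columns do not match the standardizer schema")
  if (revert)
    sweep(sweep(X, 2L, std$sd, "*"), 2L, std$mean, "+")
  else
    sweep(sweep(X, 2L, std$mean, "-"), 2L, std$sd, "/")
}

#' Resolved hyperparameter configuration for a regression method
#'
#' Defaults follow the package's tuned settings: random forest with 300
#' trees of maximum depth 20 (`mtry = NULL` keeps ranger's sqrt(p)
#' default); gradient boosting with 100 trees of depth 7; and a
#' six-hidden-layer ReLU perceptron (widths 512, 256, 128, 64, 32, 16)
#' trained with minibatch Adam on the MSE, early-stopped on the
#' validation set.
#'
#' @param method `"rf"`, `"xgb"` or `"mlp"`.
#' @param ... overrides of the method defaults (`nTrees`, `maxDepth`,
#'   `mtry`, `eta`, `hidden`, `lr`, `batchSize`, `maxEpochs`, `patience`,
#'   `l1`).
#' @return list of class settings.
#' @export
regressorConfig <- function(method = c("rf", "xgb", "mlp"), ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    rf = list(nTrees = 300L, maxDepth = 20L, mtry = NULL),
    xgb = list(nTrees = 100L, maxDepth = 7L, eta = 0.3),
    mlp = list(hidden = c(512L, 256L, 128L, 64L, 32L, 16L), lr = 1e-3,
               batchSize = 128L, maxEpochs = 500L, patience = 20L, l1 = 0))
  cfg <- utils::modifyList(defaults, list(...))
  cfg$method <- method
  cfg
}

#' Train a per-parameter regressor
#'
#' Standardizes the features on the training rows (population-sd
#' convention), fits the requested method for a single target parameter,
#' and returns a [TrainedRegressor-class].  The validation set is used
#' only for early stopping of the MLP and never enters the gradient or
#' tree fitting; tree methods are deterministic given the seed.
#'
#' @param config method configuration from [regressorConfig()] (or a
#'   method name).
#' @param X,y training features (matrix with column names) and target.
#' @param Xval,yval validation features and target (required for
#'   `"mlp"`).
#' @param target name of the demographic parameter.
#' @param bounds numeric(2) prior bounds of the parameter (used to clip
#'   MLP predictions).
#' @param seed integer seed.
#' @return a [TrainedRegressor-class].
#' @export
trainRegressor <- function(config, X, y, Xval = NULL, yval = NULL,
                           target = "parameter",
                           bounds = range(y), seed = 1L) {
  if (is.character(config)) config <- regressorConfig(config)
  method <- config$method
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in the training data")
  std <- fitStandardizer(X)
  Xs <- applyStandardizer(std, X)
  yCenter <- 0; yScale <- 1
  fit <- switch(method,
    rf = {
      ranger::ranger(
        x = Xs, y = y,
        num.trees = config$nTrees,
        max.depth = config$maxDepth,
        mtry = config$mtry,
        seed = seed, num.threads = 1L,
        verbose = FALSE)
    },
    xgb = {
      xgboost::xgboost(
        x = Xs, y = y,
        objective = "reg:squarederror",
        nrounds = config$nTrees,
        max_depth = config$maxDepth,
        learning_rate = config$eta,
        nthreads = 1L, seed = seed, verbosity = 0L)
    },
    mlp = {
      if (is.null(Xval) || is.null(yval))
        stop("the MLP requires a validation set for early stopping")
      if (any(!is.finite(Xval)) || any(!is.finite(yval)))
        stop("non-finite values in the validation data")
      yCenter <- mean(y)
      yScale <- stats::sd(y)
      if (!is.finite(yScale) || yScale == 0) yScale <- 1
      mlpFit(Xs, (y - yCenter) / yScale,
             applyStandardizer(std, Xval), (yval - yCenter) / yScale,
             hidden = config$hidden, lr = config$lr,
             batchSize = config$batchSize, maxEpochs = config$maxEpochs,
             patience = config$patience, l1 = config$l1, seed = seed)
    },
    stop("unknown method: ", method))
  new("TrainedRegressor", method = method, fit = fit, standardizer = std,
      yCenter = yCenter, yScale = yScale, target = target,
      bounds = as.numeric(bounds), featureNames = colnames(X),
      config = config, seed = as.integer(seed))
}

#' Predict demographic parameters from features
#'
#' Applies the stored standardizer and the fitted model.  MLP outputs
#' falling outside the prior interval are set to the closest bound; tree
#' methods cannot extrapolate beyond their training targets and are
#' returned as-is.
#'
#' @param object a [TrainedRegressor-class].
#' @param X feature matrix aligned to the training schema (checked by
#'   name).
#' @return numeric predictions on the parameter scale.
#' @export
setGeneric("predictParams", function(object, X) standardGeneric("predictParams"))

#' @rdname predictParams
#' @export
setMethod("predictParams", "TrainedRegressor", function(object, X) {
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), object@featureNames)) {
    missing <- setdiff(object@featureNames, colnames(X))
    extra <- setdiff(colnames(X), object@featureNames)
    if (length(missing) || length(extra))
      stop("feature schema mismatch; missing: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ..." else "",
           "; extra: ", paste(utils::head(extra, 5L), collapse = ", "),
           if (length(extra) > 5L) ", ..." else "")
    X <- X[, object@featureNames, drop = FALSE]  # same set, wrong order
  }
  Xs <- applyStandardizer(object@standardizer, X)
  pred <- switch(object@method,
    rf = stats::predict(object@fit, data = Xs,
                        num.threads = 1L)$predictions,
    xgb = stats::predict(object@fit, newdata = Xs),
    mlp = {
      raw <- mlpPredict(object@fit, Xs) * object@yScale + object@yCenter
      pmin(pmax(raw, object@bounds[1L]), object@bounds[2L])
    })
  unname(pred)
})

#' Normalized-mean-absolute-error of the midpoint predictor
#'
#' The analytic baseline used throughout the package: predicting the
#' prior midpoint for a uniform target gives an expected NMAE of 1/4.
#'
#' @return 0.25
#' @export
midpointBaselineNMAE <- function() 0.25
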