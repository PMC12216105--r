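## Feature-contribution analysis: permutation feature importance (per
## feature and per statistic class) and Shapley values (exact tree-path
## algorithm for gradient-boosted trees, seeded permutation-sampling
## estimator otherwise).

.asPredictFun <- function(model) {
  if (is.function(model)) return(model)
  if (is(model, "TrainedRegressor"))
    return(function(X) predictParams(model, X))
  stop("model must be a TrainedRegressor or a predict function")
}

#' Permutation feature importance
#'
#' For each feature, measures the degradation of held-out performance when
#' that feature column is randomly shuffled (breaking its relationship
#' with the target), averaged over `nRepeats` independent shuffles.  The
#' default metric is R-squared degradation (bounded scale, comparable
#' across parameters); `"mse"` gives the raw MSE increase.
#'
#' @param model a [TrainedRegressor-class] or a function `X -> predictions`.
#' @param X,y held-out features and target.
#' @param nRepeats shuffles per feature.
#' @param seed seed for the shuffles.
#' @param metric `"r2"` or `"mse"`.
#' @return list with `perFeature` (data.frame: `feature`, `importance`,
#'   `sd`), `baseScore`, `metric`, `seed`.
#' @export
permutationImportance <- function(model, X, y, nRepeats = 5L, seed = 1L,
                                  metric = c("r2", "mse")) {
  metric <- match.arg(metric)
  f <- .asPredictFun(model)
  score <- function(pred) {
    mse <- mean((pred - y)^2)
    if (metric == "mse") -mse else 1 - mse / mean((y - mean(y))^2)
  }
  base <- score(f(X))
  rng <- localRNG(seed)
  p <- ncol(X)
  imp <- matrix(NA_real_, nrow = nRepeats, ncol = p)
  n <- nrow(X)
  for (r in seq_len(nRepeats)) {
    for (j in seq_len(p)) {
      Xp <- X
      Xp[, j] <- X[rng$sample(n, n), j]
      imp[r, j] <- base - score(f(Xp))
    }
  }
  perFeature <- data.frame(
    feature = colnames(X) %||% paste0("x", seq_len(p)),
    importance = colMeans(imp),
    sd = apply(imp, 2L, stats::sd))
  list(perFeature = perFeature, baseScore = base, metric = metric,
       seed = seed)
}

#' Class-level importance fractions
#'
#' Aggregates per-feature permutation importances into the 11 summary-
#' statistic classes: negative per-feature values are floored at 0, member
#' importances summed per class, and the sums normalized to fractions
#' summing to 1.
#'
#' @param report result of [permutationImportance()] computed on schema
#'   features.
#' @param schema the [FeatureSchema-class] mapping features to classes.
#' @return named numeric vector of class fractions.
#' @export
classImportance <- function(report, schema) {
  pf <- report$perFeature
  cls <- featClasses(schema)[pf$feature]
  if (any(is.na(cls)))
    stop("feature(s) without a schema class: ",
         paste(utils::head(pf$feature[is.na(cls)], 5L), collapse = ", "))
  v <- pmax(pf$importance, 0)
  sums <- tapply(v, cls, sum)
  sums <- sums[sort(unique(cls))]
  tot <- sum(sums)
  if (tot == 0) return(stats::setNames(rep(0, length(sums)), names(sums)))
  sums / tot
}

#' Shapley values of model predictions
#'
#' Explains per-instance predictions by the average marginal contribution
#' of each feature.  Gradient-boosted models are explained with the exact
#' tree-path algorithm (satisfying local accuracy to machine precision);
#' other models use a seeded permutation-sampling estimator with draws
#' from a background set, whose contributions satisfy local accuracy with
#' respect to the estimated base value by construction.
#'
#' @param model a [TrainedRegressor-class] or a predict function (the
#'   sampling estimator is used for functions).
#' @param XBackground background feature matrix (reference distribution).
#' @param XExplain instances to explain.
#' @param seed seed for the sampling estimator.
#' @param nPerm permutations per instance (sampling estimator).
#' @return list with `phi` (instances x features), `base` (numeric base
#'   value per instance), `meanAbs` (named mean absolute Shapley value per
#'   feature, sorted), `values` (= `XExplain`, for dependence plots) and
#'   `method`.
#' @export
shapleyValues <- function(model, XBackground, XExplain, seed = 1L,
                          nPerm = 30L) {
  if (is(model, "TrainedRegressor") && model@method == "xgb") {
    Xs <- applyStandardizer(model@standardizer, XExplain)
    ctr <- stats::predict(model@fit, newdata = Xs, type = "contrib")
    p <- ncol(XExplain)
    phi <- ctr[, seq_len(p), drop = FALSE]
    colnames(phi) <- colnames(XExplain)
    base <- ctr[, p + 1L]
    method <- "treepath"
  } else {
    f <- .asPredictFun(model)
    res <- .samplingShapley(f, XBackground, XExplain, seed, nPerm)
    phi <- res$phi; base <- res$base
    method <- "sampling"
  }
  meanAbs <- sort(colMeans(abs(phi)), decreasing = TRUE)
  list(phi = phi, base = base, meanAbs = meanAbs, values = XExplain,
       method = method)
}

## Permutation-sampling Shapley estimator (Strumbelj-Kononenko): for each
## explained instance and each sampled permutation, walk through the
## features in permutation order, switching background values to instance
## values; the prediction increments are the marginal contributions.
.samplingShapley <- function(f, XBackground, XExplain, seed, nPerm) {
  p <- ncol(XExplain)
  nE <- nrow(XExplain)
  rng <- localRNG(seed)
  phi <- matrix(0, nE, p, dimnames = list(NULL, colnames(XExplain)))
  base <- numeric(nE)
  for (e in seq_len(nE)) {
    x <- XExplain[e, ]
    contrib <- numeric(p)
    b <- 0
    for (r in seq_len(nPerm)) {
      ord <- rng$sample(p, p)
      z <- XBackground[rng$sample(nrow(XBackground), 1L), ]
      ## build the p+1 hybrid rows of one permutation walk
      M <- matrix(rep(z, p + 1L), nrow = p + 1L, byrow = TRUE)
      for (step in seq_len(p))
        M[(step + 1L):(p + 1L), ord[step]] <- x[ord[step]]
      colnames(M) <- colnames(XExplain)
      pred <- f(M)
      contrib[ord] <- contrib[ord] + diff(pred)
      b <- b + pred[1L]
    }
    phi[e, ] <- contrib / nPerm
    base[e] <- b / nPerm
  }
  list(phi = phi, base = base)
}

#' Beeswarm-style data of top Shapley features
#'
#' @param shap result of [shapleyValues()].
#' @param nTop number of top features (by mean |Shapley value|).
#' @return long data.frame with `feature`, `phi`, `value` (the feature
#'   value, min-max normalized within feature).
#' @export
shapBeeswarmData <- function(shap, nTop = 10L) {
  top <- names(utils::head(shap$meanAbs, nTop))
  out <- lapply(top, function(fn) {
    v <- shap$values[, fn]
    rng <- range(v)
    nv <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else rep(0.5, length(v))
    data.frame(feature = fn, phi = shap$phi[, fn], value = nv)
  })
  do.call(rbind, out)
}

#' Beeswarm plot of Shapley values
#'
#' @param shap result of [shapleyValues()].
#' @param nTop number of features shown.
#' @return a ggplot object.
#' @export
plotShapBeeswarm <- function(shap, nTop = 10L) {
  df <- shapBeeswarmData(shap, nTop)
  df$feature <- factor(df$feature, levels = rev(unique(df$feature)))
  ggplot2::ggplot(df, ggplot2::aes(.data$phi, .data$feature,
                                   colour = .data$value)) +
    ggplot2::geom_jitter(height = 0.2, size = 0.5, alpha = 0.7) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red") +
    ggplot2::labs(x = "Shapley value", y = NULL,
                  colour = "feature value\n(normalized)") +
    ggplot2::theme_minimal()
}
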