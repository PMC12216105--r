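## Demographic models: isolation-with-migration (IM) and secondary contact
## with varying population sizes (SC), their priors, parameter sampling, and
## translation into the epoch/migration representation the coalescent
## backend consumes.

.IM_PARAMS <- c("split_time", "migration_rate", "n_ancestral",
                "n_current_1", "n_current_2")
.SC_PARAMS <- c(.IM_PARAMS, "growth_rate_1", "growth_rate_2",
                "migration_duration")

#' Parameter names of a demographic model
#'
#' @param model `"IM"` or `"SC"`.
#' @return character vector of parameter labels.
#' @export
modelParams <- function(model) {
  switch(match.arg(model, c("IM", "SC")), IM = .IM_PARAMS, SC = .SC_PARAMS)
}

#' Default uniform priors of the demographic models
#'
#' Returns the uniform prior bounds used for simulation under the
#' isolation-with-migration (IM) or secondary-contact (SC) model.  Under IM,
#' the split time is drawn on U\[1, 5000\] generations, the three diploid
#' effective sizes on U\[100, 10000\], and the symmetric per-generation
#' migration rate on U\[0, 0.001\].  Under SC, the split time is U\[100,
#' 5000\], the sizes U\[1000, 5000\], the migration rate U\[0, 0.005\], the
#' two per-generation exponential growth rates U\[-0.001, 0.002\], and the
#' migration duration (fraction of the post-split period with gene flow,
#' anchored at the present) U\[0, 1\].
#'
#' @param model `"IM"` or `"SC"`.
#' @return data.frame with columns `name`, `low`, `high`, one row per
#'   parameter, in canonical order.
#' @examples
#' defaultPriors("IM")
#' @export
defaultPriors <- function(model) {
  model <- match.arg(model, c("IM", "SC"))
  if (model == "IM") {
    data.frame(
      name = .IM_PARAMS,
      low  = c(1,    0,     100,   100,   100),
      high = c(5000, 0.001, 10000, 10000, 10000)
    )
  } else {
    data.frame(
      name = .SC_PARAMS,
      low  = c(100,  0,     1000, 1000, 1000, -0.001, -0.001, 0),
      high = c(5000, 0.005, 5000, 5000, 5000,  0.002,  0.002, 1)
    )
  }
}

.checkPriors <- function(priors) {
  stopifnot(is.data.frame(priors), all(c("name", "low", "high") %in% names(priors)))
  if (any(!is.finite(priors$low)) || any(!is.finite(priors$high)))
    stop("prior bounds must be finite")
  if (any(priors$low > priors$high))
    stop("prior bounds must satisfy low <= high")
  invisible(priors)
}

#' Sample demographic parameters from uniform priors
#'
#' Draws `n` independent parameter sets, each field uniform on its prior
#' bounds, deterministically for a given seed.  For the SC model, draws
#' whose backward-time exponential size change takes a population below one
#' diploid before the split (i.e. `n_current_i * exp(-growth_rate_i *
#' split_time) < 1`) would be invalid coalescent inputs; such draws are
#' rejected and redrawn, and the number of rejections is recorded in the
#' `"nRejected"` attribute.
#'
#' @param priors data.frame of prior bounds as returned by
#'   [defaultPriors()].
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @param model `"IM"` or `"SC"`; determines the validity constraint.
#' @return data.frame with `n` rows, one column per parameter, attribute
#'   `nRejected`.
#' @export
sampleParameters <- function(priors, n, seed, model = c("IM", "SC")) {
  model <- match.arg(model)
  .checkPriors(priors)
  stopifnot(n >= 1)
  rng <- localRNG(seed)
  draw <- function(k) {
    out <- lapply(seq_len(nrow(priors)), function(i)
      rng$runif(k, priors$low[i], priors$high[i]))
    names(out) <- priors$name
    as.data.frame(out)
  }
  res <- draw(n)
  nRejected <- 0L
  if (model == "SC") {
    for (round in seq_len(1000L)) {
      bad <- .invalidSCDraws(res)
      if (!any(bad)) break
      nRejected <- nRejected + sum(bad)
      res[bad, ] <- draw(sum(bad))
    }
    if (any(.invalidSCDraws(res)))
      stop("could not sample valid SC draws: the priors force a population ",
           "below 1 diploid before the split (n_current_i * ",
           "exp(-growth_rate_i * split_time) < 1)")
  }
  attr(res, "nRejected") <- nRejected
  attr(res, "model") <- model
  res
}

.invalidSCDraws <- function(params) {
  if (!all(c("growth_rate_1", "growth_rate_2") %in% names(params)))
    return(rep(FALSE, nrow(params)))
  s1 <- params$n_current_1 * exp(-params$growth_rate_1 * params$split_time)
  s2 <- params$n_current_2 * exp(-params$growth_rate_2 * params$split_time)
  s1 < 1 | s2 < 1
}

#' Translate a parameter draw into demography events
#'
#' Builds the [DemographyEvents-class] representation consumed by the
#' coalescent backend.  Under IM the two descendant populations keep
#' constant sizes and exchange symmetric migrants at `migration_rate` over
#' the whole post-split period `[0, split_time]`.  Under SC, population `i`
#' has backward-time size `n_current_i * exp(-growth_rate_i * t)` and
#' migration is restricted to the most recent window
#' `[0, migration_duration * split_time]` (no gene flow between the end of
#' that window and the split).  A migration duration of 1 therefore
#' reproduces continuous-migration IM behaviour.
#'
#' @param params a single parameter draw: one-row data.frame or named
#'   vector/list with the fields of [modelParams()].
#' @param model `"IM"` or `"SC"`.
#' @return a [DemographyEvents-class] object.
#' @examples
#' p <- c(split_time = 1000, migration_rate = 1e-4, n_ancestral = 5000,
#'        n_current_1 = 2000, n_current_2 = 3000)
#' toDemographyEvents(p, "IM")
#' @export
toDemographyEvents <- function(params, model = c("IM", "SC")) {
  model <- match.arg(model)
  p <- as.list(params)
  need <- modelParams(model)
  if (!all(need %in% names(p)))
    stop("missing parameter(s): ", paste(setdiff(need, names(p)), collapse = ", "))
  p <- lapply(p, as.numeric)
  if (model == "IM") {
    growth <- c(0, 0)
    migEnd <- p$split_time
  } else {
    growth <- c(p$growth_rate_1, p$growth_rate_2)
    if (p$migration_duration < 0 || p$migration_duration > 1)
      stop("migration_duration must lie in [0, 1]")
    migEnd <- p$migration_duration * p$split_time
  }
  windows <- if (migEnd > 0)
    data.frame(start = 0, end = migEnd, rate = p$migration_rate)
  else
    data.frame(start = numeric(), end = numeric(), rate = numeric())
  new("DemographyEvents",
      splitTime = p$split_time,
      ancestralSize = p$n_ancestral,
      popSizes = c(p$n_current_1, p$n_current_2),
      growthRates = growth,
      migrationWindows = windows)
}

#' Backward-time population size under a demography
#'
#' Evaluates `N_i(t) = N_present_i * exp(-g_i * t)` for `t` generations
#' before present (valid for `t` in `[0, splitTime]`; at and beyond the
#' split the ancestral size applies).
#'
#' @param events a [DemographyEvents-class].
#' @param pop population index (1 or 2).
#' @param t time in generations before present.
#' @return numeric vector of diploid sizes.
#' @export
populationSizeAt <- function(events, pop, t) {
  stopifnot(pop %in% c(1L, 2L))
  ## the split time itself still belongs to the descendant epoch
  ifelse(t > events@splitTime, events@ancestralSize,
         events@popSizes[pop] * exp(-events@growthRates[pop] * t))
}
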