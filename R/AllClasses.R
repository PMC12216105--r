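#' @import methods
#' @importFrom stats cor mad median predict quantile rnorm runif sd var
NULL

#' Sampling design of a simulated polymorphism data set
#'
#' A `SampleDesign` describes how genomic data are sampled under a
#' demographic model: the number of diploid individuals per population, the
#' number of independent neutral loci, the locus length in base pairs, and
#' the per-base per-generation recombination and mutation rates.  The
#' defaults correspond to a human-like design: 10 diploids per population,
#' 20 loci of 2 Mb, recombination 1e-8 and mutation 1.25e-8.
#'
#' @slot nDiploidPerPop integer(1), diploid sample size per population.
#' @slot nLoci integer(1), number of independent loci.
#' @slot locusLength numeric(1), locus length in bp.
#' @slot recombinationRate numeric(1), per bp per generation.
#' @slot mutationRate numeric(1), per bp per generation.
#' @export
setClass("SampleDesign",
  representation(
    nDiploidPerPop = "integer",
    nLoci = "integer",
    locusLength = "numeric",
    recombinationRate = "numeric",
    mutationRate = "numeric"
  )
)

setValidity("SampleDesign", function(object) {
  msg <- character()
  if (length(object@nDiploidPerPop) != 1L || object@nDiploidPerPop < 1L)
    msg <- c(msg, "nDiploidPerPop must be a single integer >= 1")
  if (length(object@nLoci) != 1L || object@nLoci < 1L)
    msg <- c(msg, "nLoci must be a single integer >= 1")
  for (s in c("locusLength", "recombinationRate", "mutationRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("%s must be a single finite non-negative number", s))
  }
  if (length(object@locusLength) == 1L && object@locusLength <= 0)
    msg <- c(msg, "locusLength must be positive")
  if (length(msg)) msg else TRUE
})

#' Epoch/migration representation of a two-population demography
#'
#' `DemographyEvents` is the canonical intermediate representation handed to
#' the coalescent backend.  Time is measured in generations before the
#' present.  Each descendant population `i` has backward-time size
#' `N_i(t) = popSizes[i] * exp(-growthRates[i] * t)` for `t` in
#' `[0, splitTime]`; at `splitTime` both merge into a single ancestral
#' population of constant size `ancestralSize`.  Migration is symmetric and
#' active on the windows in `migrationWindows` (columns `start`, `end`,
#' `rate`; rate is the per-generation proportion of migrants in each
#' direction).
#'
#' @slot splitTime numeric(1), generations before present.
#' @slot ancestralSize numeric(1), diploid ancestral effective size.
#' @slot popSizes numeric(2), present-day diploid effective sizes.
#' @slot growthRates numeric(2), per-generation exponential rates (positive
#'   means forward-time growth).
#' @slot migrationWindows data.frame with columns `start`, `end`, `rate`.
#' @export
setClass("DemographyEvents",
  representation(
    splitTime = "numeric",
    ancestralSize = "numeric",
    popSizes = "numeric",
    growthRates = "numeric",
    migrationWindows = "data.frame"
  )
)

setValidity("DemographyEvents", function(object) {
  msg <- character()
  if (length(object@splitTime) != 1L || object@splitTime < 0)
    msg <- c(msg, "splitTime must be a single non-negative number")
  if (length(object@ancestralSize) != 1L || object@ancestralSize < 1)
    msg <- c(msg, "ancestralSize must be >= 1 diploid")
  if (length(object@popSizes) != 2L || any(object@popSizes <= 0))
    msg <- c(msg, "popSizes must be two strictly positive numbers")
  if (length(object@growthRates) != 2L || any(!is.finite(object@growthRates)))
    msg <- c(msg, "growthRates must be two finite numbers")
  mw <- object@migrationWindows
  if (!all(c("start", "end", "rate") %in% names(mw)))
    msg <- c(msg, "migrationWindows needs columns start, end, rate")
  else if (nrow(mw) && (any(mw$start < 0) || any(mw$end < mw$start) ||
                        any(mw$rate < 0)))
    msg <- c(msg, "migration windows must satisfy 0 <= start <= end, rate >= 0")
  # sizes must stay >= 1 diploid over the whole post-split period
  if (length(object@popSizes) == 2L && length(object@growthRates) == 2L &&
      length(object@splitTime) == 1L) {
    atSplit <- object@popSizes * exp(-object@growthRates * object@splitTime)
    bad <- which(pmin(object@popSizes, atSplit) < 1)
    if (length(bad))
      msg <- c(msg, sprintf(
        "population %d size drops below 1 diploid before the split (present size %.3g, growth rate %.3g, split time %.6g)",
        bad[1L], object@popSizes[bad[1L]], object@growthRates[bad[1L]],
        object@splitTime))
  }
  if (length(msg)) msg else TRUE
})

#' Phased haplotype data for one locus
#'
#' A `LocusData` holds the phased 0/1 haplotype matrix of one simulated (or
#' observed) locus: rows are haplotypes grouped by population, columns are
#' biallelic segregating sites (0 = ancestral, 1 = derived), with strictly
#' increasing positions on `[0, locusLength)`.
#'
#' @slot haplotypes integer matrix of 0/1 entries, haplotypes x sites.
#' @slot positions numeric, strictly increasing site coordinates.
#' @slot popLabels integer, population index (1 or 2) per haplotype row.
#' @slot locusLength numeric(1), locus length in bp.
#' @export
setClass("LocusData",
  representation(
    haplotypes = "matrix",
    positions = "numeric",
    popLabels = "integer",
    locusLength = "numeric"
  )
)

setValidity("LocusData", function(object) {
  msg <- character()
  H <- object@haplotypes
  if (!is.numeric(H) && !is.integer(H))
    msg <- c(msg, "haplotypes must be a numeric 0/1 matrix")
  else if (length(H) && !all(H %in% c(0L, 1L)))
    msg <- c(msg, "haplotype entries must be 0 or 1")
  if (ncol(H) != length(object@positions))
    msg <- c(msg, "positions length must equal the number of sites")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@positions) &&
      (any(object@positions < 0) || any(object@positions >= object@locusLength)))
    msg <- c(msg, "positions must lie in [0, locusLength)")
  if (nrow(H) != length(object@popLabels))
    msg <- c(msg, "popLabels length must equal the number of haplotypes")
  if (length(object@popLabels) && !all(object@popLabels %in% c(1L, 2L)))
    msg <- c(msg, "popLabels must be 1 or 2")
  if (length(object@popLabels) && is.unsorted(object@popLabels))
    msg <- c(msg, "haplotype rows must be grouped by population (pop 1 first)")
  if (ncol(H) && nrow(H)) {
    cs <- colSums(H)
    if (any(cs == 0L) || any(cs == nrow(H)))
      msg <- c(msg, "every site must be segregating in the pooled sample")
  }
  if (length(msg)) msg else TRUE
})

#' Ordered manifest of the aggregated summary-statistic features
#'
#' A `FeatureSchema` enumerates, in a fixed and reproducible order, every
#' aggregated summary-statistic feature produced for a given
#' [SampleDesign-class]: each per-locus base statistic (identified by its
#' class, sub-statistic index and sample scope) crossed with the three
#' cross-locus aggregators (mean, median, variance).  The schema alone
#' determines the layout of every feature table the package reads or
#' writes.
#'
#' @slot baseNames character, per-locus base statistic names.
#' @slot baseClasses character, statistic class of each base entry (one of
#'   S, D, PI, WinH, SFS, LD, IBS, AFIBS, Fst, Dxy, JSFS).
#' @slot baseScopes character, sample scope of each base entry
#'   (`p1`, `p2`, `all`, `cross`).
#' @slot featureNames character, full aggregated feature names
#'   (`<base>_<mean|med|var>`).
#' @slot design the [SampleDesign-class] the schema was built for.
#' @slot config list of statistic configuration used (LD bins, IBS subset
#'   sizes, window size, caps, ...).
#' @export
setClass("FeatureSchema",
  representation(
    baseNames = "character",
    baseClasses = "character",
    baseScopes = "character",
    featureNames = "character",
    design = "SampleDesign",
    config = "list"
  )
)

setValidity("FeatureSchema", function(object) {
  msg <- character()
  if (anyDuplicated(object@featureNames))
    msg <- c(msg, "feature names must be unique")
  if (length(object@baseNames) * 3L != length(object@featureNames))
    msg <- c(msg, "featureNames must be baseNames x {mean, med, var}")
  if (length(object@baseClasses) != length(object@baseNames) ||
      length(object@baseScopes) != length(object@baseNames))
    msg <- c(msg, "baseClasses/baseScopes must align with baseNames")
  if (length(msg)) msg else TRUE
})

#' Reference table of simulated parameter draws and their features
#'
#' A `ReferenceTable` couples the matrix of sampled demographic parameters
#' (one row per simulation) with the matrix of aggregated summary-statistic
#' features computed on the corresponding simulated data sets, plus the
#' train/validation/test split assignment used downstream.
#'
#' @slot params data.frame of parameter draws, one column per parameter.
#' @slot features numeric matrix, simulations x features, columns named
#'   after the schema.
#' @slot split factor with levels `train`, `validation`, `test`.
#' @slot schema the [FeatureSchema-class] describing the feature columns.
#' @slot model character(1), `"IM"` or `"SC"`.
#' @slot priors data.frame of prior bounds (columns `name`, `low`, `high`).
#' @slot seed integer(1), master seed of the run.
#' @export
setClass("ReferenceTable",
  representation(
    params = "data.frame",
    features = "matrix",
    split = "factor",
    schema = "FeatureSchema",
    model = "character",
    priors = "data.frame",
    seed = "integer"
  )
)

setValidity("ReferenceTable", function(object) {
  msg <- character()
  n <- nrow(object@params)
  if (nrow(object@features) != n)
    msg <- c(msg, "params and features must have the same number of rows")
  if (length(object@split) != n)
    msg <- c(msg, "split must have one entry per simulation")
  if (!all(levels(object@split) %in% c("train", "validation", "test")))
    msg <- c(msg, "split levels must be train/validation/test")
  if (ncol(object@features) != length(object@schema@featureNames))
    msg <- c(msg, "feature columns must match the schema")
  if (length(msg)) msg else TRUE
})

#' A fitted per-parameter regressor
#'
#' A `TrainedRegressor` bundles a fitted model (random forest, gradient
#' boosted trees, or multilayer perceptron) for one demographic parameter
#' together with everything needed to predict reproducibly: the feature
#' standardizer fitted on the training rows, the target standardizer (MLP),
#' the prior bounds used to clip out-of-range MLP predictions, and the
#' training metadata.
#'
#' @slot method character(1), `"rf"`, `"xgb"` or `"mlp"`.
#' @slot fit the fitted model object.
#' @slot standardizer list with per-feature `mean` and `sd` (population
#'   convention) fitted on the training rows only.
#' @slot yCenter,yScale numeric(1), target standardization (MLP; 0/1 for
#'   tree methods).
#' @slot target character(1), name of the demographic parameter.
#' @slot bounds numeric(2), prior lower/upper bound for clipping.
#' @slot featureNames character, training feature schema.
#' @slot config list, resolved hyperparameter configuration.
#' @slot seed integer(1).
#' @export
setClass("TrainedRegressor",
  representation(
    method = "character",
    fit = "ANY",
    standardizer = "list",
    yCenter = "numeric",
    yScale = "numeric",
    target = "character",
    bounds = "numeric",
    featureNames = "character",
    config = "list",
    seed = "integer"
  )
)

setValidity("TrainedRegressor", function(object) {
  msg <- character()
  if (!object@method %in% c("rf", "xgb", "mlp"))
    msg <- c(msg, "method must be rf, xgb or mlp")
  if (length(object@bounds) != 2L || object@bounds[1L] > object@bounds[2L])
    msg <- c(msg, "bounds must be (low, high) with low <= high")
  if (length(msg)) msg else TRUE
})

#' Result of an approximate Bayesian computation run
#'
#' An `ABCResult` stores, for one target and one algorithm, the accepted
#' parameter draws (raw, and regression-adjusted where the algorithm
#' applies a correction), the scaled Euclidean distances of the accepted
#' simulations, the tolerance (proportion of the reference table accepted)
#' and bookkeeping about the statistics used.
#'
#' @slot algorithm character(1): `"rejection"`, `"loclinear"` or
#'   `"neuralnet"`.
#' @slot accepted data.frame of raw accepted parameter draws.
#' @slot adjusted `NULL` or data.frame of regression-adjusted draws.
#' @slot acceptedIdx integer, row indices into the reference table.
#' @slot distances numeric, scaled distances of the accepted rows.
#' @slot tolerance numeric(1), proportion accepted.
#' @slot selectedStats character, statistics used for distance/regression.
#' @slot notes character, warnings raised during fitting (e.g. ridge
#'   fallback, non-convergence).
#' @export
setClass("ABCResult",
  representation(
    algorithm = "character",
    accepted = "data.frame",
    adjusted = "ANY",
    acceptedIdx = "integer",
    distances = "numeric",
    tolerance = "numeric",
    selectedStats = "character",
    notes = "character"
  )
)

setValidity("ABCResult", function(object) {
  msg <- character()
  if (nrow(object@accepted) < 1L)
    msg <- c(msg, "at least one accepted draw is required")
  if (!is.null(object@adjusted)) {
    if (!identical(dim(object@adjusted), dim(object@accepted)))
      msg <- c(msg, "adjusted draws must align with accepted draws")
    else if (any(!is.finite(as.matrix(object@adjusted))))
      msg <- c(msg, "adjusted draws must be finite")
  }
  if (length(object@tolerance) != 1L || object@tolerance <= 0 ||
      object@tolerance > 1)
    msg <- c(msg, "tolerance must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "SampleDesign", function(object) {
  cat("SampleDesign:", object@nDiploidPerPop, "diploids/pop,",
      object@nLoci, "loci x", format(object@locusLength, big.mark = ","),
      "bp\n  recombination", object@recombinationRate,
      "/bp/gen, mutation", object@mutationRate, "/bp/gen\n")
})

setMethod("show", "DemographyEvents", function(object) {
  cat("DemographyEvents: split", format(object@splitTime, digits = 6),
      "generations ago; ancestral size", format(object@ancestralSize, digits = 6), "\n")
  cat("  present sizes:", paste(format(object@popSizes, digits = 6), collapse = ", "),
      "; growth rates:", paste(format(object@growthRates, digits = 4), collapse = ", "), "\n")
  if (nrow(object@migrationWindows))
    cat("  migration windows:",
        paste(sprintf("[%.4g, %.4g] @ %.3g", object@migrationWindows$start,
                      object@migrationWindows$end, object@migrationWindows$rate),
              collapse = "; "), "\n")
  else cat("  no migration\n")
})

setMethod("show", "LocusData", function(object) {
  cat("LocusData:", nrow(object@haplotypes), "haplotypes x",
      ncol(object@haplotypes), "segregating sites on",
      format(object@locusLength, big.mark = ","), "bp\n  populations:",
      sum(object@popLabels == 1L), "+", sum(object@popLabels == 2L),
      "haplotypes\n")
})

setMethod("show", "FeatureSchema", function(object) {
  cat("FeatureSchema:", length(object@featureNames), "features (",
      length(object@baseNames), "base statistics x 3 aggregators)\n")
  tab <- table(object@baseClasses)
  cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "ReferenceTable", function(object) {
  cat("ReferenceTable:", nrow(object@params), "simulations under the",
      object@model, "model\n  split:",
      paste(sprintf("%s=%d", levels(object@split), table(object@split)),
            collapse = ", "), "\n  features:", ncol(object@features), "\n")
})

setMethod("show", "TrainedRegressor", function(object) {
  cat("TrainedRegressor[", object@method, "] for", object@target,
      "- prior [", format(object@bounds[1L]), ",", format(object@bounds[2L]),
      "],", length(object@featureNames), "features\n")
})

setMethod("show", "ABCResult", function(object) {
  cat("ABCResult[", object@algorithm, "]: ", nrow(object@accepted),
      " accepted draws (tolerance ", format(object@tolerance), ")",
      if (!is.null(object@adjusted)) ", regression-adjusted" else "",
      "\n", sep = "")
})

## ---- accessors -------------------------------------------------------------

#' Accessors for package classes
#'
#' `featNames()` returns the full aggregated feature names of a schema or
#' reference table; `baseNames()` the per-locus base statistic names;
#' `featClasses()` maps every aggregated feature to its statistic class;
#' `nFeatures()` counts features; `refParams()`, `refFeatures()` and
#' `refSplit()` extract the components of a [ReferenceTable-class];
#' `haplotypes()`, `positions()` and `popLabels()` the components of a
#' [LocusData-class].
#'
#' @param x a package object.
#' @return the extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featNames", function(x) standardGeneric("featNames"))
#' @rdname accessors
#' @export
setMethod("featNames", "FeatureSchema", function(x) x@featureNames)
#' @rdname accessors
#' @export
setMethod("featNames", "ReferenceTable", function(x) x@schema@featureNames)

#' @rdname accessors
#' @export
setGeneric("baseNames", function(x) standardGeneric("baseNames"))
#' @rdname accessors
#' @export
setMethod("baseNames", "FeatureSchema", function(x) x@baseNames)

#' @rdname accessors
#' @export
setGeneric("featClasses", function(x) standardGeneric("featClasses"))
#' @rdname accessors
#' @export
setMethod("featClasses", "FeatureSchema", function(x) {
  cl <- rep(x@baseClasses, each = 3L)
  names(cl) <- x@featureNames
  cl
})

#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))
#' @rdname accessors
#' @export
setMethod("nFeatures", "FeatureSchema", function(x) length(x@featureNames))

#' @rdname accessors
#' @export
setGeneric("refParams", function(x) standardGeneric("refParams"))
#' @rdname accessors
#' @export
setMethod("refParams", "ReferenceTable", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("refFeatures", function(x) standardGeneric("refFeatures"))
#' @rdname accessors
#' @export
setMethod("refFeatures", "ReferenceTable", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("refSplit", function(x) standardGeneric("refSplit"))
#' @rdname accessors
#' @export
setMethod("refSplit", "ReferenceTable", function(x) x@split)

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setMethod("haplotypes", "LocusData", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "LocusData", function(x) x@positions)

#' @rdname accessors
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))
#' @rdname accessors
#' @export
setMethod("popLabels", "LocusData", function(x) x@popLabels)
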