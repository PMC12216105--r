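## Coalescent simulation of per-locus phased haplotype data.  The heavy
## lifting (coalescent with recombination under an arbitrary two-population
## demography, infinite-sites mutations with known ancestral state) is
## delegated to msprime through the bundled backend script; this file owns
## the job/parse protocol, seeding, and the reference-table builder.

#' Construct a sampling design
#'
#' @param nDiploidPerPop diploid individuals sampled per population.
#' @param nLoci number of independent neutral loci per simulated data set.
#' @param locusLength locus length in bp.
#' @param recombinationRate per bp per generation.
#' @param mutationRate per bp per generation.
#' @return a [SampleDesign-class].
#' @examples
#' sampleDesign()            # the default human-like design
#' @export
sampleDesign <- function(nDiploidPerPop = 10L, nLoci = 20L,
                         locusLength = 2e6, recombinationRate = 1e-8,
                         mutationRate = 1.25e-8) {
  new("SampleDesign",
      nDiploidPerPop = as.integer(nDiploidPerPop),
      nLoci = as.integer(nLoci),
      locusLength = as.numeric(locusLength),
      recombinationRate = as.numeric(recombinationRate),
      mutationRate = as.numeric(mutationRate))
}

#' Construct a LocusData object
#'
#' @param haplotypes 0/1 matrix, haplotypes x sites, population 1 rows
#'   first.
#' @param positions strictly increasing site coordinates in
#'   `[0, locusLength)`.
#' @param popLabels population index (1/2) per haplotype row.
#' @param locusLength locus length in bp.
#' @return a [LocusData-class].
#' @export
locusData <- function(haplotypes, positions, popLabels, locusLength) {
  storage.mode(haplotypes) <- "integer"
  new("LocusData", haplotypes = haplotypes,
      positions = as.numeric(positions),
      popLabels = as.integer(popLabels),
      locusLength = as.numeric(locusLength))
}

.pythonBin <- function() {
  bin <- getOption("demSBI.python", Sys.getenv("DEMSBI_PYTHON", "python"))
  path <- Sys.which(bin)
  if (!nzchar(path)) stop("python interpreter '", bin, "' not found on PATH")
  path
}

.backendScript <- function() {
  p <- system.file("python", "msprime_backend.py", package = "demSBI")
  if (!nzchar(p))
    p <- file.path("inst", "python", "msprime_backend.py")  # pre-install
  normalizePath(p, mustWork = TRUE)
}

#' Check that the coalescent backend is available
#'
#' @return `TRUE` invisibly, or an error describing the problem.
#' @export
checkBackend <- function() {
  out <- suppressWarnings(system2(.pythonBin(), c("-c", shQuote("import msprime")),
                                  stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    stop("the msprime coalescent backend is not importable from python: ",
         paste(out, collapse = "\n"))
  invisible(TRUE)
}

.eventsToJob <- function(events) {
  list(split_time = events@splitTime,
       ancestral_size = events@ancestralSize,
       pop_sizes = events@popSizes,
       growth_rates = events@growthRates,
       mig_windows = if (nrow(events@migrationWindows))
         lapply(seq_len(nrow(events@migrationWindows)), function(i)
           list(start = events@migrationWindows$start[i],
                end = events@migrationWindows$end[i],
                rate = events@migrationWindows$rate[i]))
       else list())
}

## Run the backend for a batch of simulations.
## sims: list of list(id, events, lociSeeds = matrix n_loci x 2)
## Returns list (per sim, in input order) of lists of LocusData.
.runBackend <- function(sims, design) {
  job <- list(
    design = list(n_diploid_per_pop = design@nDiploidPerPop,
                  locus_length = design@locusLength,
                  recombination_rate = design@recombinationRate,
                  mutation_rate = design@mutationRate),
    sims = lapply(sims, function(s)
      list(id = s$id,
           demography = .eventsToJob(s$events),
           loci = lapply(seq_len(nrow(s$lociSeeds)), function(i)
             list(idx = i,
                  ancestry_seed = s$lociSeeds[i, 1L],
                  mutation_seed = s$lociSeeds[i, 2L])))))
  jobFile <- tempfile("demsbi_job_", fileext = ".json")
  outFile <- tempfile("demsbi_out_", fileext = ".txt")
  on.exit(unlink(c(jobFile, outFile)), add = TRUE)
  jsonlite::write_json(job, jobFile, auto_unbox = TRUE, digits = NA)
  err <- tempfile("demsbi_err_")
  status <- system2(.pythonBin(), c(.backendScript(), jobFile, outFile),
                    stdout = FALSE, stderr = err)
  if (status != 0) {
    ids <- paste(vapply(sims, function(s) as.character(s$id), ""),
                 collapse = ", ")
    stop("coalescent backend failed (simulations ", ids, "):\n",
         paste(readLines(err, warn = FALSE), collapse = "\n"))
  }
  .parseBackendOutput(outFile, design)
}

.parseBackendOutput <- function(outFile, design) {
  lines <- readLines(outFile)
  nHap <- 4L * design@nDiploidPerPop
  labels <- rep(1:2, each = nHap %/% 2L)
  res <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    stopifnot(hdr[1L] == "L")
    simId <- hdr[2L]
    nh <- as.integer(hdr[4L]); ns <- as.integer(hdr[5L])
    pos <- if (ns > 0)
      as.numeric(strsplit(substring(lines[i + 1L], 3L), " ",
                          fixed = TRUE)[[1L]])
    else numeric()
    hapLines <- lines[(i + 2L):(i + 1L + nh)]
    H <- if (ns > 0) {
      raw <- as.integer(charToRaw(paste(hapLines, collapse = ""))) - 48L
      matrix(raw, nrow = nh, ncol = ns, byrow = TRUE)
    } else matrix(integer(), nrow = nh, ncol = 0L)
    ld <- locusData(H, pos, labels, design@locusLength)
    if (is.null(res[[simId]])) res[[simId]] <- list()
    res[[simId]][[length(res[[simId]]) + 1L]] <- ld
    i <- i + 2L + nh
  }
  res
}

#' Simulate one locus under a demography
#'
#' Draws phased haplotype data for a single locus from the neutral
#' coalescent with recombination under the given demography, with
#' infinite-sites biallelic mutations whose ancestral state is known (0 =
#' ancestral, 1 = derived).  Deterministic given `seed`.
#'
#' @param events a [DemographyEvents-class] (see [toDemographyEvents()]).
#' @param design a [SampleDesign-class].
#' @param seed integer seed.
#' @return a [LocusData-class].
#' @export
simulateLocus <- function(events, design, seed) {
  validObject(events); validObject(design)
  seeds <- matrix(deriveSeeds(seed, 2L), ncol = 2L)
  res <- .runBackend(list(list(id = "1", events = events, lociSeeds = seeds)),
                     design)
  res[["1"]][[1L]]
}

#' Simulate a multi-locus data set
#'
#' Simulates `design@nLoci` independent loci under one parameter draw, with
#' per-locus seeds derived deterministically from the master seed.
#'
#' @param params a parameter draw (named vector / one-row data.frame) or a
#'   [DemographyEvents-class].
#' @param design a [SampleDesign-class].
#' @param seed integer master seed.
#' @param model `"IM"` or `"SC"` (ignored when `params` is already a
#'   `DemographyEvents`).
#' @return list of [LocusData-class] of length `design@nLoci`.
#' @export
simulateDataset <- function(params, design, seed, model = "IM") {
  events <- if (is(params, "DemographyEvents")) params
            else toDemographyEvents(params, model)
  seeds <- matrix(deriveSeeds(seed, 2L * design@nLoci), ncol = 2L)
  res <- .runBackend(list(list(id = "1", events = events, lociSeeds = seeds)),
                     design)
  res[["1"]]
}

#' Build a reference table of simulations and features
#'
#' Samples `nSims` parameter draws from the priors, simulates each
#' multi-locus data set, computes the aggregated summary-statistic feature
#' vector of each simulation, and assigns the rows to
#' train/validation/test in sampling order.  Simulations are dispatched to
#' the backend in chunks; when `outDir` is given, each completed chunk is
#' checkpointed as a CSV and the build is resumable.
#'
#' @param model `"IM"` or `"SC"`.
#' @param priors prior bounds data.frame (see [defaultPriors()]).
#' @param design a [SampleDesign-class].
#' @param nSims total number of simulated data sets.
#' @param splitSizes integer(3), train/validation/test sizes; must sum to
#'   `nSims`.
#' @param seed integer master seed.
#' @param chunkSize simulations per backend call.
#' @param outDir optional checkpoint directory.
#' @param verbose print per-chunk progress.
#' @return a [ReferenceTable-class].
#' @export
buildReferenceTable <- function(model, priors, design, nSims,
                                splitSizes = NULL, seed = 1L,
                                chunkSize = 200L, outDir = NULL,
                                verbose = FALSE) {
  model <- match.arg(model, c("IM", "SC"))
  if (nSims < 1) stop("nSims must be >= 1")
  if (is.null(splitSizes)) {
    nTr <- floor(nSims / 2); nVa <- floor(nSims / 4)
    splitSizes <- c(nTr, nVa, nSims - nTr - nVa)
  }
  if (sum(splitSizes) != nSims)
    stop("splitSizes must sum to nSims")
  seeds <- deriveSeeds(seed, 1L + nSims)
  params <- sampleParameters(priors, nSims, seeds[1L], model)
  simSeeds <- seeds[-1L]
  schema <- buildSchema(design)
  nb <- length(schema@baseNames)

  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  chunks <- split(seq_len(nSims), ceiling(seq_len(nSims) / chunkSize))
  features <- matrix(NA_real_, nrow = nSims, ncol = nFeatures(schema),
                     dimnames = list(NULL, featNames(schema)))
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    ckpt <- if (!is.null(outDir))
      file.path(outDir, sprintf("features_chunk_%04d.csv", ci)) else NULL
    if (!is.null(ckpt) && file.exists(ckpt)) {
      m <- as.matrix(data.table::fread(ckpt))
      stopifnot(nrow(m) == length(idx))
      features[idx, ] <- m
      if (verbose) message("chunk ", ci, " restored from checkpoint")
      next
    }
    sims <- lapply(idx, function(i) {
      list(id = as.character(i),
           events = toDemographyEvents(params[i, ], model),
           lociSeeds = matrix(deriveSeeds(simSeeds[i], 2L * design@nLoci),
                              ncol = 2L))
    })
    loci <- .runBackend(sims, design)
    for (i in idx) {
      perLocus <- lapply(loci[[as.character(i)]], locusStatVector,
                         schema = schema)
      features[i, ] <- aggregateFeatures(perLocus, schema)
    }
    if (!is.null(ckpt))
      data.table::fwrite(data.table::as.data.table(features[idx, ,
                                                            drop = FALSE]),
                         ckpt)
    if (verbose) message("chunk ", ci, "/", length(chunks), " done")
  }

  split <- factor(rep(c("train", "validation", "test"), times = splitSizes),
                  levels = c("train", "validation", "test"))
  attr(params, "nRejected") <- NULL
  attr(params, "model") <- NULL
  new("ReferenceTable", params = params, features = features, split = split,
      schema = schema, model = model, priors = priors,
      seed = as.integer(seed))
}

#' Scaled-down benchmark configuration
#'
#' The desk-scale counterpart of the full study design, used to exercise
#' the complete inference pipeline on one CPU in minutes: the standard IM
#' priors with 5 loci of 500 kb and 4 diploids per population, 1500
#' simulations split 1000/250/250 into train/validation/test.
#'
#' @return list with `model`, `priors`, `design`, `nSims`, `splitSizes`.
#' @export
benchmarkConfig <- function() {
  list(model = "IM",
       priors = defaultPriors("IM"),
       design = sampleDesign(nDiploidPerPop = 4L, nLoci = 5L,
                             locusLength = 5e5),
       nSims = 1500L,
       splitSizes = c(1000L, 250L, 250L))
}

#' Miniature configuration for tests and examples
#'
#' A deterministic small-scale configuration (2 loci of 100 kb, 4 diploids
#' per population, narrowed IM priors) that simulates and featurizes in
#' seconds while exercising every statistic class.
#'
#' @return list with elements `model`, `priors`, `design`.
#' @export
fixtureConfig <- function() {
  list(model = "IM",
       priors = data.frame(
         name = .IM_PARAMS,
         low  = c(100,  0,     500,  500,  500),
         high = c(3000, 0.001, 5000, 5000, 5000)),
       design = sampleDesign(nDiploidPerPop = 4L, nLoci = 2L,
                             locusLength = 1e5))
}
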