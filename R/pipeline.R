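## End-to-end orchestration: run configuration (YAML), strict tabular I/O
## for feature/parameter tables, checkpointed stage execution and the run
## manifest.

#' Assemble a run configuration
#'
#' @param model `"IM"` or `"SC"`.
#' @param priors prior data.frame; defaults to [defaultPriors()] of the
#'   model.
#' @param design a [SampleDesign-class].
#' @param nSims number of simulated data sets.
#' @param splitSizes integer(3) train/validation/test sizes.
#' @param methods regression methods to train.
#' @param targets parameters to infer (default: all model parameters).
#' @param abc list with `run` (logical), `algorithms`, `tolerance`,
#'   `pointMode`, `nTargets` (test rows used as pseudo-observed targets).
#' @param outDir output directory.
#' @param seed master seed.
#' @param chunkSize simulations per backend call.
#' @return list of class `demSBIRunConfig`.
#' @export
runConfig <- function(model = "IM", priors = NULL, design = sampleDesign(),
                      nSims = 100L, splitSizes = NULL,
                      methods = c("rf", "xgb", "mlp"), targets = NULL,
                      abc = list(run = FALSE), outDir = tempfile("demsbi_run_"),
                      seed = 1L, chunkSize = 200L) {
  model <- match.arg(model, c("IM", "SC"))
  priors <- priors %||% defaultPriors(model)
  abc <- utils::modifyList(
    list(run = FALSE, algorithms = "rejection", tolerance = 0.01,
         pointMode = "mean", nTargets = 50L), abc)
  cfg <- list(model = model, priors = priors, design = design,
              nSims = as.integer(nSims), splitSizes = splitSizes,
              methods = methods,
              targets = targets %||% modelParams(model), abc = abc,
              outDir = outDir, seed = as.integer(seed),
              chunkSize = as.integer(chunkSize))
  class(cfg) <- "demSBIRunConfig"
  cfg
}

#' Read/write a run configuration as YAML
#'
#' The configuration round-trips losslessly through serialization.
#'
#' @param config a `demSBIRunConfig`.
#' @param path file path.
#' @return `readRunConfig` returns the configuration.
#' @export
writeRunConfig <- function(config, path) {
  d <- config$design
  out <- list(
    model = config$model,
    priors = lapply(seq_len(nrow(config$priors)), function(i)
      list(name = config$priors$name[i], low = config$priors$low[i],
           high = config$priors$high[i])),
    design = list(n_diploid_per_pop = d@nDiploidPerPop, n_loci = d@nLoci,
                  locus_length = d@locusLength,
                  recombination_rate = d@recombinationRate,
                  mutation_rate = d@mutationRate),
    n_sims = config$nSims, split_sizes = config$splitSizes,
    methods = config$methods, targets = config$targets, abc = config$abc,
    out_dir = config$outDir, seed = config$seed,
    chunk_size = config$chunkSize)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  priors <- do.call(rbind, lapply(y$priors, function(p)
    data.frame(name = p$name, low = p$low, high = p$high)))
  runConfig(model = y$model, priors = priors,
            design = sampleDesign(y$design$n_diploid_per_pop,
                                  y$design$n_loci, y$design$locus_length,
                                  y$design$recombination_rate,
                                  y$design$mutation_rate),
            nSims = y$n_sims, splitSizes = unlist(y$split_sizes),
            methods = unlist(y$methods), targets = unlist(y$targets),
            abc = y$abc, outDir = y$out_dir, seed = y$seed,
            chunkSize = y$chunk_size)
}

#' Strict tabular I/O for feature tables
#'
#' Feature tables are comma-separated text with a header row exactly
#' matching the schema feature names, in schema order.  Reading validates
#' the header and rejects missing, extra or reordered columns, listing the
#' discrepancies; numeric values round-trip at full precision.
#'
#' @param features numeric matrix with schema column names.
#' @param path file path.
#' @param schema a [FeatureSchema-class] to validate against.
#' @return `readFeatureTable` returns the numeric matrix.
#' @export
writeFeatureTable <- function(features, path) {
  .writeNumericCSV(features, path)
  invisible(path)
}

## format doubles with 17 significant digits so values round-trip exactly
.writeNumericCSV <- function(x, path) {
  m <- as.matrix(x)
  ch <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  dt <- data.table::as.data.table(ch)
  data.table::setnames(dt, colnames(m))
  data.table::fwrite(dt, path, quote = FALSE)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path, schema = NULL) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  header <- gsub('^"|"$', "", header)
  if (!is.null(schema)) {
    want <- featNames(schema)
    if (!identical(header, want)) {
      missing <- setdiff(want, header)
      extra <- setdiff(header, want)
      reordered <- length(missing) == 0L && length(extra) == 0L
      stop("feature table header does not match the schema; ",
           if (reordered) "columns are present but in a different order"
           else paste0("missing: ",
                       paste(utils::head(missing, 5L), collapse = ", "),
                       "; extra: ",
                       paste(utils::head(extra, 5L), collapse = ", ")))
    }
  }
  wmsg <- NULL
  dt <- withCallingHandlers(
    data.table::fread(path, sep = ",", header = TRUE, fill = FALSE),
    warning = function(w) {
      wmsg <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (!is.null(wmsg))
    stop("malformed feature table ", path, ": ", wmsg)
  if (ncol(dt) != length(header))
    stop("malformed feature table: ", path)
  m <- as.matrix(dt)
  if (!is.numeric(m)) stop("feature table contains non-numeric values")
  m
}

#' Write/read a parameter table
#'
#' One row per simulation, columns named exactly as the parameter labels.
#'
#' @param params data.frame of parameter draws.
#' @param path file path.
#' @param model `"IM"` or `"SC"`, used to validate columns on read.
#' @return `readParameterTable` returns the data.frame.
#' @export
writeParameterTable <- function(params, path) {
  .writeNumericCSV(params, path)
  invisible(path)
}

#' @rdname writeParameterTable
#' @export
readParameterTable <- function(path, model = NULL) {
  df <- as.data.frame(data.table::fread(path))
  if (!is.null(model) && !identical(names(df), modelParams(model)))
    stop("parameter table columns do not match the ", model, " model")
  df
}

#' Write a schema manifest
#'
#' @param schema a [FeatureSchema-class].
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
writeSchemaManifest <- function(schema, path) {
  d <- schema@design
  jsonlite::write_json(list(
    hash = schemaHash(schema),
    n_features = nFeatures(schema),
    design = list(n_diploid_per_pop = d@nDiploidPerPop, n_loci = d@nLoci,
                  locus_length = d@locusLength,
                  recombination_rate = d@recombinationRate,
                  mutation_rate = d@mutationRate),
    feature_names = featNames(schema)), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' Run the full inference pipeline
#'
#' Executes the stages simulate+featurize, train, evaluate and
#' (optionally) ABC from a single configuration, writing tables and a run
#' manifest under `config$outDir`.  Completed stages are checkpointed by
#' their output files and skipped on re-run, so an interrupted run resumes
#' from the last completed stage.  Given the same configuration and master
#' seed, the simulated features and the tree-model outputs are identical
#' across runs.
#'
#' @param config a `demSBIRunConfig` from [runConfig()].
#' @param verbose print stage progress.
#' @return list (the run manifest): configuration snapshot, schema hash,
#'   stage seeds, file paths, completion flags.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "demSBIRunConfig"))
  od <- config$outDir
  if (!dir.exists(od)) dir.create(od, recursive = TRUE)
  stageSeeds <- deriveSeeds(config$seed, 4L)
  schema <- buildSchema(config$design)
  paths <- list(params = file.path(od, "params.csv"),
                features = file.path(od, "features.csv"),
                split = file.path(od, "split.csv"),
                schema = file.path(od, "schema.json"),
                predictions = file.path(od, "predictions.csv"),
                evalTab = file.path(od, "eval.csv"),
                abcTab = file.path(od, "abc.csv"),
                manifest = file.path(od, "manifest.yaml"),
                models = file.path(od, "models"))

  ## stage 1: simulate + featurize
  if (!file.exists(paths$features)) {
    if (verbose) message("stage simulate/featurize")
    ref <- buildReferenceTable(config$model, config$priors, config$design,
                               config$nSims, config$splitSizes,
                               seed = stageSeeds[1L],
                               chunkSize = config$chunkSize,
                               outDir = file.path(od, "checkpoints"),
                               verbose = verbose)
    writeParameterTable(refParams(ref), paths$params)
    writeFeatureTable(refFeatures(ref), paths$features)
    data.table::fwrite(data.frame(split = as.character(refSplit(ref))),
                       paths$split)
    writeSchemaManifest(schema, paths$schema)
  } else if (verbose) message("stage simulate/featurize: checkpoint found")
  params <- readParameterTable(paths$params, config$model)
  features <- readFeatureTable(paths$features, schema)
  split <- factor(data.table::fread(paths$split)$split,
                  levels = c("train", "validation", "test"))

  tr <- split == "train"; va <- split == "validation"; te <- split == "test"

  ## stage 2: train + predict
  if (!file.exists(paths$predictions)) {
    if (verbose) message("stage train")
    if (!dir.exists(paths$models)) dir.create(paths$models)
    preds <- data.frame(row.names = seq_len(sum(te)))
    for (method in config$methods) {
      for (pn in config$targets) {
        pr <- config$priors[config$priors$name == pn, ]
        reg <- trainRegressor(regressorConfig(method),
                              features[tr, , drop = FALSE], params[[pn]][tr],
                              features[va, , drop = FALSE], params[[pn]][va],
                              target = pn, bounds = c(pr$low, pr$high),
                              seed = stageSeeds[2L])
        saveRDS(reg, file.path(paths$models,
                               sprintf("%s_%s.rds", method, pn)))
        preds[[paste(method, pn, sep = ".")]] <-
          predictParams(reg, features[te, , drop = FALSE])
      }
    }
    data.table::fwrite(preds, paths$predictions)
  } else if (verbose) message("stage train: checkpoint found")
  preds <- as.data.frame(data.table::fread(paths$predictions))

  ## stage 3: evaluate
  if (!file.exists(paths$evalTab)) {
    if (verbose) message("stage evaluate")
    predictions <- list()
    for (method in config$methods)
      predictions[[method]] <- lapply(
        stats::setNames(config$targets, config$targets),
        function(pn) preds[[paste(method, pn, sep = ".")]])
    ev <- evalReport(predictions, params[te, , drop = FALSE], config$priors)
    data.table::fwrite(ev, paths$evalTab)
  } else if (verbose) message("stage evaluate: checkpoint found")

  ## stage 4: ABC baselines (optional)
  if (isTRUE(config$abc$run) && !file.exists(paths$abcTab)) {
    if (verbose) message("stage abc")
    refIdx <- which(!te)
    teIdx <- which(te)[seq_len(min(config$abc$nTargets, sum(te)))]
    rows <- list()
    for (algo in config$abc$algorithms) {
      fn <- switch(algo, rejection = abcRejection,
                   loclinear = abcLoclinear, neuralnet = abcNeuralnet,
                   stop("unknown ABC algorithm: ", algo))
      for (ti in teIdx) {
        res <- fn(features[ti, ], features[refIdx, , drop = FALSE],
                  params[refIdx, config$targets, drop = FALSE],
                  config$abc$tolerance)
        est <- pointEstimate(res, config$abc$pointMode)
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = algo, target = ti,
          parameter = names(est), estimate = unname(est),
          truth = unlist(params[ti, names(est)]))
      }
    }
    data.table::fwrite(do.call(rbind, rows), paths$abcTab)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("demSBI")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = stageSeeds,
    schema_hash = schemaHash(schema),
    model = config$model,
    n_sims = config$nSims,
    files = lapply(paths, identity),
    completed = list(
      simulate = file.exists(paths$features),
      train = file.exists(paths$predictions),
      evaluate = file.exists(paths$evalTab),
      abc = !isTRUE(config$abc$run) || file.exists(paths$abcTab)))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(manifest)
}
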