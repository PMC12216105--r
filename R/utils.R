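## Internal utilities: seed-isolated RNG streams, derived seeds, and a small
## stable string hash used to fingerprint feature schemas.

`%||%` <- function(a, b) if (is.null(a)) b else a

.getRNGState <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  else NULL
}

.setRNGState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  } else assign(".Random.seed", state, envir = .GlobalEnv)
  invisible(NULL)
}

#' Seed-isolated random number stream
#'
#' Returns a set of RNG functions drawing from a private stream seeded with
#' `seed`, leaving the caller's global RNG state untouched.  Used so that
#' every stochastic operation in the package is reproducible from an
#' explicit seed without side effects on user code.
#'
#' @param seed integer seed.
#' @return list of functions `runif`, `rnorm`, `sample`, `sample.int`.
#' @keywords internal
localRNG <- function(seed) {
  outer <- .getRNGState()
  set.seed(seed)
  state <- .getRNGState()
  .setRNGState(outer)
  wrap <- function(f) {
    function(...) {
      caller <- .getRNGState()
      .setRNGState(state)
      on.exit({ state <<- .getRNGState(); .setRNGState(caller) }, add = TRUE)
      f(...)
    }
  }
  list(runif = wrap(stats::runif),
       rnorm = wrap(stats::rnorm),
       sample = wrap(base::sample),
       sample.int = wrap(base::sample.int))
}

#' Derive reproducible child seeds from a master seed
#'
#' Deterministically expands one master seed into `n` distinct integer
#' seeds (all in `[1, 2^31 - 2]`), so that parallel or per-locus
#' sub-simulations are reproducible from a single recorded seed.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
deriveSeeds <- function(master, n) {
  rng <- localRNG(master)
  rng$sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

## FNV-1a style rolling hash over a character vector, returned as hex.
## Stable across platforms; used to fingerprint schemas in manifests.
hashStrings <- function(x) {
  h <- 2166136261
  for (r in as.integer(charToRaw(paste(x, collapse = "\x1f")))) {
    h <- bitwXor(as.integer(h %% 2^31), r)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## weighted quantile-free helpers
.sampleVar <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::var(x)
}

.sampleSD <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}
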