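## Per-locus summary statistics (11 classes) and their cross-locus
## aggregation into the feature vector used for inference.
##
## Within-population classes (S, Tajima's D, PI, windowed haplotypic
## heterozygosity, SFS, LD, IBS, AFIBS) are computed on each population
## sample and on the pooled sample; among-population classes (Hudson's Fst,
## Dxy, joint SFS) once per locus.  All coordinates are 0-based on
## [0, locusLength).

#' Default linkage-disequilibrium distance bins
#'
#' Nineteen geometrically spaced distance bins whose centres range from
#' 282 bp to 1.4 Mb; edges are the geometric midpoints between adjacent
#' centres (outer edges extended by half a spacing ratio).
#'
#' @return numeric vector of 20 bin edges (bp).
#' @export
ldBinEdges <- function() {
  centers <- exp(seq(log(282), log(1.4e6), length.out = 19L))
  r <- sqrt(centers[2L] / centers[1L])
  c(centers[1L] / r, centers * r)
}

.defaultStatConfig <- function() {
  list(windowSize = 5e4,
       ldEdges = ldBinEdges(),
       ldMaxPairsPerBin = 10000L,
       ibsNSubsets = 20L,
       decileProbs = seq(0.1, 0.9, by = 0.1),
       statSeed = 1000003L)
}

## powers of two up to the haplotype count: 2, 4, 8, ... (default design:
## {2,4,8,16} per 20-haplotype population sample, {2,4,8,16,32} pooled)
.ibsMList <- function(nHap) 2L^seq_len(max(1L, floor(log2(nHap))))

## ---- individual statistic classes -----------------------------------------

#' Classic nucleotide-diversity statistics
#'
#' Computes, for one sample of haplotypes at one locus: `S`, the proportion
#' of segregating sites per bp; Tajima's `D`; and the mean and standard
#' deviation across segregating sites of the unbiased expected
#' heterozygosity `h_j = n/(n-1) * (1 - p_j^2 - (1-p_j)^2)`.
#'
#' @param hap 0/1 haplotype matrix (haplotypes x sites).
#' @param positions site coordinates (unused; kept for a uniform
#'   interface).
#' @param locusLength locus length in bp.
#' @return list with `S`, `D`, `piMean`, `piSd` (`NA` where undefined, e.g.
#'   no segregating site).
#' @export
classicStats <- function(hap, positions, locusLength) {
  n <- nrow(hap)
  stopifnot(n >= 2L)
  counts <- colSums(hap)
  seg <- counts > 0L & counts < n
  Sn <- sum(seg)
  if (Sn == 0L)
    return(list(S = 0, D = NA_real_, piMean = NA_real_, piSd = NA_real_))
  p <- counts[seg] / n
  h <- n / (n - 1) * (1 - p^2 - (1 - p)^2)
  ii <- seq_len(n - 1L)
  a1 <- sum(1 / ii); a2 <- sum(1 / ii^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * Sn + e2 * Sn * (Sn - 1))
  D <- if (denom > 0) (sum(h) - Sn / a1) / denom else NA_real_
  list(S = Sn / locusLength, D = D, piMean = mean(h), piSd = .sampleSD(h))
}

#' Windowed haplotypic heterozygosity
#'
#' Tiles the locus with non-overlapping windows of `windowSize` bp (partial
#' trailing window dropped; a locus shorter than one window is a single
#' window) and computes, per window, `H_k = 1 - sum(f_h^2)` over the
#' frequencies of the distinct haplotype strings restricted to the sites in
#' the window.  Windows without polymorphism have `H_k = 0`.
#'
#' @inheritParams classicStats
#' @param windowSize window width in bp.
#' @return list with `mean` and `sd` of the per-window heterozygosities.
#' @export
windowHaploHet <- function(hap, positions, locusLength, windowSize = 5e4) {
  stopifnot(windowSize > 0)
  nw <- max(1L, floor(locusLength / windowSize))
  ## sites beyond the last full window (partial remainder) belong to none
  keep <- positions < nw * windowSize
  hap <- hap[, keep, drop = FALSE]
  win <- as.integer(floor(positions[keep] / windowSize))
  H <- .winh_het(hap, win, nw)
  list(mean = mean(H), sd = .sampleSD(H))
}

#' Site-frequency-spectrum features
#'
#' For derived-allele counts `i = 1, ..., maxCount`: the percentage of
#' qualifying sites with derived count `i` (percentages sum to 100), and
#' the standard deviation of the distances between adjacent sites of count
#' `i` (masked when fewer than two gaps exist).
#'
#' @inheritParams classicStats
#' @param maxCount largest derived count indexed (default `nrow(hap) - 1`,
#'   the classic within-sample spectrum).
#' @return list with numeric vectors `pct` and `gapSd`, both indexed
#'   1..`maxCount`; all entries `NA` when no site qualifies.
#' @export
sfsFeatures <- function(hap, positions, maxCount = nrow(hap) - 1L) {
  counts <- colSums(hap)
  qual <- counts >= 1L & counts <= maxCount
  pct <- rep(NA_real_, maxCount)
  gapSd <- rep(NA_real_, maxCount)
  tot <- sum(qual)
  if (tot == 0L) return(list(pct = pct, gapSd = gapSd))
  pct <- 100 * tabulate(counts[qual], nbins = maxCount) / tot
  for (i in unique(counts[qual])) {
    gp <- diff(positions[counts == i])
    if (length(gp) >= 2L) gapSd[i] <- stats::sd(gp)
  }
  list(pct = pct, gapSd = gapSd)
}

## Enumerate (or uniformly subsample) site pairs per distance bin, using
## the sorted positions: pairs (i, j), j > i, with pos_j - pos_i in
## [edges[k], edges[k+1]).  Returns list(bin -> list(ii, jj)).
.pairsByBin <- function(pos, edges, cap, rng) {
  nb <- length(edges) - 1L
  S <- length(pos)
  res <- vector("list", nb)
  if (S < 2L) return(res)
  idx <- seq_len(S)
  for (k in seq_len(nb)) {
    ## first j with pos_j >= pos_i + lo, last j with pos_j < pos_i + hi
    jmin <- findInterval(pos + edges[k], pos, left.open = TRUE) + 1L
    jmax <- findInterval(pos + edges[k + 1L], pos, left.open = TRUE)
    jmin <- pmax(jmin, idx + 1L)
    np <- pmax(jmax - jmin + 1L, 0L)
    tot <- sum(np)
    if (tot == 0L) next
    if (tot <= cap) {
      ii <- rep.int(idx, np)
      jj <- sequence(np, from = jmin)
    } else {
      cum <- cumsum(as.numeric(np))
      ranks <- rng$sample(tot, cap)
      ii <- findInterval(ranks, cum, left.open = TRUE) + 1L
      off <- ranks - c(0, cum)[ii]
      jj <- jmin[ii] + off - 1L
    }
    res[[k]] <- list(ii = ii, jj = jj)
  }
  res
}

#' Linkage-disequilibrium features
#'
#' Mean and standard deviation of the squared allele-frequency correlation
#' `r^2` between pairs of segregating sites, per distance bin.  `r^2` is
#' computed from phased haplotype frequencies as
#' `(p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B))`.  Pairs per bin are
#' capped by seeded subsampling; bins with fewer than two pairs are masked.
#'
#' @inheritParams classicStats
#' @param edges distance-bin edges (bp), see [ldBinEdges()].
#' @param maxPairsPerBin subsampling cap per bin.
#' @param seed seed for the subsampling.
#' @return list with numeric vectors `mean` and `sd`, one entry per bin.
#' @export
ldFeatures <- function(hap, positions, edges = ldBinEdges(),
                       maxPairsPerBin = 10000L, seed = 1L) {
  n <- nrow(hap)
  counts <- colSums(hap)
  seg <- counts > 0L & counts < n
  X <- hap[, seg, drop = FALSE]
  pos <- positions[seg]
  nb <- length(edges) - 1L
  mu <- rep(NA_real_, nb); sdv <- rep(NA_real_, nb)
  if (ncol(X) >= 2L) {
    rng <- localRNG(seed)
    pairs <- .pairsByBin(pos, edges, maxPairsPerBin, rng)
    storage.mode(X) <- "integer"
    for (k in seq_len(nb)) {
      pk <- pairs[[k]]
      if (is.null(pk) || length(pk$ii) < 2L) next
      r2 <- .ld_r2_pairs(X, pk$ii, pk$jj)
      mu[k] <- mean(r2); sdv[k] <- stats::sd(r2)
    }
  }
  list(mean = mu, sd = sdv)
}

#' Identity-by-state segment-length deciles
#'
#' For each subset size `m`, draws seeded random subsets of `m` haplotypes;
#' the sites polymorphic within a subset partition `[0, locusLength]` into
#' segments over which the `m` haplotypes are completely identical
#' (including the two flanking segments).  Segment lengths are pooled over
#' subsets and summarized by the nine interior deciles.  Subset sampling is
#' made invariant to haplotype row order by canonicalizing (sorting) the
#' rows first.
#'
#' @inheritParams classicStats
#' @param mList subset sizes (each must be `<= nrow(hap)`).
#' @param nSubsets seeded random subsets per `m`.
#' @param seed subsampling seed.
#' @param probs decile probabilities.
#' @return matrix `length(mList)` x `length(probs)` of segment-length
#'   quantiles (rows named `m<m>`).
#' @export
ibsFeatures <- function(hap, positions, locusLength,
                        mList = c(2L, 4L, 8L, 16L), nSubsets = 20L,
                        seed = 1L, probs = seq(0.1, 0.9, by = 0.1)) {
  n <- nrow(hap)
  if (any(mList > n))
    stop("IBS subset size m exceeds the number of haplotypes (",
         max(mList), " > ", n, ")")
  ## canonical row order: statistics must not depend on input row order
  if (ncol(hap)) {
    key <- apply(hap, 1L, paste, collapse = "")
    hap <- hap[order(key), , drop = FALSE]
  }
  rng <- localRNG(seed)
  out <- matrix(NA_real_, nrow = length(mList), ncol = length(probs),
                dimnames = list(paste0("m", mList), NULL))
  nc <- ncol(hap)
  for (mi in seq_along(mList)) {
    m <- mList[mi]
    ## when few subsets exist, enumerate each exactly once instead of
    ## sampling (deterministic and exhaustive for small samples)
    subsets <- if (choose(n, m) <= nSubsets) {
      asplit(utils::combn(n, m), 2L)
    } else {
      keys <- matrix(rng$runif(n * nSubsets), nrow = n)
      lapply(seq_len(nSubsets), function(s) order(keys[, s])[seq_len(m)])
    }
    pool <- vector("list", length(subsets))
    for (s in seq_along(subsets)) {
      rows <- subsets[[s]]
      if (nc) {
        cs <- .colSums(hap[rows, , drop = FALSE], m, nc)
        bp <- positions[cs > 0L & cs < m]
      } else bp <- numeric()
      pool[[s]] <- diff(c(0, bp, locusLength))
    }
    out[mi, ] <- stats::quantile(unlist(pool), probs = probs, names = FALSE,
                                 type = 7)
  }
  out
}

#' Allele-frequency-conditioned IBS segment features
#'
#' For each site whose derived allele is carried by `i` haplotypes
#' (`minCount <= i <= maxCount`), the AFIBS segment is the maximal region
#' around the site over which the `i` carrier haplotypes are completely
#' identical: it extends to the nearest flanking site at which the carriers
#' are not all identical (exclusive), truncated at the locus boundaries.
#' Returns the per-frequency mean and standard deviation of segment
#' lengths.  A single-carrier site has no interrupting site by
#' construction, so its segment is the whole locus.
#'
#' @inheritParams classicStats
#' @param minCount,maxCount derived-count range indexed.
#' @return list of numeric vectors `mu` and `sd` indexed 1..`maxCount`
#'   (entries below `minCount` or without qualifying sites are `NA`).
#' @export
afibsFeatures <- function(hap, positions, locusLength, minCount = 1L,
                          maxCount = nrow(hap) - 1L) {
  counts <- colSums(hap)
  S <- length(counts)
  mu <- rep(NA_real_, maxCount); sdv <- rep(NA_real_, maxCount)
  focal <- which(counts >= minCount & counts <= maxCount)
  if (!length(focal)) return(list(mu = mu, sd = sdv))
  storage.mode(hap) <- "integer"
  lens <- numeric(length(focal))
  single <- counts[focal] == 1L
  ## a single carrier has no interrupting site: segment spans the locus
  lens[single] <- locusLength
  if (any(!single))
    lens[!single] <- .afibs_lengths(hap, positions, focal[!single],
                                    locusLength)
  fc <- counts[focal]
  for (i in unique(fc)) {
    v <- lens[fc == i]
    mu[i] <- mean(v)
    if (length(v) >= 2L) sdv[i] <- stats::sd(v)
  }
  list(mu = mu, sd = sdv)
}

#' Among-population statistics
#'
#' Hudson's Fst estimator (`1 - Hw/Hb` as a ratio of sums over sites,
#' where `Hw` is the mean within-population and `Hb` the between-population
#' pairwise difference), the absolute divergence `Dxy` per bp, and the full
#' joint site frequency spectrum as percentages of the pooled segregating
#' sites on the `(n1+1) x (n2+1)` derived-count grid (the two
#' all-ancestral/all-derived corner cells are structurally zero).
#'
#' @param hap1,hap2 0/1 haplotype matrices of the two population samples at
#'   the same sites.
#' @param positions site coordinates.
#' @param locusLength locus length in bp.
#' @return list with `Fst`, `Dxy` and the `jsfs` percentage vector
#'   (row-major, population 1 count as the outer index).
#' @export
crossPopFeatures <- function(hap1, hap2, positions, locusLength) {
  n1 <- nrow(hap1); n2 <- nrow(hap2)
  stopifnot(n1 >= 2L, n2 >= 2L, ncol(hap1) == ncol(hap2))
  c1 <- colSums(hap1); c2 <- colSums(hap2)
  ct <- c1 + c2
  keep <- ct > 0L & ct < (n1 + n2)
  nc <- (n1 + 1L) * (n2 + 1L)
  jn <- sprintf("JSFS_%d_%d", rep(0:n1, each = n2 + 1L), rep(0:n2, n1 + 1L))
  if (!any(keep))
    return(list(Fst = NA_real_, Dxy = NA_real_,
                jsfs = stats::setNames(rep(NA_real_, nc), jn)))
  c1 <- c1[keep]; c2 <- c2[keep]
  p1 <- c1 / n1; p2 <- c2 / n2
  hw <- (2 * p1 * (1 - p1) * n1 / (n1 - 1) +
         2 * p2 * (1 - p2) * n2 / (n2 - 1)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  jsfs <- 100 * tabulate(c1 * (n2 + 1L) + c2 + 1L, nbins = nc) / sum(keep)
  list(Fst = 1 - sum(hw) / sum(hb),
       Dxy = sum(hb) / locusLength,
       jsfs = stats::setNames(jsfs, jn))
}

## ---- schema ----------------------------------------------------------------

.scopeSpec <- function(design) {
  nPop <- 2L * design@nDiploidPerPop
  nAll <- 4L * design@nDiploidPerPop
  list(p1 = list(n = nPop, hi = min(nPop, nAll - 1L)),
       p2 = list(n = nPop, hi = min(nPop, nAll - 1L)),
       all = list(n = nAll, hi = nAll - 1L))
}

.scopeBaseTable <- function(sc, spec, cfg) {
  nb <- length(cfg$ldEdges) - 1L
  nd <- length(cfg$decileProbs)
  mList <- .ibsMList(spec$n)
  hi <- spec$hi
  name <- c(sprintf("S_%s", sc), sprintf("D_%s", sc),
            sprintf("PI_mu_%s", sc), sprintf("PI_sd_%s", sc),
            sprintf("WinH_mu_%s", sc), sprintf("WinH_sd_%s", sc),
            sprintf("SFS_%d_%s", seq_len(hi), sc),
            sprintf("SFSgap_%d_%s", seq_len(hi), sc),
            sprintf("LD_mu_b%02d_%s", seq_len(nb), sc),
            sprintf("LD_sd_b%02d_%s", seq_len(nb), sc),
            sprintf("IBS_m%d_d%d_%s", rep(mList, each = nd),
                    rep(seq_len(nd), length(mList)), sc),
            sprintf("AFIBS_mu_%d_%s", seq_len(hi), sc),
            sprintf("AFIBS_sd_%d_%s", seq_len(hi), sc))
  cls <- c("S", "D", "PI", "PI", "WinH", "WinH",
           rep("SFS", 2L * hi), rep("LD", 2L * nb),
           rep("IBS", nd * length(mList)), rep("AFIBS", 2L * hi))
  data.frame(name = name, class = cls, scope = sc)
}

#' Build the feature schema for a sampling design
#'
#' Deterministically enumerates every aggregated feature name for a design:
#' the per-locus base statistics of the 11 classes over the three sample
#' scopes (population 1, population 2, pooled) plus the among-population
#' statistics, each crossed with the three cross-locus aggregators (mean,
#' median, variance).  Under the default configuration and the default
#' human-like design (10 diploids per population), the schema enumerates
#' exactly 3024 features.
#'
#' @param design a [SampleDesign-class].
#' @param config optional list overriding elements of the statistic
#'   configuration (window size, LD bin edges and pair cap, IBS subset
#'   count, decile probabilities, internal statistic seed).
#' @return a [FeatureSchema-class].
#' @examples
#' nFeatures(buildSchema(sampleDesign()))   # 3024
#' @export
buildSchema <- function(design, config = list()) {
  validObject(design)
  cfg <- utils::modifyList(.defaultStatConfig(), config)
  scopes <- .scopeSpec(design)
  tabs <- lapply(names(scopes), function(sc)
    .scopeBaseTable(sc, scopes[[sc]], cfg))
  n1 <- scopes$p1$n; n2 <- scopes$p2$n
  cross <- data.frame(
    name = c("Fst", "Dxy",
             sprintf("JSFS_%d_%d", rep(0:n1, each = n2 + 1L),
                     rep(0:n2, n1 + 1L))),
    class = c("Fst", "Dxy", rep("JSFS", (n1 + 1L) * (n2 + 1L))),
    scope = "cross")
  base <- do.call(rbind, c(tabs, list(cross)))
  aggs <- c("mean", "med", "var")
  featureNames <- paste(rep(base$name, each = 3L), aggs, sep = "_")
  new("FeatureSchema",
      baseNames = base$name,
      baseClasses = base$class,
      baseScopes = base$scope,
      featureNames = featureNames,
      design = design,
      config = cfg)
}

#' Stable fingerprint of a schema
#'
#' @param schema a [FeatureSchema-class].
#' @return character hash of the ordered feature names.
#' @export
schemaHash <- function(schema) hashStrings(featNames(schema))

## ---- per-locus vector and aggregation -------------------------------------

#' Compute the per-locus base statistic vector
#'
#' Runs every statistic class on population 1, population 2 and the pooled
#' sample (within-population classes use the sites segregating within the
#' scope; the frequency-indexed SFS and AFIBS classes additionally cover
#' counts up to fixation within a population, which remain attainable at
#' sites still segregating in the pooled sample) and the among-population
#' classes once, returning values aligned to `baseNames(schema)` with `NA`
#' for masked (undefined) entries.
#'
#' @param locus a [LocusData-class].
#' @param schema the [FeatureSchema-class] built for the matching design.
#' @return named numeric vector over `baseNames(schema)`.
#' @export
locusStatVector <- function(locus, schema) {
  cfg <- schema@config
  H <- locus@haplotypes
  pos <- locus@positions
  L <- locus@locusLength
  scopes <- .scopeSpec(schema@design)
  rows <- list(p1 = which(locus@popLabels == 1L),
               p2 = which(locus@popLabels == 2L),
               all = seq_len(nrow(H)))
  out <- stats::setNames(rep(NA_real_, length(schema@baseNames)),
                         schema@baseNames)
  for (sc in names(scopes)) {
    sp <- scopes[[sc]]
    Hs <- H[rows[[sc]], , drop = FALSE]
    counts <- colSums(Hs)
    seg <- counts > 0L & counts < sp$n
    Hseg <- Hs[, seg, drop = FALSE]
    posSeg <- pos[seg]

    cs <- classicStats(Hs, pos, L)
    out[sprintf("S_%s", sc)] <- cs$S
    out[sprintf("D_%s", sc)] <- cs$D
    out[sprintf("PI_mu_%s", sc)] <- cs$piMean
    out[sprintf("PI_sd_%s", sc)] <- cs$piSd

    wh <- windowHaploHet(Hseg, posSeg, L, cfg$windowSize)
    out[sprintf("WinH_mu_%s", sc)] <- wh$mean
    out[sprintf("WinH_sd_%s", sc)] <- wh$sd

    sf <- sfsFeatures(Hs, pos, maxCount = sp$hi)
    out[sprintf("SFS_%d_%s", seq_len(sp$hi), sc)] <- sf$pct
    out[sprintf("SFSgap_%d_%s", seq_len(sp$hi), sc)] <- sf$gapSd

    ld <- ldFeatures(Hseg, posSeg, cfg$ldEdges, cfg$ldMaxPairsPerBin,
                     seed = cfg$statSeed)
    nb <- length(cfg$ldEdges) - 1L
    out[sprintf("LD_mu_b%02d_%s", seq_len(nb), sc)] <- ld$mean
    out[sprintf("LD_sd_b%02d_%s", seq_len(nb), sc)] <- ld$sd

    mList <- .ibsMList(sp$n)
    ib <- ibsFeatures(Hseg, posSeg, L, mList = mList,
                      nSubsets = cfg$ibsNSubsets, seed = cfg$statSeed,
                      probs = cfg$decileProbs)
    nd <- length(cfg$decileProbs)
    out[sprintf("IBS_m%d_d%d_%s", rep(mList, each = nd),
                rep(seq_len(nd), length(mList)), sc)] <- as.vector(t(ib))

    af <- afibsFeatures(Hs, pos, L, minCount = 1L, maxCount = sp$hi)
    out[sprintf("AFIBS_mu_%d_%s", seq_len(sp$hi), sc)] <- af$mu
    out[sprintf("AFIBS_sd_%d_%s", seq_len(sp$hi), sc)] <- af$sd
  }
  cp <- crossPopFeatures(H[rows$p1, , drop = FALSE],
                         H[rows$p2, , drop = FALSE], pos, L)
  out["Fst"] <- cp$Fst
  out["Dxy"] <- cp$Dxy
  out[names(cp$jsfs)] <- cp$jsfs
  out
}

#' Aggregate per-locus statistics into the feature vector
#'
#' For every base statistic, computes the mean, median and sample variance
#' (n-1 denominator) across loci, ignoring masked entries.  Base statistics
#' masked in all loci (and variances undefined with a single observed
#' locus) are imputed with 0 after aggregation; the imputed feature names
#' are recorded in the `"imputed"` attribute.
#'
#' @param perLocus list of per-locus base vectors from [locusStatVector()].
#' @param schema the matching [FeatureSchema-class].
#' @return named numeric vector over `featNames(schema)`, free of
#'   non-finite values.
#' @export
aggregateFeatures <- function(perLocus, schema) {
  stopifnot(length(perLocus) >= 1L)
  M <- do.call(rbind, perLocus)
  stopifnot(identical(colnames(M), schema@baseNames))
  mu <- colMeans(M, na.rm = TRUE)
  med <- apply(M, 2L, stats::median, na.rm = TRUE)
  va <- apply(M, 2L, .sampleVar)
  out <- as.vector(rbind(mu, med, va))
  names(out) <- featNames(schema)
  bad <- !is.finite(out)
  out[bad] <- 0
  attr(out, "imputed") <- names(out)[bad]
  out
}
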