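# Independent brute-force implementations of every statistic class, used
# as oracles on tiny haplotype matrices.  All of them work by explicit
# enumeration (pairs, subsets, per-site scans) and share no code with the
# package implementations.

# per-site heterozygosity as the fraction of differing haplotype pairs
bfSiteHet <- function(hap) {
  n <- nrow(hap)
  pairs <- utils::combn(n, 2L)
  apply(hap, 2L, function(col) {
    diffs <- sum(col[pairs[1L, ]] != col[pairs[2L, ]])
    diffs / ncol(pairs)
  })
}

bfClassic <- function(hap, positions, L) {
  n <- nrow(hap)
  counts <- colSums(hap)
  seg <- counts > 0 & counts < n
  Sn <- sum(seg)
  if (Sn == 0) return(list(S = 0, D = NA_real_, piMean = NA_real_,
                           piSd = NA_real_))
  h <- bfSiteHet(hap[, seg, drop = FALSE])
  # Tajima (1989) with pi-hat from explicit pair enumeration
  pihat <- sum(h)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- (pihat - Sn / a1) / sqrt(e1 * Sn + e2 * Sn * (Sn - 1))
  list(S = Sn / L, D = D, piMean = mean(h),
       piSd = if (Sn >= 2) sd(h) else NA_real_)
}

bfWinH <- function(hap, positions, L, w = 5e4) {
  nw <- max(1, floor(L / w))
  H <- numeric(nw)
  for (k in seq_len(nw)) {
    idx <- which(positions >= (k - 1) * w & positions < k * w)
    if (!length(idx)) { H[k] <- 0; next }
    key <- apply(hap[, idx, drop = FALSE], 1L, paste, collapse = "/")
    f <- as.vector(table(key)) / nrow(hap)
    H[k] <- 1 - sum(f^2)
  }
  list(mean = mean(H), sd = if (nw >= 2) sd(H) else NA_real_)
}

bfSFS <- function(hap, positions, maxCount = nrow(hap) - 1L) {
  counts <- colSums(hap)
  pct <- rep(NA_real_, maxCount); gapSd <- rep(NA_real_, maxCount)
  qual <- which(counts >= 1 & counts <= maxCount)
  if (!length(qual)) return(list(pct = pct, gapSd = gapSd))
  for (i in seq_len(maxCount)) {
    pct[i] <- 100 * sum(counts[qual] == i) / length(qual)
    ps <- sort(positions[counts == i])
    if (length(ps) >= 3) gapSd[i] <- sd(diff(ps))
  }
  list(pct = pct, gapSd = gapSd)
}

# r^2 of one site pair from the explicit 2x2 haplotype table
bfR2pair <- function(a, b) {
  pA <- mean(a); pB <- mean(b); pAB <- mean(a == 1 & b == 1)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

bfLD <- function(hap, positions, edges) {
  n <- nrow(hap)
  counts <- colSums(hap)
  seg <- which(counts > 0 & counts < n)
  nb <- length(edges) - 1L
  mu <- rep(NA_real_, nb); sdv <- rep(NA_real_, nb)
  if (length(seg) < 2) return(list(mean = mu, sd = sdv))
  vals <- vector("list", nb)
  for (i in seq_along(seg)[-length(seg)]) {
    for (j in (i + 1):length(seg)) {
      d <- positions[seg[j]] - positions[seg[i]]
      b <- which(d >= edges[-length(edges)] & d < edges[-1L])
      if (length(b))
        vals[[b]] <- c(vals[[b]], bfR2pair(hap[, seg[i]], hap[, seg[j]]))
    }
  }
  for (b in seq_len(nb)) {
    if (length(vals[[b]]) >= 2) { mu[b] <- mean(vals[[b]]); sdv[b] <- sd(vals[[b]]) }
  }
  list(mean = mu, sd = sdv)
}

# exhaustive-subset IBS segment pool for one m
bfIBSPool <- function(hap, positions, L, m) {
  n <- nrow(hap)
  pool <- numeric()
  sub <- utils::combn(n, m)
  for (s in seq_len(ncol(sub))) {
    rows <- sub[, s]
    cs <- colSums(hap[rows, , drop = FALSE])
    bp <- positions[cs > 0 & cs < m]
    pool <- c(pool, diff(c(0, bp, L)))
  }
  pool
}

bfAFIBS <- function(hap, positions, L, minCount = 1L,
                    maxCount = nrow(hap) - 1L) {
  counts <- colSums(hap)
  mu <- rep(NA_real_, maxCount); sdv <- rep(NA_real_, maxCount)
  lens <- list()
  for (j in seq_along(counts)) {
    i <- counts[j]
    if (i < minCount || i > maxCount) next
    carriers <- which(hap[, j] == 1)
    lb <- 0; rb <- L
    if (i >= 2) {
      for (k in rev(seq_len(j - 1))) {
        v <- hap[carriers, k]
        if (length(unique(v)) > 1) { lb <- positions[k]; break }
      }
      for (k in seq(j + 1, length.out = length(counts) - j)) {
        v <- hap[carriers, k]
        if (length(unique(v)) > 1) { rb <- positions[k]; break }
      }
    }
    lens[[as.character(i)]] <- c(lens[[as.character(i)]], rb - lb)
  }
  for (i in names(lens)) {
    v <- lens[[i]]
    mu[as.integer(i)] <- mean(v)
    if (length(v) >= 2) sdv[as.integer(i)] <- sd(v)
  }
  list(mu = mu, sd = sdv)
}

# Hudson's Fst and Dxy from explicit haplotype-pair difference counts
bfCross <- function(hap1, hap2, positions, L) {
  n1 <- nrow(hap1); n2 <- nrow(hap2)
  ct <- colSums(hap1) + colSums(hap2)
  keep <- ct > 0 & ct < (n1 + n2)
  h1 <- hap1[, keep, drop = FALSE]; h2 <- hap2[, keep, drop = FALSE]
  pairDiff <- function(a, b) sum(a != b)
  hw <- 0
  for (pop in list(h1, h2)) {
    n <- nrow(pop); tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      tot <- tot + pairDiff(pop[i, ], pop[j, ])
    hw <- hw + tot / choose(n, 2) / 2
  }
  hb <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2))
    hb <- hb + pairDiff(h1[i, ], h2[j, ])
  hb <- hb / (n1 * n2)
  jsfs <- matrix(0, n1 + 1, n2 + 1)
  for (s in which(keep)) {
    c1 <- sum(hap1[, s]); c2 <- sum(hap2[, s])
    jsfs[c1 + 1, c2 + 1] <- jsfs[c1 + 1, c2 + 1] + 1
  }
  list(Fst = if (any(keep)) 1 - hw / hb else NA_real_,
       Dxy = if (any(keep)) hb / L else NA_real_,
       jsfs = if (any(keep)) 100 * jsfs / sum(keep) else jsfs * NA)
}

# random tiny haplotype matrix with all pooled-segregating sites
randomTinyLocus <- function(nHap = 6L, nSites = 8L, L = 10000, seed = 1L) {
  set.seed(seed)
  repeat {
    H <- matrix(rbinom(nHap * nSites, 1L, runif(1, 0.2, 0.8)), nrow = nHap)
    cs <- colSums(H)
    keep <- cs > 0 & cs < nHap
    if (sum(keep) >= 2) {
      H <- H[, keep, drop = FALSE]
      pos <- sort(sample(seq_len(L - 1), ncol(H)))
      return(list(H = H, pos = as.numeric(pos), L = L))
    }
  }
}
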