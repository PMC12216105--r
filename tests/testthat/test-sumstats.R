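test_that("classic statistics match hand-derived values", {
  # 4 haplotypes, 2 sites with derived counts {1, 2}, L = 1000
  H <- rbind(c(1L, 1L), c(0L, 1L), c(0L, 0L), c(0L, 0L))
  cs <- classicStats(H, c(100, 600), 1000)
  expect_equal(cs$S, 0.002)
  expect_equal(cs$piMean, mean(c(0.5, 2 / 3)))  # h = {1/2, 2/3}
  # Tajima (1989) constants for n = 4, S = 2, pi-hat = 7/6,
  # evaluated by hand: D = 0.075758 / sqrt(0.016400...) = 0.5916
  expect_equal(cs$D, 0.59, tolerance = 0.005)
  bf <- bfClassic(H, c(100, 600), 1000)
  expect_equal(cs$D, bf$D, tolerance = 1e-12)

  mono <- matrix(0L, nrow = 4, ncol = 0)
  cs0 <- classicStats(mono, numeric(), 1000)
  expect_equal(cs0$S, 0)
  expect_true(is.na(cs0$D))
})

test_that("windowed haplotypic heterozygosity handles tiling and degeneracy", {
  # all four haplotypes pairwise distinct in the window -> H = 0.75
  H <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  wh <- windowHaploHet(H, c(100, 200), 5e4, windowSize = 5e4)
  expect_equal(wh$mean, 0.75)
  # a locus of 100 kb tiles into exactly two 50 kb windows; SNPs only in
  # the first -> second window has H = 0
  wh2 <- windowHaploHet(H, c(100, 200), 1e5, windowSize = 5e4)
  expect_equal(wh2$mean, 0.75 / 2)
  # no SNPs at all -> all haplotypes identical, H = 0 everywhere
  wh3 <- windowHaploHet(matrix(0L, 4, 0), numeric(), 1e5)
  expect_equal(wh3$mean, 0)
})

test_that("SFS features normalize and measure adjacent-SNP gaps", {
  # single singleton among 20 haplotypes
  H <- matrix(0L, nrow = 20, ncol = 1); H[1, 1] <- 1L
  sf <- sfsFeatures(H, 5000)
  expect_equal(sf$pct[1L], 100)
  expect_equal(sum(sf$pct, na.rm = TRUE), 100)
  expect_true(all(is.na(sf$gapSd)))

  # three doubleton sites at {100, 300, 700}: gaps {200, 400}
  H2 <- matrix(0L, nrow = 4, ncol = 3); H2[1:2, ] <- 1L
  sf2 <- sfsFeatures(H2, c(100, 300, 700))
  expect_equal(sf2$gapSd[2L], sd(c(200, 400)))
  expect_equal(sf2$pct[2L], 100)

  expect_true(all(is.na(sfsFeatures(matrix(0L, 4, 0), numeric())$pct)))
})

test_that("LD r-squared reproduces the textbook cases", {
  edges <- c(0, 1e6)
  # identical columns -> perfect LD
  a <- c(1L, 1L, 0L, 0L)
  H <- cbind(a, a)
  ld <- ldFeatures(H, c(10, 500), edges)
  expect_equal(ld$mean[1L], NA_real_)  # single pair: masked by design
  H3 <- cbind(a, a, a)
  ld3 <- ldFeatures(H3, c(10, 500, 900), edges)
  expect_equal(ld3$mean[1L], 1)
  expect_equal(ld3$sd[1L], 0)
  # exact linkage equilibrium: p_AB = p_A p_B
  b <- c(1L, 0L, 1L, 0L)
  Hle <- cbind(a, b, a, b)
  ldle <- ldFeatures(Hle, c(10, 400, 700, 950), edges)
  expect_equal(ldle$mean[1L], mean(c(0, 1, 0, 0, 1, 0)))  # brute force

  # three sites in one bin: mean/sd over the three pairwise r2 values
  tiny <- randomTinyLocus(nHap = 6, nSites = 3, seed = 42)
  got <- ldFeatures(tiny$H, tiny$pos, c(0, tiny$L))
  bf <- bfLD(tiny$H, tiny$pos, c(0, tiny$L))
  expect_equal(got$mean, bf$mean, tolerance = 1e-12)
  expect_equal(got$sd, bf$sd, tolerance = 1e-12)
})

test_that("IBS segment deciles follow the partition arithmetic", {
  # two haplotypes differing at {1000, 5000} on a 10 kb locus:
  # segments {1000, 4000, 5000}
  H <- rbind(c(1L, 1L), c(0L, 0L))
  ib <- ibsFeatures(H, c(1000, 5000), 1e4, mList = 2L)
  expect_equal(as.vector(ib), quantile(c(1000, 4000, 5000), 1:9 / 10,
                                       names = FALSE))
  expect_true(all(diff(as.vector(ib)) >= 0))  # decile monotonicity

  # subset with zero internal differences -> single segment of length L
  H0 <- rbind(rep(1L, 3), rep(1L, 3), c(0L, 1L, 0L), c(1L, 0L, 1L))
  ib0 <- ibsFeatures(H0[1:2, , drop = FALSE], c(10, 20, 30), 1e4,
                     mList = 2L)
  expect_true(all(ib0 == 1e4))

  expect_error(ibsFeatures(H, c(1000, 5000), 1e4, mList = 4L),
               "exceeds")
})

test_that("AFIBS segments scan to the nearest interrupting site", {
  # focal SNP at 5000 carried by haplotypes 1-2, which differ at 2000 and
  # 8000: segment length 8000 - 2000 = 6000
  H <- rbind(c(1L, 1L, 0L), c(0L, 1L, 1L), c(0L, 0L, 0L), c(0L, 0L, 0L))
  af <- afibsFeatures(H, c(2000, 5000, 8000), 1e4)
  expect_equal(af$mu[2L], 6000)
  expect_equal(af$mu[1L], 1e4)   # singleton segments span the locus
  # single SNP whose carriers are identical elsewhere -> whole locus
  H1 <- rbind(c(1L), c(1L), c(0L), c(0L))
  af1 <- afibsFeatures(H1, 5000, 1e4)
  expect_equal(af1$mu[2L], 1e4)
})

test_that("cross-population statistics capture differentiation", {
  # every site fixed derived in pop1 and absent in pop2 -> Fst = 1
  h1 <- matrix(1L, nrow = 4, ncol = 3)
  h2 <- matrix(0L, nrow = 4, ncol = 3)
  cp <- crossPopFeatures(h1, h2, c(10, 20, 30), 1e4)
  expect_equal(cp$Fst, 1)
  expect_equal(cp$jsfs[["JSFS_4_0"]], 100)
  expect_equal(sum(cp$jsfs), 100)

  # single derived copy in pop1
  h1b <- matrix(0L, 4, 1); h1b[1, 1] <- 1L
  cpb <- crossPopFeatures(h1b, matrix(0L, 4, 1), 50, 1e4)
  expect_equal(cpb$jsfs[["JSFS_1_0"]], 100)
  expect_equal(sum(cpb$jsfs == 0), length(cpb$jsfs) - 1L)
})

test_that("every statistic class matches brute force on random tiny matrices", {
  for (case in 1:20) {
    tiny <- randomTinyLocus(nHap = 6, nSites = 8, seed = 1000 + case)
    H <- tiny$H; pos <- tiny$pos; L <- tiny$L

    expect_equal(classicStats(H, pos, L), bfClassic(H, pos, L),
                 tolerance = 1e-9)
    expect_equal(windowHaploHet(H, pos, L, windowSize = 2500),
                 bfWinH(H, pos, L, w = 2500), tolerance = 1e-9)
    expect_equal(sfsFeatures(H, pos), bfSFS(H, pos), tolerance = 1e-9)

    edges <- c(0, 1000, 3000, L)
    expect_equal(ldFeatures(H, pos, edges), bfLD(H, pos, edges),
                 tolerance = 1e-9)

    for (m in c(2L, 4L)) {
      got <- ibsFeatures(H, pos, L, mList = m, nSubsets = 1000L)
      expect_equal(as.vector(got),
                   quantile(bfIBSPool(H, pos, L, m), 1:9 / 10,
                            names = FALSE),
                   tolerance = 1e-9)
    }

    expect_equal(afibsFeatures(H, pos, L), bfAFIBS(H, pos, L),
                 tolerance = 1e-9)

    n1 <- 3L
    got <- crossPopFeatures(H[1:n1, , drop = FALSE],
                            H[(n1 + 1):6, , drop = FALSE], pos, L)
    bf <- bfCross(H[1:n1, , drop = FALSE], H[(n1 + 1):6, , drop = FALSE],
                  pos, L)
    expect_equal(got$Fst, bf$Fst, tolerance = 1e-9)
    expect_equal(got$Dxy, bf$Dxy, tolerance = 1e-9)
    expect_equal(unname(got$jsfs), as.vector(t(bf$jsfs)), tolerance = 1e-9)
  }
})

test_that("statistics are invariant to haplotype row order within populations", {
  ld <- fixtureLoci()[[1L]]
  sch <- fixtureSchema()
  v1 <- locusStatVector(ld, sch)
  set.seed(9)
  perm <- c(sample(1:8), sample(9:16))
  ld2 <- locusData(haplotypes(ld)[perm, ], positions(ld),
                   popLabels(ld), ld@locusLength)
  v2 <- locusStatVector(ld2, sch)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("per-locus vectors satisfy the range invariants", {
  sch <- fixtureSchema()
  for (ld in fixtureLoci()) {
    v <- locusStatVector(ld, sch)
    L <- ld@locusLength
    pick <- function(re) v[grepl(re, names(v))]
    expect_true(all(pick("^LD_mu_") >= -1e-12 & pick("^LD_mu_") <= 1 + 1e-12,
                    na.rm = TRUE))
    expect_true(all(pick("^WinH_mu_") >= 0 & pick("^WinH_mu_") <= 1,
                    na.rm = TRUE))
    expect_true(all(pick("^PI_mu_") >= 0 & pick("^PI_mu_") <= 1, na.rm = TRUE))
    expect_true(all(pick("^IBS_") > 0 & pick("^IBS_") <= L, na.rm = TRUE))
    expect_true(all(pick("^AFIBS_mu_") > 0 & pick("^AFIBS_mu_") <= L,
                    na.rm = TRUE))
    expect_lte(v[["Fst"]], 1)
    expect_gte(v[["Dxy"]], 0)
    for (sc in c("p1", "p2", "all")) {
      pct <- v[grepl(sprintf("^SFS_[0-9]+_%s$", sc), names(v))]
      if (!all(is.na(pct)))
        expect_equal(sum(pct, na.rm = TRUE), 100, tolerance = 1e-9)
    }
    expect_equal(sum(v[grepl("^JSFS_", names(v))], na.rm = TRUE), 100,
                 tolerance = 1e-9)
  }
})

test_that("cross-locus aggregation computes mean, median and variance", {
  sch <- fixtureSchema()
  nb <- length(baseNames(sch))
  mk <- function(x) setNames(rep(x, nb), baseNames(sch))
  fv <- aggregateFeatures(list(mk(1), mk(2), mk(4)), sch)
  expect_equal(unname(fv[paste0(baseNames(sch)[1], "_mean")]), 7 / 3)
  expect_equal(unname(fv[paste0(baseNames(sch)[1], "_med")]), 2)
  expect_equal(unname(fv[paste0(baseNames(sch)[1], "_var")]), 7 / 3)

  # identical loci: zero variance, mean = median = value
  fv2 <- aggregateFeatures(list(mk(3), mk(3)), sch)
  expect_equal(unname(fv2[paste0(baseNames(sch)[2], "_var")]), 0)

  # one masked locus drops out of the aggregation
  a <- mk(1); b <- mk(2); cvec <- mk(4)
  a[5] <- NA
  fv3 <- aggregateFeatures(list(a, b, cvec), sch)
  expect_equal(unname(fv3[paste0(baseNames(sch)[5], "_mean")]), 3)
  # fully masked statistics are imputed with zero
  a[7] <- b[7] <- cvec[7] <- NA
  fv4 <- aggregateFeatures(list(a, b, cvec), sch)
  expect_equal(unname(fv4[paste0(baseNames(sch)[7], "_mean")]), 0)
  expect_true(paste0(baseNames(sch)[7], "_mean") %in% attr(fv4, "imputed"))
})

test_that("the schema enumerates the full statistic layout", {
  sch <- buildSchema(sampleDesign())   # 10 diploids/pop, 20 x 2 Mb loci
  expect_equal(nFeatures(sch), 3024L)

  # enumeration rule, recomputed independently for any design
  expected <- function(nDip) {
    nPop <- 2 * nDip; nAll <- 4 * nDip
    perScope <- function(n, hi) 6 + 2 * 19 + 9 * floor(log2(n)) + 4 * hi
    base <- perScope(nPop, min(nPop, nAll - 1)) * 2 +
      perScope(nAll, nAll - 1) + 2 + (nPop + 1)^2
    3 * base
  }
  expect_equal(nFeatures(sch), expected(10L))
  fx <- buildSchema(sampleDesign(nDiploidPerPop = 4L, nLoci = 2L,
                                 locusLength = 1e5))
  expect_equal(nFeatures(fx), expected(4L))

  # deterministic: two invocations agree name for name
  expect_identical(featNames(buildSchema(sampleDesign())), featNames(sch))
  expect_false(anyDuplicated(featNames(sch)) > 0)
  expect_equal(sort(unique(sch@baseClasses)),
               sort(c("S", "D", "PI", "WinH", "SFS", "LD", "IBS", "AFIBS",
                      "Fst", "Dxy", "JSFS")))
})
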