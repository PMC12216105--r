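test_that("default priors match the study design for both models", {
  im <- defaultPriors("IM")
  expect_equal(im$low[im$name == "migration_rate"], 0)
  expect_equal(im$high[im$name == "migration_rate"], 0.001)
  expect_equal(im$low[im$name == "split_time"], 1)
  expect_equal(im$high[im$name == "split_time"], 5000)
  expect_equal(im$high[im$name == "n_ancestral"], 10000)

  sc <- defaultPriors("SC")
  expect_equal(sc$low[sc$name == "growth_rate_1"], -0.001)
  expect_equal(sc$high[sc$name == "growth_rate_1"], 0.002)
  expect_equal(sc$low[sc$name == "split_time"], 100)
  expect_equal(sc$high[sc$name == "migration_rate"], 0.005)
  expect_equal(sc$low[sc$name == "migration_duration"], 0)
  expect_equal(sc$high[sc$name == "migration_duration"], 1)

  expect_error(defaultPriors("XX"))
})

test_that("parameter sampling respects bounds, moments and determinism", {
  pr <- defaultPriors("IM")
  draws <- sampleParameters(pr, 10000L, seed = 11L, model = "IM")
  for (i in seq_len(nrow(pr))) {
    v <- draws[[pr$name[i]]]
    expect_true(all(v >= pr$low[i] & v <= pr$high[i]))
  }
  # uniform mean check: U[1,5000] has mean 2500.5, sd (5000-1)/sqrt(12)
  se <- (5000 - 1) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(draws$split_time) - 2500.5), 3 * se)

  expect_identical(sampleParameters(pr, 50L, seed = 7L, model = "IM"),
                   sampleParameters(pr, 50L, seed = 7L, model = "IM"))

  degenerate <- data.frame(name = pr$name, low = 5, high = 5)
  dd <- sampleParameters(degenerate, 3L, seed = 1L, model = "IM")
  expect_true(all(as.matrix(dd) == 5))
})

test_that("SC sampling rejects draws that shrink a population below one diploid", {
  pr <- defaultPriors("SC")
  draws <- sampleParameters(pr, 2000L, seed = 3L, model = "SC")
  s1 <- draws$n_current_1 * exp(-draws$growth_rate_1 * draws$split_time)
  s2 <- draws$n_current_2 * exp(-draws$growth_rate_2 * draws$split_time)
  expect_true(all(s1 >= 1 & s2 >= 1))
  expect_gte(attr(draws, "nRejected"), 0L)

  impossible <- data.frame(
    name = pr$name,
    low  = c(5000, 0, 1000, 1000, 1000, 0.002, 0.002, 0),
    high = c(5000, 0, 1000, 1000, 1000, 0.002, 0.002, 1))
  expect_error(sampleParameters(impossible, 5L, seed = 1L, model = "SC"),
               "below 1 diploid")
})

test_that("demography events encode the models' structure", {
  imp <- c(split_time = 1000, migration_rate = 0, n_ancestral = 5000,
           n_current_1 = 2000, n_current_2 = 3000)
  ev <- toDemographyEvents(imp, "IM")
  expect_equal(ev@splitTime, 1000)
  expect_equal(ev@growthRates, c(0, 0))
  # zero-rate migration window is equivalent to no migration
  expect_true(nrow(ev@migrationWindows) == 0 ||
              all(ev@migrationWindows$rate == 0))

  scp <- c(split_time = 1000, migration_rate = 2e-3, n_ancestral = 3000,
           n_current_1 = 2000, n_current_2 = 3000, growth_rate_1 = 0,
           growth_rate_2 = 0, migration_duration = 0.25)
  ev2 <- toDemographyEvents(scp, "SC")
  expect_equal(ev2@migrationWindows$start, 0)
  expect_equal(ev2@migrationWindows$end, 250)  # most recent quarter
  # growth rate 0 keeps the population constant
  expect_equal(populationSizeAt(ev2, 1L, c(0, 500, 999)), rep(2000, 3))

  expect_error(toDemographyEvents(imp[-1], "IM"), "missing parameter")
})

test_that("SC with zero growth and full migration duration reproduces IM", {
  shared <- c(split_time = 1234, migration_rate = 5e-4, n_ancestral = 4000,
              n_current_1 = 1500, n_current_2 = 2500)
  im <- toDemographyEvents(shared, "IM")
  sc <- toDemographyEvents(c(shared, growth_rate_1 = 0, growth_rate_2 = 0,
                             migration_duration = 1), "SC")
  expect_equal(im, sc)
})

test_that("backward-time size follows the exponential convention", {
  scp <- c(split_time = 2000, migration_rate = 0, n_ancestral = 3000,
           n_current_1 = 4000, n_current_2 = 1200, growth_rate_1 = 0.0015,
           growth_rate_2 = -5e-4, migration_duration = 0.5)
  ev <- toDemographyEvents(scp, "SC")
  expect_equal(populationSizeAt(ev, 1L, 2000), 4000 * exp(-0.0015 * 2000),
               tolerance = 1e-9)
  expect_equal(populationSizeAt(ev, 2L, 2000), 1200 * exp(5e-4 * 2000),
               tolerance = 1e-9)
  # beyond the split the ancestral size applies
  expect_equal(populationSizeAt(ev, 1L, 2500), 3000)
})
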