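test_that("percent input RFU is the post/pre ratio times 100", {
  expect_equal(percentInputRFU(2500, 1000), 40)
  expect_equal(percentInputRFU(1234.5, 1234.5), 100)
  expect_equal(percentInputRFU(800, 0), 0)
  expect_error(percentInputRFU(0, 10), "positive")
})

test_that("noiseless 4PL data are recovered to machine-level accuracy", {
  a <- 100; d <- 5000; cc <- 2e4; b <- 1.5
  x <- c(250, 700, 2000, 6000, 2e4, 6e4, 1.5e5, 4e5)
  fit <- fitFourPL(x, fourPLRef(x, a, d, cc, b))
  cf <- curveCoef(fit)
  expect_equal(unname(cf), c(a, d, cc, b), tolerance = 1e-6)
  expect_lt(fit@residualSD, 1e-6 * d)
  # midpoint symmetry: f(c) = (a + d) / 2
  expect_equal(evalFourPL(fit, cf[["c"]]), (cf[["a"]] + cf[["d"]]) / 2)
})

test_that("4PL fit refuses underdetermined designs", {
  x <- c(100, 100, 1000, 1000)
  expect_error(fitFourPL(x, fourPLRef(x, 10, 100, 500, 1)), "4 distinct")
})

test_that("noisy 4PL fits recover parameters within sampling error", {
  set.seed(88)
  a <- 150; d <- 65000; cc <- 25000; b <- 1.3
  x <- round(exp(seq(log(500), log(80000), length.out = 8)))
  rel <- replicate(60, {
    y <- fourPLRef(x, a, d, cc, b) * exp(rnorm(8, 0, 0.02))
    cf <- curveCoef(fitFourPL(x, y))
    (cf[["c"]] - cc) / cc
  })
  # unbiased inflection recovery at 2% multiplicative noise
  expect_lt(abs(mean(rel)), 2.5 * sd(rel) / sqrt(length(rel)) + 0.01)
})

test_that("4PL inversion is the exact algebraic preimage", {
  crv <- toyCurve()
  cf <- curveCoef(crv)
  expect_equal(invertFourPL(crv, (cf[["a"]] + cf[["d"]]) / 2), cf[["c"]],
               tolerance = 1e-9)
  expect_equal(invertFourPL(crv, evalFourPL(crv, 12345)), 12345,
               tolerance = 1e-6)
  expect_error(invertFourPL(crv, cf[["d"]]), "asymptote")
  expect_error(invertFourPL(crv, cf[["a"]] - 1), "asymptote")
})

test_that("inversion inverts evaluation over random valid parameter sets", {
  set.seed(19)
  for (i in 1:30) {
    a <- runif(1, 0, 500); d <- runif(1, 2000, 9e4)
    cc <- runif(1, 1e3, 5e4); b <- runif(1, 0.5, 3)
    if (runif(1) < 0.3) b <- -b   # decreasing curves invert too
    crv <- new("FourPLCurve", a = a, d = d, c = cc, b = b,
               residualSD = 0, nPoints = 0L)
    x <- exp(runif(5, log(10), log(2e5)))
    expect_equal(invertFourPL(crv, evalFourPL(crv, x)), x,
                 tolerance = 1e-6)
  }
})

test_that("percent adherent reproduces the control working range", {
  crv <- toyCurve()
  # positive-control-like: RFU at 17,500 cells, 50,000 loaded -> 35%
  expect_equal(percentAdherent(crv, evalFourPL(crv, 17500), 50000), 35,
               tolerance = 1e-6)
  # negative-control-like: RFU at 2,500 cells -> 5%
  expect_equal(percentAdherent(crv, evalFourPL(crv, 2500), 50000), 5,
               tolerance = 1e-6)
  expect_equal(percentAdherent(crv, evalFourPL(crv, 50000), 50000), 100,
               tolerance = 1e-6)
})

test_that("standardization to the positive control is a plain ratio", {
  expect_equal(standardizeToControl(35, 35), 1)
  expect_equal(standardizeToControl(22.4, 35), 0.64)
  r <- standardizeToControl(c(20, 25, 30), 35)
  expect_true(all(diff(r) > 0))
  expect_error(standardizeToControl(10, 0), "positive")
})

test_that("cross-plate ANOVA is calibrated under the null and powered under shift", {
  set.seed(5150)
  # null: identical plate means -> uniform p over replications
  ps <- replicate(200, {
    crossPlateConsistency(rnorm(24, 0.65, 0.05),
                          rep(c("P1", "P2", "P3"), each = 8))$p
  })
  rej <- mean(ps < 0.05)
  expect_gt(rej, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200) - 1e-9)
  expect_lt(rej, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200) + 0.02)
  expect_gt(mean(ps), 0.40)  # uniform mean 0.5
  # 5-sd mean shift between two plates -> decisive rejection
  shifted <- crossPlateConsistency(
    c(rnorm(8, 0.65, 0.05), rnorm(8, 0.65 + 5 * 0.05, 0.05)),
    rep(c("P1", "P2"), each = 8))
  expect_lt(shifted$p, 0.01)
  # degenerate cases are flagged, never forced
  expect_true(is.na(crossPlateConsistency(rnorm(8), rep("P1", 8))$p))
  expect_match(crossPlateConsistency(rep(1, 8),
                                     rep(c("P1", "P2"), each = 4))$note,
               "degenerate")
})

test_that("quantification recovers phenotypes and cancels plate gain", {
  cfg <- GenerativeConfig(nMZPairs = 3, nSIBPairs = 3, seed = 21)
  sim <- simulatePairPhenotypes(cfg)
  # noiseless, unit-gain generator: % input RFU equals the phenotype
  cfg0 <- GenerativeConfig(nMZPairs = 3, nSIBPairs = 3, seed = 21,
                           replicateCV = 1e-9)
  pl0 <- simulatePlateReadings(sim$samples, cfg0)
  phen0 <- quantifyAdhesion(pl0$readings)
  truth <- setNames(sim$samples$phenotype, sim$samples$sample_id)
  expect_equal(phen0$pct_input_rfu_mean, unname(truth[phen0$sample_id]),
               tolerance = 1e-6)

  # plate gain 2.0 doubles raw RFU but leaves standardized coefficients
  plG <- simulatePlateReadings(sim$samples,
                               GenerativeConfig(nMZPairs = 3, nSIBPairs = 3,
                                                seed = 21, replicateCV = 1e-9,
                                                plateGain = 2))
  expect_equal(readings(plG$readings)$rfu[1],
               2 * readings(pl0$readings)$rfu[1])
  phenG <- quantifyAdhesion(plG$readings)
  expect_equal(phenG$standardized_coefficient, phen0$standardized_coefficient,
               tolerance = 1e-9)
})

test_that("phenotypes are invariant to a common RFU gain with a refit curve", {
  cfg <- GenerativeConfig(nMZPairs = 3, nSIBPairs = 3, seed = 33)
  sim <- simulatePairPhenotypes(cfg)
  pl <- simulatePlateReadings(sim$samples, cfg)
  phen1 <- quantifyAdhesion(pl$readings)
  df <- readings(pl$readings)
  df$rfu <- df$rfu * 3.7
  phen2 <- quantifyAdhesion(new("PlateReadingSet", readings = df))
  expect_equal(phen2$pct_input_rfu_mean, phen1$pct_input_rfu_mean)
  expect_equal(phen2$pct_adherent_mean, phen1$pct_adherent_mean,
               tolerance = 1e-4)
})
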