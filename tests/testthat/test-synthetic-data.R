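test_that("generator config enforces the variance budget", {
  expect_error(GenerativeConfig(h2 = 0.8, c2 = 0.3), "exceed 1")
  expect_error(GenerativeConfig(phenotypeSD = 0), "positive")
  cfg <- GenerativeConfig()
  expect_equal(cfg@nMZPairs, 23L)
  expect_equal(cfg@nSIBPairs, 23L)
})

test_that("implied pair correlations follow the additive model", {
  # r_MZ = h2 + c2, r_SIB = h2/2 + c2, at several architecture points
  for (pars in list(c(0.7, 0.1, 1L), c(0.4, 0.3, 2L), c(0, 0, 3L))) {
    sim <- simulatePairPhenotypes(
      GenerativeConfig(nMZPairs = 20000, nSIBPairs = 20000,
                       h2 = pars[1], c2 = pars[2], seed = pars[3]))
    mz <- sim$pairs[sim$pairs$zygosity == "MZ", ]
    sib <- sim$pairs[sim$pairs$zygosity == "SIB", ]
    tol <- 3 / sqrt(20000) + 0.005
    expect_lt(abs(cor(mz$y_a, mz$y_b) - (pars[1] + pars[2])), tol)
    expect_lt(abs(cor(sib$y_a, sib$y_b) - (pars[1] / 2 + pars[2])), tol)
  }
})

test_that("degenerate architectures behave as limits", {
  sim0 <- simulatePairPhenotypes(GenerativeConfig(nMZPairs = 5000,
                                                  nSIBPairs = 5000,
                                                  h2 = 0, c2 = 0, seed = 4))
  mz <- sim0$pairs[sim0$pairs$zygosity == "MZ", ]
  expect_lt(abs(cor(mz$y_a, mz$y_b)), 0.05)
  # h2 = 1: monozygotic members are identical
  sim1 <- simulatePairPhenotypes(GenerativeConfig(nMZPairs = 50,
                                                  nSIBPairs = 50,
                                                  h2 = 1, c2 = 0, seed = 5))
  mz1 <- sim1$pairs[sim1$pairs$zygosity == "MZ", ]
  expect_equal(mz1$y_a, mz1$y_b, tolerance = 1e-12)
})

test_that("phenotype scale and clipping match the study conditions", {
  sim <- simulatePairPhenotypes(GenerativeConfig(nMZPairs = 5000,
                                                 nSIBPairs = 5000, seed = 6))
  expect_lt(sim$clipRate, 0.001)
  expect_equal(mean(sim$samples$phenotype), 40.25, tolerance = 0.02)
  expect_equal(sd(sim$samples$phenotype), 10.37, tolerance = 0.05)
})

test_that("covariates are independent of phenotype unless injected", {
  sim <- simulatePairPhenotypes(GenerativeConfig(nMZPairs = 1000,
                                                 nSIBPairs = 1000, seed = 2))
  expect_gt(cor.test(sim$samples$phenotype, sim$samples$age)$p.value, 1e-4)
  inj <- simulatePairPhenotypes(GenerativeConfig(nMZPairs = 1000,
                                                 nSIBPairs = 1000, seed = 2),
                                injectConfounder = c(age = 8))
  expect_lt(cor.test(inj$samples$phenotype, inj$samples$age)$p.value, 1e-6)
})

test_that("plate simulation paginates, controls every plate, seeds deterministically", {
  cfg <- GenerativeConfig(seed = 30)
  sim <- simulatePairPhenotypes(cfg)
  pl <- simulatePlateReadings(sim$samples, cfg)
  df <- readings(pl$readings)
  # 92 samples at 8 reps with per-plate controls never drop a sample
  expect_setequal(unique(df$sample_id[df$role == "test"]),
                  sim$samples$sample_id)
  for (pid in unique(df$plate_id)) {
    p <- df[df$plate_id == pid, ]
    expect_gte(sum(p$role == "positive_control" &
                     p$read_stage == "wash3"), 8)
    expect_gte(sum(p$role == "negative_control" &
                     p$read_stage == "wash3"), 8)
    expect_gte(length(unique(p$known_cells[p$role == "standard_curve"])), 4)
  }
  reps <- table(df$sample_id[df$role == "test" & df$read_stage == "wash3"])
  expect_true(all(reps == 8))
  pl2 <- simulatePlateReadings(sim$samples, cfg)
  expect_identical(readings(pl2$readings), df)
})

test_that("the default assay realization hits its QC targets end to end", {
  cfg <- GenerativeConfig(seed = 1)
  sim <- simulatePairPhenotypes(cfg)
  pl <- simulatePlateReadings(sim$samples, cfg)
  phen <- quantifyAdhesion(pl$readings)
  # pipeline-recomputed replicate CV sits at the generative 8.68%
  expect_equal(mean(phen$pct_input_rfu_cv), 8.68, tolerance = 0.08)
  qc <- plateQC(pl$readings)
  expect_gt(qc$composite, 0.5)
  expect_lt(qc$composite, 0.9)
})

test_that("fixture studies re-read cleanly and carry their ground truth", {
  cfg <- GenerativeConfig(nMZPairs = 4, nSIBPairs = 4, seed = 77)
  dir <- tempfile()
  paths <- makeFixtureStudy(cfg, dir)
  expect_true(all(file.exists(paths)))
  rds <- readPlateReadings(paths[["readings"]])
  lay <- readPlateLayouts(paths[["layouts"]])
  man <- readPairManifest(paths[["pairs"]])
  expect_true(validateStudy(rds, lay, man)@ok)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$h2, cfg@h2)
  expect_equal(truth$r_mz_implied, cfg@h2 + cfg@c2)
  std <- readStandardCurve(paths[["curves"]])
  expect_gte(nrow(std), 8)
  # same seed -> byte-identical files
  dir2 <- tempfile()
  paths2 <- makeFixtureStudy(cfg, dir2)
  for (k in names(paths))
    expect_identical(readLines(paths2[[k]]), readLines(paths[[k]]))
})
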