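test_that("ICC handles concordance, exchangeability and degeneracy", {
  expect_equal(intraclassCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(14)
  pr <- rPairs(40, rho = 0.5)
  icc1 <- intraclassCorrelation(pr$y_a, pr$y_b)
  # swapping members within random pairs changes nothing
  swap <- runif(40) < 0.5
  a2 <- ifelse(swap, pr$y_b, pr$y_a); b2 <- ifelse(swap, pr$y_a, pr$y_b)
  expect_identical(icc1, intraclassCorrelation(a2, b2))
  expect_gte(icc1, -1); expect_lte(icc1, 1)
  expect_error(intraclassCorrelation(rep(2, 5), rep(2, 5)), "zero total")
  expect_error(intraclassCorrelation(c(1, 2), c(1, 2)), ">= 3 pairs")
})

test_that("ICC agrees with the one-way ANOVA oracle and the generative rho", {
  set.seed(99)
  pr <- rPairs(200, rho = 0.6)
  # independent oracle: literal one-way random-effects ANOVA via aov()
  long <- data.frame(y = c(pr$y_a, pr$y_b),
                     pair = factor(rep(seq_len(200), 2)))
  ms <- summary(aov(y ~ pair, data = long))[[1]][["Mean Sq"]]
  oracle <- (ms[1] - ms[2]) / (ms[1] + ms[2])
  expect_equal(intraclassCorrelation(pr$y_a, pr$y_b), oracle,
               tolerance = 1e-12)
  # large-sample recovery of the true intra-pair correlation 0.60
  set.seed(100)
  big <- rPairs(10000, rho = 0.6)
  expect_equal(intraclassCorrelation(big$y_a, big$y_b), 0.6,
               tolerance = 0.03)
})

test_that("double-entry Pearson is symmetric and tracks the ICC", {
  expect_equal(pearsonDoubleEntry(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearsonDoubleEntry(c(-1, 1, -1), c(1, -1, 1)), -1)
  expect_error(pearsonDoubleEntry(rep(1, 4), rep(1, 4)), "zero variance")
  set.seed(42)
  for (n in c(30, 100, 400)) {
    pr <- rPairs(n, rho = 0.45)
    d <- abs(pearsonDoubleEntry(pr$y_a, pr$y_b) -
               intraclassCorrelation(pr$y_a, pr$y_b))
    expect_lt(d, 5 / n)  # estimators agree to O(1/n)
  }
})

test_that("Falconer's formula is exact arithmetic with optional truncation", {
  expect_equal(falconerH2(0.60, 0.25), 0.70)
  expect_equal(falconerH2(0.3, 0.3), 0)
  expect_equal(falconerH2(0.5, 0.4), 0.2, tolerance = 1e-12)
  expect_equal(falconerH2(0.9, 0.1), 1.6)           # raw, not clipped
  expect_equal(falconerH2(0.9, 0.1, truncate = TRUE), 1)
  expect_equal(falconerH2(0.1, 0.4, truncate = TRUE), 0)
  expect_error(falconerH2(1.2, 0), "\\[-1, 1\\]")
})

test_that("permutation p has add-one bounds, determinism and exchangeability", {
  set.seed(61)
  pairsDF <- data.frame(zygosity = rep(c("MZ", "SIB"), each = 12),
                        rbind(rPairs(12, 0.8), rPairs(12, 0.4)))
  r1 <- permutationPvalue(pairsDF, nPerm = 200, seed = 17)
  r2 <- permutationPvalue(pairsDF, nPerm = 200, seed = 17)
  expect_identical(r1, r2)                           # same seed, same bits
  expect_gte(r1$p, 1 / 201); expect_lte(r1$p, 1)
  # member order within pairs is irrelevant, including for p
  sw <- pairsDF; sw$y_a <- pairsDF$y_b; sw$y_b <- pairsDF$y_a
  r3 <- permutationPvalue(sw, nPerm = 200, seed = 17)
  expect_identical(r1$p, r3$p)
  expect_identical(r1$observedH2, r3$observedH2)
  # degenerate data propagate the estimator error
  dg <- pairsDF; dg$y_a <- 1; dg$y_b <- 1
  expect_error(permutationPvalue(dg, nPerm = 10, seed = 1), "zero total")
  expect_error(permutationPvalue(pairsDF, nPerm = 0, seed = 1), "nPerm")
})

test_that("an extreme statistic attains the minimum add-one p", {
  set.seed(77)
  pairsDF <- data.frame(zygosity = rep(c("MZ", "SIB"), each = 200),
                        rbind(rPairs(200, 0.9), rPairs(200, 0.45)))
  r <- permutationPvalue(pairsDF, nPerm = 1000, seed = 3)
  expect_equal(r$p, 1 / 1001)
  # pair-label scheme also sees a clearly extreme statistic
  r2 <- permutationPvalue(pairsDF, nPerm = 300, seed = 3,
                          scheme = "pair_label")
  expect_equal(r2$p, 1 / 301)
})

test_that("confounder screen picks the right test per covariate type", {
  set.seed(23)
  n <- 40
  cov <- data.frame(age = round(runif(n, 20, 60)),
                    sex = sample(c("F", "M"), n, TRUE),
                    ethnicity = sample(c("W", "B", "A"), n, TRUE),
                    growth_class = sample(c("slow", "fast"), n, TRUE),
                    transformation_time = round(runif(n, 20, 120)),
                    constant = rep("x", n))
  y <- rnorm(n, 40, 10)
  tab <- confounderScreen(y, cov)
  expect_equal(tab$type[tab$covariate == "age"], "continuous")
  expect_equal(tab$type[tab$covariate == "sex"], "binary")
  expect_equal(tab$type[tab$covariate == "ethnicity"], "multi_level")
  expect_match(tab$note[tab$covariate == "constant"], "not testable")
  expect_true(all(tab$p_bonferroni >= tab$p, na.rm = TRUE))
  # a phenotype equal to a covariate is detected with r = 1
  tab2 <- confounderScreen(cov$age, cov["age"])
  expect_equal(tab2$statistic, 1, tolerance = 1e-12)
  expect_lt(tab2$p, 1e-12)
})

test_that("confounder screen p-values are uniform under independence", {
  set.seed(321)
  ps <- replicate(200, {
    y <- rnorm(20); x <- data.frame(age = rnorm(20))
    confounderScreen(y, x)$p
  })
  rej <- mean(ps < 0.05)
  expect_lt(abs(rej - 0.05), 1.96 * sqrt(0.05 * 0.95 / 200) + 0.02)
})

test_that("variance-equality F-test behaves at both extremes", {
  set.seed(9)
  # identical samples duplicated: F = 1, p = 1
  x <- rnorm(10)
  eq <- varianceEquality(c(x, x), rep(c("g1", "g2"), each = 10))
  expect_equal(eq$statistic, 1)
  expect_equal(eq$p, 1)
  # variance ratio 16 at n = 20: closed-form F tail, decisively small
  vr <- varianceEquality(c(rnorm(20, 0, 4), rnorm(20, 0, 1)),
                         rep(c("g1", "g2"), each = 20))
  expect_lt(vr$p, 0.001)
  # null calibration
  ps <- replicate(200, varianceEquality(rnorm(24),
                                        rep(c("a", "b"), each = 12))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 1.96 * sqrt(0.05 * 0.95 / 200) + 0.02)
  # >2 groups: pairwise with Bonferroni, flagged
  v3 <- varianceEquality(rnorm(30), rep(c("a", "b", "c"), each = 10))
  expect_match(v3$note, "Bonferroni")
  expect_equal(nrow(v3$pairwise), 3L)
  expect_error(varianceEquality(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "zero variance")
})

test_that("the full analysis is antisymmetric in the groups and validates inputs", {
  cfg <- GenerativeConfig(seed = 8)
  sim <- simulatePairPhenotypes(cfg)
  pheno <- setNames(sim$samples$phenotype, sim$samples$sample_id)
  res <- runHeritabilityAnalysis(pheno, sim$manifest, nPerm = 50, seed = 4)
  expect_s4_class(res, "HeritabilityResult")
  expect_equal(h2(res), 2 * (rMZ(res) - rSIB(res)))
  expect_equal(res@nPairs, c(MZ = 23L, SIB = 23L))
  # swapping the zygosity labels negates the Falconer estimate
  manSwap <- sim$manifest
  manSwap@pairs$zygosity <- ifelse(manSwap@pairs$zygosity == "MZ",
                                   "SIB", "MZ")
  resSwap <- runHeritabilityAnalysis(pheno, manSwap, nPerm = 50, seed = 4)
  expect_equal(h2(resSwap), -h2(res), tolerance = 1e-12)
  # unmatched ids are an error listing the culprits
  expect_error(runHeritabilityAnalysis(pheno[-1], sim$manifest,
                                       nPerm = 10, seed = 1),
               names(pheno)[1])
  # a single zygosity group is refused
  manMZ <- sim$manifest
  manMZ@pairs <- manMZ@pairs[manMZ@pairs$zygosity == "MZ", ]
  expect_error(runHeritabilityAnalysis(pheno, manMZ, nPerm = 10, seed = 1),
               "zygosity group")
})

test_that("h2 estimates are unbiased across the generative grid", {
  # parameter recovery at large n over several (h2, c2) points
  seeds <- 1:8
  for (pars in list(c(0, 0.2), c(0.3, 0.1), c(0.7, 0.1))) {
    est <- vapply(seeds, function(s) {
      sim <- simulatePairPhenotypes(
        GenerativeConfig(nMZPairs = 2000, nSIBPairs = 2000,
                         h2 = pars[1], c2 = pars[2], seed = s))
      mz <- sim$pairs[sim$pairs$zygosity == "MZ", ]
      sib <- sim$pairs[sim$pairs$zygosity == "SIB", ]
      falconerH2(intraclassCorrelation(mz$y_a, mz$y_b),
                 intraclassCorrelation(sib$y_a, sib$y_b))
    }, numeric(1))
    expect_lt(abs(mean(est) - pars[1]), 0.03)
  }
})
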