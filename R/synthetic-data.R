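#' Construct a synthetic-study generator configuration
#'
#' Defaults encode the study conditions the generator emulates: 23
#' monozygotic and 23 sibling pairs; an adhesion phenotype with population
#' mean 40.25% input RFU and sd 10.37%; technical-replicate CV 8.68% over
#' 8 replicate wells per line; positive-control (Trisomy-21-like) adhesion
#' 35% and negative-control (Ramos-like) adhesion 5%; heritability
#' h2 = 0.6966 with shared-environment c2 = 0.10, so the implied
#' intra-pair correlations are `r_MZ = h2 + c2` and `r_SIB = h2/2 + c2`.
#'
#' @param nMZPairs,nSIBPairs pairs per zygosity group.
#' @param h2,c2 additive-genetic and shared-environment variance
#'   fractions; `h2 + c2 <= 1`.
#' @param phenotypeMean,phenotypeSD phenotype population mean and sd
#'   (% input RFU).
#' @param replicateCV technical replicate CV, percent.
#' @param posControlMean,negControlMean control adhesion levels, percent.
#' @param replicatesPerSample replicate wells per line.
#' @param loadedCells cells loaded per well.
#' @param curveParams named `(a, d, c, b)` of the generative 4PL
#'   fluorescence curve (RFU as a function of cells/well).
#' @param plateGain per-plate multiplicative gain (batch effect); scalar
#'   or one value per plate.
#' @param seed integer RNG seed.
#' @return A [GenerativeConfig-class].
#' @export
GenerativeConfig <- function(nMZPairs = 23L, nSIBPairs = 23L,
                             h2 = 0.6966, c2 = 0.10,
                             phenotypeMean = 40.25, phenotypeSD = 10.37,
                             replicateCV = 8.68,
                             posControlMean = 35, negControlMean = 5,
                             replicatesPerSample = 8L,
                             loadedCells = 50000,
                             curveParams = c(a = 150, d = 65000,
                                             c = 25000, b = 1.3),
                             plateGain = 1,
                             seed = 1L) {
  new("GenerativeConfig",
      nMZPairs = as.integer(nMZPairs), nSIBPairs = as.integer(nSIBPairs),
      h2 = h2, c2 = c2, phenotypeMean = phenotypeMean,
      phenotypeSD = phenotypeSD, replicateCV = replicateCV,
      posControlMean = posControlMean, negControlMean = negControlMean,
      replicatesPerSample = as.integer(replicatesPerSample),
      loadedCells = loadedCells, curveParams = curveParams,
      plateGain = plateGain, seed = as.integer(seed))
}

#' Simulate twin/sibling pair phenotypes under the additive model
#'
#' Each subject's phenotype is
#' `y = mu + sigma * (sqrt(h2) A + sqrt(c2) C + sqrt(1 - h2 - c2) E)`
#' with standard-normal components: the additive genetic value `A` is
#' shared fully within monozygotic pairs and with correlation 1/2 within
#' sibling pairs, the common-environment value `C` is shared within every
#' pair, and `E` is independent. The implied intra-pair correlations are
#' `r_MZ = h2 + c2` and `r_SIB = h2/2 + c2`, so the Falconer estimator
#' recovers `h2` in expectation. Phenotypes are clipped to (1, 99) before
#' any plate simulation; at the default parameters the clipping rate is
#' well below 0.1% so the genetic signal is not distorted (the realized
#' rate is returned for asserting this).
#'
#' Covariates (age, sex, ethnicity, growth class, transformation time)
#' are drawn independently of the phenotype -- twins share age, sex and
#' ethnicity; siblings share ethnicity -- unless `injectConfounder` names
#' a continuous covariate and a slope, in which case that covariate is
#' added to the phenotype (per sd of covariate) to create a detectable
#' confounder for power checks.
#'
#' @param config a [GenerativeConfig-class].
#' @param injectConfounder optional named numeric, e.g. `c(age = 0.5)`:
#'   phenotype points added per standard deviation of the covariate.
#' @return A list: `pairs` (data.frame `pair_id, zygosity, sample_id_a,
#'   sample_id_b, y_a, y_b`), `samples` (per-sample `sample_id, phenotype`
#'   plus covariates), `manifest` (a [PairManifest-class] carrying the
#'   covariates), and `clipRate`.
#' @export
simulatePairPhenotypes <- function(config, injectConfounder = NULL) {
  stopifnot(is(config, "GenerativeConfig"))
  set.seed(config@seed)
  nMZ <- config@nMZPairs; nSIB <- config@nSIBPairs
  n <- nMZ + nSIB
  zyg <- rep(c("MZ", "SIB"), c(nMZ, nSIB))
  h2v <- config@h2; c2v <- config@c2
  e2 <- 1 - h2v - c2v

  aShared <- rnorm(n)                       # pair-level additive component
  aA <- aShared
  # sibling B-member: correlation 1/2 with the A-member, unit variance
  aB <- ifelse(zyg == "MZ", aShared,
               0.5 * aShared + sqrt(0.75) * rnorm(n))
  cc <- rnorm(n)                            # common environment, shared
  eA <- rnorm(n); eB <- rnorm(n)
  z <- function(a, e) sqrt(h2v) * a + sqrt(c2v) * cc + sqrt(e2) * e
  yA <- config@phenotypeMean + config@phenotypeSD * z(aA, eA)
  yB <- config@phenotypeMean + config@phenotypeSD * z(aB, eB)

  pid <- sprintf("PAIR%03d", seq_len(n))
  sidA <- sprintf("S%03dA", seq_len(n))
  sidB <- sprintf("S%03dB", seq_len(n))

  # covariates, independent of phenotype by construction
  pairAge <- round(runif(n, 18, 60))
  ageA <- ifelse(zyg == "MZ", pairAge,
                 pmax(18, pairAge + sample(-8:8, n, replace = TRUE)))
  ageB <- pairAge
  pairSex <- sample(c("F", "M"), n, replace = TRUE)
  sexA <- ifelse(zyg == "MZ", pairSex, sample(c("F", "M"), n, replace = TRUE))
  sexB <- pairSex
  eth <- sample(c("White", "Black"), n, replace = TRUE, prob = c(0.7, 0.3))
  grA <- sample(c("slow", "fast"), n, replace = TRUE)
  grB <- sample(c("slow", "fast"), n, replace = TRUE)
  ttA <- round(runif(n, 20, 120)); ttB <- round(runif(n, 20, 120))

  samples <- data.frame(
    sample_id = c(sidA, sidB),
    phenotype = c(yA, yB),
    age = c(ageA, ageB), sex = c(sexA, sexB),
    ethnicity = c(eth, eth), growth_class = c(grA, grB),
    transformation_time = c(ttA, ttB),
    stringsAsFactors = FALSE)

  if (!is.null(injectConfounder)) {
    for (nm in names(injectConfounder)) {
      v <- samples[[nm]]
      if (!is.numeric(v))
        .domainError("confounder injection supports continuous covariates only ('%s' is not numeric)", nm)
      samples$phenotype <- samples$phenotype +
        injectConfounder[[nm]] * as.numeric(scale(v))
    }
  }

  clipped <- samples$phenotype <= 1 | samples$phenotype >= 99
  clipRate <- mean(clipped)
  if (clipRate >= 0.001)
    warning(sprintf("%.2f%% of phenotypes clipped to (1, 99); genetic signal may be distorted",
                    100 * clipRate))
  samples$phenotype <- pmin(pmax(samples$phenotype, 1), 99)

  yA <- samples$phenotype[seq_len(n)]
  yB <- samples$phenotype[n + seq_len(n)]
  pairs <- data.frame(pair_id = pid, zygosity = zyg,
                      sample_id_a = sidA, sample_id_b = sidB,
                      y_a = yA, y_b = yB, stringsAsFactors = FALSE)
  manifest <- new("PairManifest", pairs = data.frame(
    pair_id = pid, zygosity = zyg, sample_id_a = sidA, sample_id_b = sidB,
    age_a = ageA, age_b = ageB, sex_a = sexA, sex_b = sexB,
    ethnicity = eth, growth_class_a = grA, growth_class_b = grB,
    transformation_time_a = ttA, transformation_time_b = ttB,
    stringsAsFactors = FALSE))
  list(pairs = pairs, samples = samples, manifest = manifest,
       clipRate = clipRate)
}

#' Simulate 96-well plate readings for given sample phenotypes
#'
#' Lays the samples out on as many 96-well plates as needed (8 replicate
#' wells per line by default, 8 positive-control, 8 negative-control and 8
#' standard-curve wells per plate; extra samples paginate onto additional
#' plates, never dropped) and generates pre-wash and post-third-wash
#' fluorescence for every well. The pre-wash signal is the generative 4PL
#' curve evaluated at the loaded cell count times the plate gain; the
#' post-wash signal is the well's adhesion fraction times its pre-wash
#' signal. Multiplicative log-normal noise is applied to each read,
#' calibrated so the technical-replicate CV of the % input RFU readout
#' matches `replicateCV`. Standard-curve wells carry noiseless known cell
#' loads read through the same curve and gain. Deterministic under the
#' config seed.
#'
#' @param samples data.frame with `sample_id` and `phenotype` (% input,
#'   in (0, 100)), e.g. `simulatePairPhenotypes(config)$samples`.
#' @param config a [GenerativeConfig-class].
#' @return A list: `readings` ([PlateReadingSet-class]), `layouts`
#'   ([PlateLayoutSet-class]), `curve` (the generative [FourPLCurve-class]).
#' @export
simulatePlateReadings <- function(samples, config) {
  stopifnot(is(config, "GenerativeConfig"))
  .requireColumns(samples, c("sample_id", "phenotype"), "samples table")
  if (any(samples$phenotype <= 0 | samples$phenotype >= 100))
    .domainError("sample phenotypes must lie in (0, 100) percent")
  set.seed(config@seed + 1L)

  cp <- config@curveParams
  curve <- new("FourPLCurve", a = cp[["a"]], d = cp[["d"]], c = cp[["c"]],
               b = cp[["b"]], residualSD = 0, nPoints = 0L)
  nRep <- config@replicatesPerSample
  # plate budget: 8 pos + 8 neg + 8 standard-curve wells, rest for samples
  nCtrl <- 8L
  nStd <- 8L
  capacity <- (96L - 2L * nCtrl - nStd) %/% nRep
  if (capacity < 1L)
    .domainError("replicatesPerSample too large for a 96-well plate")
  nPlates <- ceiling(nrow(samples) / capacity)
  gains <- rep_len(config@plateGain, nPlates)
  stdLoads <- round(exp(seq(log(500), log(80000), length.out = nStd)))

  # per-read noise: CV of the post/pre ratio is the replicate CV, split
  # evenly between the two reads
  cvRead <- (config@replicateCV / 100) / sqrt(2)
  sdlog <- sqrt(log(1 + cvRead^2))
  noise <- function(k) exp(rnorm(k, -sdlog^2 / 2, sdlog))

  preSignal <- evalFourPL(curve, config@loadedCells)
  grid <- .wellGrid()
  readingRows <- vector("list", nPlates)
  layoutRows <- vector("list", nPlates)
  for (p in seq_len(nPlates)) {
    pid <- sprintf("P%02d", p)
    idx <- ((p - 1L) * capacity + 1L):min(p * capacity, nrow(samples))
    batch <- samples[idx, , drop = FALSE]
    ids <- c(rep(batch$sample_id, each = nRep),
             rep("POS_T21", nCtrl), rep("NEG_RAMOS", nCtrl),
             rep("STD", nStd))
    roles <- c(rep("test", nrow(batch) * nRep),
               rep("positive_control", nCtrl),
               rep("negative_control", nCtrl),
               rep("standard_curve", nStd))
    adhesion <- c(rep(batch$phenotype, each = nRep),
                  rep(config@posControlMean, nCtrl),
                  rep(config@negControlMean, nCtrl),
                  rep(NA_real_, nStd))
    wells <- grid[seq_along(ids)]
    nMeas <- sum(roles != "standard_curve")
    pre <- preSignal * gains[p] * noise(nMeas)
    post <- (adhesion[roles != "standard_curve"] / 100) *
      preSignal * gains[p] * noise(nMeas)
    meas <- roles != "standard_curve"
    readingRows[[p]] <- data.frame(
      plate_id = pid,
      well = c(wells[meas], wells[meas], wells[!meas]),
      sample_id = c(ids[meas], ids[meas], ids[!meas]),
      role = c(roles[meas], roles[meas], roles[!meas]),
      read_stage = c(rep("pre_wash", nMeas), rep("wash3", nMeas),
                     rep("pre_wash", nStd)),
      rfu = c(pre, post, evalFourPL(curve, stdLoads) * gains[p]),
      known_cells = c(rep(NA_real_, 2L * nMeas), stdLoads),
      stringsAsFactors = FALSE)
    layoutRows[[p]] <- data.frame(plate_id = pid, well = wells,
                                  sample_id = ids, role = roles,
                                  stringsAsFactors = FALSE)
  }
  rd <- do.call(rbind, readingRows)
  # canonical row order: plate, well (grid order), stage
  rd <- rd[order(rd$plate_id, match(rd$well, grid),
                 match(rd$read_stage, .READ_STAGES)), ]
  list(readings = newPlateReadingSet(rd),
       layouts = new("PlateLayoutSet", layout = do.call(rbind, layoutRows),
                     replicatesPerSample = nRep),
       curve = curve)
}

#' Write a complete synthetic study to disk
#'
#' Generates pair phenotypes and plate readings under the config and
#' writes the four canonical CSVs (`readings.csv`, `plate_layouts.csv`,
#' `standard_curves.csv`, `pair_manifest.csv`) plus
#' `ground_truth.json` (true h2, c2, implied correlations, per-sample
#' generative phenotypes, full generation parameters) for test
#' assertions. Byte-identical output under the same config and seed.
#'
#' @param config a [GenerativeConfig-class].
#' @param outDir writable output directory (created if absent).
#' @return Named character vector of the written file paths (the
#'   manifest), invisibly.
#' @export
makeFixtureStudy <- function(config, outDir) {
  stopifnot(is(config, "GenerativeConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, mode = 2L) != 0L)
    .domainError("output directory '%s' is not writable", outDir)
  sim <- simulatePairPhenotypes(config)
  plates <- simulatePlateReadings(sim$samples, config)

  paths <- c(readings = file.path(outDir, "readings.csv"),
             layouts = file.path(outDir, "plate_layouts.csv"),
             curves = file.path(outDir, "standard_curves.csv"),
             pairs = file.path(outDir, "pair_manifest.csv"),
             truth = file.path(outDir, "ground_truth.json"))
  writePlateReadings(plates$readings, paths[["readings"]])
  writePlateLayouts(plates$layouts, paths[["layouts"]])
  rd <- readings(plates$readings)
  std <- rd[rd$role == "standard_curve", ]
  write.csv(data.frame(plate_id = std$plate_id, known_cells = std$known_cells,
                       rfu = .fmtNum(std$rfu)),
            paths[["curves"]], row.names = FALSE, quote = FALSE)
  writePairManifest(sim$manifest, paths[["pairs"]])
  truth <- list(
    h2 = config@h2, c2 = config@c2,
    r_mz_implied = config@h2 + config@c2,
    r_sib_implied = config@h2 / 2 + config@c2,
    clip_rate = sim$clipRate,
    seed = config@seed,
    parameters = list(
      n_mz_pairs = config@nMZPairs, n_sib_pairs = config@nSIBPairs,
      phenotype_mean = config@phenotypeMean,
      phenotype_sd = config@phenotypeSD,
      replicate_cv = config@replicateCV,
      pos_control_mean = config@posControlMean,
      neg_control_mean = config@negControlMean,
      replicates_per_sample = config@replicatesPerSample,
      loaded_cells = config@loadedCells,
      curve_params = as.list(config@curveParams),
      plate_gain = config@plateGain),
    samples = setNames(as.list(sim$samples$phenotype),
                       sim$samples$sample_id))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
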