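#' PlateReadingSet: per-well fluorescence readings for one study
#'
#' Long-format container for leukocyte-endothelial adhesion (LEA) plate-reader
#' output: one row per (plate, well, read stage), holding the sample occupying
#' the well, its role on the plate, and the total-area fluorescence signal in
#' relative fluorescence units (RFU). Standard-curve wells additionally carry
#' the known number of cells loaded into the well.
#'
#' @slot readings data.frame with columns `plate_id`, `well`, `sample_id`,
#'   `role`, `read_stage`, `rfu`, `known_cells`. Wells are 96-well grid
#'   positions (`A1`--`H12`); roles are one of `test`, `positive_control`,
#'   `negative_control`, `endothelial_only_blank`, `standard_curve`; read
#'   stages one of `pre_wash`, `wash1`, `wash2`, `wash3`. `rfu` is
#'   non-negative; `known_cells` is present iff the role is `standard_curve`.
#'
#' @seealso [readPlateReadings()], [simulatePlateReadings()]
#' @export
setClass("PlateReadingSet", representation(readings = "data.frame"))

setValidity("PlateReadingSet", function(object) {
  df <- object@readings
  cols <- c("plate_id", "well", "sample_id", "role", "read_stage",
            "rfu", "known_cells")
  if (!all(cols %in% names(df)))
    return(paste("readings must have columns:", paste(cols, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(!.isValidWell(df$well)))
    return(sprintf("malformed well label(s): %s",
                   .fmtSome(df$well[!.isValidWell(df$well)])))
  if (any(!df$role %in% .WELL_ROLES))
    return(sprintf("unknown role(s): %s",
                   .fmtSome(df$role[!df$role %in% .WELL_ROLES])))
  if (any(!df$read_stage %in% .READ_STAGES))
    return(sprintf("unknown read stage(s): %s",
                   .fmtSome(df$read_stage[!df$read_stage %in% .READ_STAGES])))
  bad <- !is.na(df$rfu) & df$rfu < 0
  if (any(bad)) return("rfu must be non-negative")
  key <- paste(df$plate_id, df$well, df$read_stage, sep = "\r")
  if (anyDuplicated(key))
    return(sprintf("duplicate (plate, well, read_stage) rows: %s",
                   .fmtSome(gsub("\r", "/", key[duplicated(key)]))))
  std <- df$role == "standard_curve"
  if (any(std & is.na(df$known_cells)))
    return("standard_curve wells must carry known_cells")
  if (any(!std & !is.na(df$known_cells)))
    return("known_cells is only allowed on standard_curve wells")
  TRUE
})

#' PlateLayoutSet: well-to-sample maps for the study's plates
#'
#' @slot layout data.frame with columns `plate_id`, `well`, `sample_id`,
#'   `role` describing which sample (or control) occupies each used well.
#' @slot replicatesPerSample integer, the intended number of technical
#'   replicate wells per cell line (study convention: 8).
#'
#' @seealso [readPlateLayouts()]
#' @export
setClass("PlateLayoutSet",
         representation(layout = "data.frame",
                        replicatesPerSample = "integer"),
         prototype(replicatesPerSample = 8L))

setValidity("PlateLayoutSet", function(object) {
  df <- object@layout
  cols <- c("plate_id", "well", "sample_id", "role")
  if (!all(cols %in% names(df)))
    return(paste("layout must have columns:", paste(cols, collapse = ", ")))
  if (nrow(df) && any(!.isValidWell(df$well)))
    return("malformed well label(s) in layout")
  if (nrow(df) && any(!df$role %in% .WELL_ROLES))
    return("unknown role(s) in layout")
  if (length(object@replicatesPerSample) != 1L ||
      is.na(object@replicatesPerSample) || object@replicatesPerSample < 1L)
    return("replicatesPerSample must be a positive integer")
  TRUE
})

#' PairManifest: monozygotic twin and sibling pairs with covariates
#'
#' One row per pair: the two member cell lines, the pair's zygosity
#' (`MZ` for monozygotic twins, `SIB` for full siblings treated as
#' dizygotic), and optional per-subject covariates used for confounder
#' screening (age in years, sex, ethnicity, culture growth class,
#' transformation time in days). Covariates may be missing; they are
#' recorded as `NA` and never imputed.
#'
#' @slot pairs data.frame with columns `pair_id`, `zygosity`,
#'   `sample_id_a`, `sample_id_b` and any covariate columns.
#'
#' @seealso [readPairManifest()]
#' @export
setClass("PairManifest", representation(pairs = "data.frame"))

setValidity("PairManifest", function(object) {
  df <- object@pairs
  cols <- c("pair_id", "zygosity", "sample_id_a", "sample_id_b")
  if (!all(cols %in% names(df)))
    return(paste("pairs must have columns:", paste(cols, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(!df$zygosity %in% c("MZ", "SIB")))
    return("zygosity must be 'MZ' or 'SIB'")
  if (any(df$sample_id_a == df$sample_id_b))
    return("a pair's two sample ids must differ")
  ids <- c(df$sample_id_a, df$sample_id_b)
  if (anyDuplicated(ids))
    return(sprintf("sample(s) appear in more than one pair: %s",
                   .fmtSome(ids[duplicated(ids)])))
  if (anyDuplicated(df$pair_id)) return("duplicate pair_id")
  TRUE
})

#' FourPLCurve: fitted four-parameter logistic standard curve
#'
#' Sigmoid calibration curve `f(x) = d + (a - d) / (1 + (x / c)^b)` mapping
#' cells/well to fluorescence. `a` is the asymptote at zero cells, `d` the
#' asymptote at saturating cell numbers, `c` the inflection point in
#' cells/well, and `b` the (dimensionless) slope factor. The curve is
#' strictly monotone in `x` for `b != 0`, so RFU values strictly between the
#' asymptotes invert uniquely to a cell count.
#'
#' @slot a,d numeric, lower/upper RFU asymptotes (zero / infinite cells).
#' @slot c numeric, inflection point, cells/well; positive.
#' @slot b numeric, slope factor; non-zero.
#' @slot residualSD numeric, residual standard deviation of the fit.
#' @slot nPoints integer, number of calibration points used.
#'
#' @seealso [fitFourPL()], [evalFourPL()], [invertFourPL()]
#' @export
setClass("FourPLCurve",
         representation(a = "numeric", d = "numeric", c = "numeric",
                        b = "numeric", residualSD = "numeric",
                        nPoints = "integer"),
         prototype(residualSD = NA_real_, nPoints = 0L))

setValidity("FourPLCurve", function(object) {
  for (s in c("a", "d", "c", "b"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      return(sprintf("slot '%s' must be a single finite number", s))
  if (object@c <= 0) return("inflection point c must be positive")
  if (object@b == 0) return("slope factor b must be non-zero")
  if (object@a == object@d) return("asymptotes a and d must differ")
  TRUE
})

#' ControlSummary: positive/negative control statistics for one plate
#'
#' Means and standard deviations of the positive-control (high-adhesion,
#' Trisomy-21-like) and negative-control (low-adhesion, Ramos-like) wells,
#' the inputs to the Z'-factor and signal-to-noise statistics. Signals may
#' be raw RFU or derived adhesion percentages; both controls must be on the
#' same scale.
#'
#' @slot muPos,sdPos numeric, mean and sd of positive-control wells.
#' @slot muNeg,sdNeg numeric, mean and sd of negative-control wells.
#' @slot nPos,nNeg integer, well counts behind each summary.
#'
#' @seealso [controlSummary()], [zPrime()], [signalToNoise()]
#' @export
setClass("ControlSummary",
         representation(muPos = "numeric", sdPos = "numeric",
                        muNeg = "numeric", sdNeg = "numeric",
                        nPos = "integer", nNeg = "integer"))

setValidity("ControlSummary", function(object) {
  if (!is.finite(object@muPos) || !is.finite(object@muNeg))
    return("control means must be finite")
  if (is.finite(object@sdPos) && object@sdPos < 0) return("sdPos must be >= 0")
  if (is.finite(object@sdNeg) && object@sdNeg < 0) return("sdNeg must be >= 0")
  TRUE
})

#' ValidationReport: cross-table consistency report for a study
#'
#' Collects every structural problem found when cross-checking readings,
#' layouts and the pair manifest (report-based: validation never stops at
#' the first failure).
#'
#' @slot ok logical, `TRUE` iff no issues were found.
#' @slot issues data.frame with columns `category`, `id`, `message`.
#'
#' @seealso [validateStudy()]
#' @export
setClass("ValidationReport",
         representation(ok = "logical", issues = "data.frame"))

#' QCReport: assay quality-control summary for one plate
#'
#' @slot plateId character, the plate.
#' @slot cvBySample named numeric, replicate coefficient of variation (%)
#'   per test sample on the plate.
#' @slot zprime numeric, plate Z'-factor (at most 1).
#' @slot snr numeric, signal-to-noise ratio.
#' @slot passed logical, `TRUE` iff all gate thresholds were met.
#' @slot thresholds list of the gates applied
#'   (`min_zprime`, `max_cv_percent`).
#'
#' @seealso [plateQC()]
#' @export
setClass("QCReport",
         representation(plateId = "character", cvBySample = "numeric",
                        zprime = "numeric", snr = "numeric",
                        passed = "logical", thresholds = "list"))

#' HeritabilityResult: twin-design heritability estimate with permutation null
#'
#' @slot rMZ,rSIB numeric, intra-pair correlations for the monozygotic and
#'   sibling groups (the configured estimator).
#' @slot h2 numeric, Falconer heritability `2 * (rMZ - rSIB)`; raw value,
#'   possibly outside `[0, 1]` (see `h2OutOfRange`).
#' @slot h2OutOfRange logical, `TRUE` when the raw estimate fell outside
#'   `[0, 1]`.
#' @slot pEmpirical numeric, add-one permutation p-value, in
#'   `(1/(nPerm + 1), 1]`.
#' @slot nPerm integer, number of permutations.
#' @slot nullH2 numeric, the permuted statistics (the null distribution).
#' @slot nullSummary named numeric: mean, sd and quantiles of `nullH2`.
#' @slot estimator character, `"icc"` (ANOVA intraclass correlation) or
#'   `"double_entry"` (Pearson on the double-entered pairs).
#' @slot scheme character, the permutation scheme used.
#' @slot phenotypeScale character, which phenotype fed the analysis.
#' @slot seed integer, RNG seed (reproducibility contract).
#' @slot nPairs named integer, pairs per zygosity group.
#'
#' @seealso [runHeritabilityAnalysis()], [permutationPvalue()]
#' @export
setClass("HeritabilityResult",
         representation(rMZ = "numeric", rSIB = "numeric", h2 = "numeric",
                        h2OutOfRange = "logical", pEmpirical = "numeric",
                        nPerm = "integer", nullH2 = "numeric",
                        nullSummary = "numeric", estimator = "character",
                        scheme = "character", phenotypeScale = "character",
                        seed = "integer", nPairs = "integer"))

#' GenerativeConfig: parameters of the synthetic twin-study generator
#'
#' Defines the study conditions the generator emulates: an additive
#' genetic model for pair phenotypes (fraction `h2` of phenotypic variance
#' additive-genetic, shared fully by monozygotic twins and half by full
#' siblings; fraction `c2` shared-environmental, shared within every pair)
#' and a 96-well plate assay realization of those phenotypes with
#' technical replicates, plate controls and standard-curve wells.
#'
#' @slot nMZPairs,nSIBPairs integer, pairs per zygosity group (default 23/23).
#' @slot h2 numeric, additive-genetic variance fraction (default 0.6966).
#' @slot c2 numeric, shared-environment variance fraction (default 0.10).
#' @slot phenotypeMean,phenotypeSD numeric, population mean and sd of the
#'   adhesion phenotype on the % input RFU scale (defaults 40.25, 10.37).
#' @slot replicateCV numeric, technical-replicate coefficient of variation
#'   in percent (default 8.68).
#' @slot posControlMean,negControlMean numeric, adhesion of the
#'   positive-control (Trisomy-21-like, default 35) and negative-control
#'   (Ramos-like, default 5) lines, % input.
#' @slot replicatesPerSample integer, technical replicate wells per cell
#'   line (default 8).
#' @slot loadedCells numeric, cells loaded per well (default 50000).
#' @slot curveParams named numeric `(a, d, c, b)` of the generative 4PL
#'   fluorescence curve.
#' @slot plateGain numeric, per-plate multiplicative gain (batch effect);
#'   scalar recycled over plates, or one value per plate.
#' @slot seed integer, RNG seed.
#'
#' @seealso [GenerativeConfig()], [simulatePairPhenotypes()],
#'   [simulatePlateReadings()], [makeFixtureStudy()]
#' @export
setClass("GenerativeConfig",
         representation(nMZPairs = "integer", nSIBPairs = "integer",
                        h2 = "numeric", c2 = "numeric",
                        phenotypeMean = "numeric", phenotypeSD = "numeric",
                        replicateCV = "numeric",
                        posControlMean = "numeric", negControlMean = "numeric",
                        replicatesPerSample = "integer",
                        loadedCells = "numeric", curveParams = "numeric",
                        plateGain = "numeric", seed = "integer"))

setValidity("GenerativeConfig", function(object) {
  if (object@h2 < 0 || object@c2 < 0)
    return("h2 and c2 must be non-negative")
  if (object@h2 + object@c2 > 1)
    return("h2 + c2 must not exceed 1")
  if (object@phenotypeSD <= 0) return("phenotypeSD must be positive")
  if (object@replicateCV <= 0) return("replicateCV must be positive")
  if (object@nMZPairs < 0L || object@nSIBPairs < 0L)
    return("pair counts must be non-negative")
  if (object@replicatesPerSample < 1L)
    return("replicatesPerSample must be >= 1")
  if (object@loadedCells <= 0) return("loadedCells must be positive")
  if (!all(c("a", "d", "c", "b") %in% names(object@curveParams)))
    return("curveParams must be named (a, d, c, b)")
  if (any(object@plateGain <= 0)) return("plateGain must be positive")
  TRUE
})
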