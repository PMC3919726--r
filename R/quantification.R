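#' Percent of input fluorescence remaining after washing
#'
#' The assay's primary readout:
#' `100 * (RFU after the third wash) / (RFU before washing)`, i.e. the
#' fraction of loaded, dye-labeled cells still adherent to the endothelial
#' monolayer, on the fluorescence scale.
#'
#' @param preWashRfu numeric, total-area fluorescence before washing;
#'   strictly positive.
#' @param postWash3Rfu numeric, fluorescence after the third wash;
#'   non-negative.
#' @return Percent of input RFU (vectorized).
#' @examples
#' percentInputRFU(2500, 1000)  # 40
#' @export
percentInputRFU <- function(preWashRfu, postWash3Rfu) {
  pre <- as.numeric(preWashRfu); post <- as.numeric(postWash3Rfu)
  if (any(!is.finite(pre)) || any(pre <= 0))
    .domainError("pre-wash RFU must be positive and finite")
  if (any(post < 0, na.rm = TRUE))
    .domainError("post-wash RFU must be non-negative")
  100 * post / pre
}

#' Percent adherent cells via the standard curve
#'
#' Converts a post-wash fluorescence reading to a cell count with
#' [invertFourPL()] and expresses it as a percentage of the cells loaded
#' into the well (study convention: 50,000 cells/well).
#'
#' @param curve a [FourPLCurve-class] for the cell line (or line class).
#' @param postWash3Rfu numeric, post-third-wash RFU, strictly inside the
#'   curve's asymptote interval.
#' @param loadedCells cells loaded per well; positive (default 50000).
#' @return Percent of input cell number remaining adherent.
#' @export
percentAdherent <- function(curve, postWash3Rfu, loadedCells = 50000) {
  if (any(loadedCells <= 0)) .domainError("loadedCells must be positive")
  100 * invertFourPL(curve, postWash3Rfu) / loadedCells
}

#' Standardize a sample's adhesion to the on-plate positive control
#'
#' Ratio of a sample's mean adhesion to the mean adhesion of the
#' positive-control (Trisomy-21-like) line on the same plate. A plate-wide
#' multiplicative gain (batch effect) applies equally to numerator and
#' denominator, so the standardized coefficient cancels it exactly.
#'
#' @param sampleMean numeric, the sample's mean adhesion (any consistent
#'   scale).
#' @param positiveControlMean numeric, same-plate positive-control mean;
#'   strictly positive.
#' @return Dimensionless ratio (> 0 for positive sample signal).
#' @export
standardizeToControl <- function(sampleMean, positiveControlMean) {
  if (any(!is.finite(positiveControlMean)) || any(positiveControlMean <= 0))
    .domainError("positive-control mean must be positive")
  sampleMean / positiveControlMean
}

#' Cross-plate consistency of standardized coefficients
#'
#' One-way ANOVA F-test of the standardized replicate values across plate
#' groups: under plate-to-plate consistency the group means are equal and
#' the p-value is uniform. Requires at least two plates with at least two
#' replicates each; with a single plate, or zero within-group variance,
#' the test is not applicable and the result is flagged instead of forced.
#'
#' @param values numeric, standardized replicate values.
#' @param plate character/factor, the plate of each value.
#' @return A list: `p` (the ANOVA p-value, or `NA` when not applicable),
#'   `statistic` (the F statistic), `df`, and `note` (why no p, if `NA`).
#' @export
crossPlateConsistency <- function(values, plate) {
  values <- as.numeric(values)
  plate <- factor(plate)
  ok <- is.finite(values) & !is.na(plate)
  values <- values[ok]; plate <- droplevels(plate[ok])
  if (nlevels(plate) < 2L)
    return(list(p = NA_real_, statistic = NA_real_, df = c(NA, NA),
                note = "single plate: cross-plate test not applicable"))
  if (any(table(plate) < 2L))
    return(list(p = NA_real_, statistic = NA_real_, df = c(NA, NA),
                note = "a plate has < 2 replicates"))
  if (all(tapply(values, plate, var) == 0))
    return(list(p = NA_real_, statistic = NA_real_, df = c(NA, NA),
                note = "zero within-group variance: F degenerate"))
  av <- anova(lm(values ~ plate))
  list(p = av[["Pr(>F)"]][1], statistic = av[["F value"]][1],
       df = c(av[["Df"]][1], av[["Df"]][2]), note = NA_character_)
}

#' Quantify per-cell-line adhesion phenotypes
#'
#' Turns raw well fluorescence into one phenotype row per cell line:
#' \itemize{
#'   \item `pct_input_rfu_*`: per-well `100 * wash3/pre_wash` summarized
#'     over technical replicates (mean, sd, CV);
#'   \item `pct_adherent_mean`: % of loaded cells remaining, from the 4PL
#'     standard curve fitted to the plate's own calibration wells when
#'     present (else one study-wide curve, else `NA`);
#'   \item `standardized_coefficient`: sample mean over the same-plate
#'     positive-control mean (averaged across plates the sample appears
#'     on), the control-anchored cross-plate normalization.
#' }
#' Replicates on plates that fail QC are excluded when `qc` is supplied.
#'
#' @param x a [PlateReadingSet-class].
#' @param qc optional result of [plateQC()]; failed plates are dropped.
#' @param loadedCells cells loaded per well (default 50000).
#' @param curveSource `"per_plate"` (default), `"study"`, or `"none"`.
#' @return data.frame with columns `sample_id, n_rep, pct_input_rfu_mean,
#'   pct_input_rfu_sd, pct_input_rfu_cv, pct_adherent_mean,
#'   standardized_coefficient, plate_ids, flag` (flag notes phenotypes
#'   above 120% input, which only measurement noise should produce).
#' @export
quantifyAdhesion <- function(x, qc = NULL, loadedCells = 50000,
                             curveSource = c("per_plate", "study", "none")) {
  stopifnot(is(x, "PlateReadingSet"))
  curveSource <- match.arg(curveSource)
  df <- x@readings
  if (!is.null(qc)) {
    failed <- vapply(Filter(function(r) is(r, "QCReport"), qc),
                     function(r) if (!r@passed) r@plateId else NA_character_,
                     character(1))
    failed <- failed[!is.na(failed)]
    if (length(failed)) df <- df[!df$plate_id %in% failed, , drop = FALSE]
  }
  set <- newPlateReadingSet(df)
  wellPct <- .perWellPercentInput(set)

  curves <- list()
  if (curveSource != "none") {
    std <- df[df$role == "standard_curve" & df$read_stage == "pre_wash", ]
    if (nrow(std)) {
      if (curveSource == "per_plate") {
        for (pid in unique(std$plate_id)) {
          s <- std[std$plate_id == pid, ]
          if (length(unique(s$known_cells)) >= 4L)
            curves[[pid]] <- fitFourPL(s$known_cells, s$rfu)
        }
      }
      if (curveSource == "study" || length(curves) == 0L)
        curves[["__study__"]] <- fitFourPL(std$known_cells, std$rfu)
    }
  }
  curveFor <- function(pid) {
    if (!is.null(curves[[pid]])) curves[[pid]] else curves[["__study__"]]
  }

  post <- df[df$read_stage == "wash3", ]
  posMeanByPlate <- vapply(
    split(wellPct$pct_input[wellPct$role == "positive_control"],
          wellPct$plate_id[wellPct$role == "positive_control"]),
    mean, numeric(1))

  test <- wellPct[wellPct$role == "test", ]
  out <- lapply(split(test, test$sample_id), function(s) {
    v <- s$pct_input
    n <- length(v)
    m <- mean(v)
    # % adherent: invert each wash3 well reading through its plate's curve
    adh <- NA_real_
    if (length(curves)) {
      key <- paste(s$plate_id, s$well, sep = "\r")
      pk <- paste(post$plate_id, post$well, sep = "\r")
      rfu3 <- post$rfu[match(key, pk)]
      vals <- mapply(function(pid, y) {
        cv <- curveFor(pid)
        if (is.null(cv)) return(NA_real_)
        tryCatch(percentAdherent(cv, y, loadedCells),
                 error = function(e) NA_real_)
      }, s$plate_id, rfu3)
      if (any(is.finite(vals))) adh <- mean(vals[is.finite(vals)])
    }
    # control-anchored standardization, averaged over the sample's plates
    stdc <- NA_real_
    perPlate <- split(v, s$plate_id)
    ctrl <- posMeanByPlate[names(perPlate)]
    okp <- is.finite(ctrl) & ctrl > 0
    if (any(okp))
      stdc <- mean(mapply(function(sv, cm) standardizeToControl(mean(sv), cm),
                          perPlate[okp], ctrl[okp]))
    data.frame(
      sample_id = s$sample_id[1], n_rep = n,
      pct_input_rfu_mean = m,
      pct_input_rfu_sd = if (n >= 2L) sd(v) else NA_real_,
      pct_input_rfu_cv = if (n >= 2L && m != 0) 100 * sd(v) / m else NA_real_,
      pct_adherent_mean = adh,
      standardized_coefficient = stdc,
      plate_ids = paste(sort(unique(s$plate_id)), collapse = ";"),
      flag = if (m > 120) "pct_input>120" else "",
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the phenotype table as TSV
#'
#' @param phenotypes result of [quantifyAdhesion()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypeTable <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
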