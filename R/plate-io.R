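#' Read per-well plate readings from a long-format CSV
#'
#' The canonical reading table is tidy/long: one row per (plate, well, read
#' stage), with header columns `plate_id, well, sample_id, role, read_stage,
#' rfu` and optionally `known_cells` (standard-curve wells only). Wells are
#' letter+number positions on the 96-well grid (`A1`--`H12`, 1-based
#' columns). Rows with an empty `rfu` cell are treated as absent wells and
#' dropped (never read as zeros).
#'
#' @param path path to a UTF-8, RFC-4180 CSV file with a header row.
#' @return A [PlateReadingSet-class].
#' @details Validation is total: a syntactically valid CSV yields either a
#'   dataset or a located error. Missing columns raise a schema error naming
#'   the column; negative `rfu` and malformed well labels raise validation
#'   errors carrying the offending data row numbers; duplicated
#'   (plate, well, stage) keys are rejected.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("plate_id,well,sample_id,role,read_stage,rfu",
#'              "P1,A1,S1,test,pre_wash,2500",
#'              "P1,A1,S1,test,wash3,1000"), tf)
#' readings(readPlateReadings(tf))
#' @seealso [writePlateReadings()], [validateStudy()]
#' @export
readPlateReadings <- function(path) {
  if (!file.exists(path)) .schemaError("readings file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .requireColumns(df, c("plate_id", "well", "sample_id", "role",
                        "read_stage", "rfu"), "plate readings CSV")
  if (!"known_cells" %in% names(df)) df$known_cells <- NA_character_
  df <- df[, c("plate_id", "well", "sample_id", "role", "read_stage",
               "rfu", "known_cells")]
  # absent measurements: empty rfu cells are dropped, not zeroed
  absent <- is.na(df$rfu) | !nzchar(trimws(df$rfu))
  if (any(absent)) df <- df[!absent, , drop = FALSE]
  rfu <- suppressWarnings(as.numeric(df$rfu))
  if (anyNA(rfu))
    .validationError("non-numeric rfu at data row(s): %s",
                     .fmtSome(which(is.na(rfu))))
  if (any(rfu < 0))
    .validationError("negative rfu at data row(s): %s",
                     .fmtSome(which(rfu < 0)))
  badWell <- !.isValidWell(df$well)
  if (any(badWell))
    .validationError("malformed well label '%s' at data row(s): %s",
                     .fmtSome(df$well[badWell]), .fmtSome(which(badWell)))
  df$rfu <- rfu
  df$known_cells <- suppressWarnings(as.numeric(df$known_cells))
  newPlateReadingSet(df)
}

# internal constructor: validity-checked, canonical row order untouched
newPlateReadingSet <- function(df) {
  rownames(df) <- NULL
  new("PlateReadingSet", readings = df)
}

#' Write plate readings to the canonical long CSV dialect
#'
#' Writes the columns in canonical order with `known_cells` empty on
#' non-standard-curve wells, so that `writePlateReadings(readPlateReadings(f))`
#' reproduces `f` byte-for-byte for canonicalized files.
#'
#' @param x a [PlateReadingSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePlateReadings <- function(x, path) {
  stopifnot(is(x, "PlateReadingSet"))
  df <- x@readings
  df$rfu <- .fmtNum(df$rfu)
  df$known_cells <- ifelse(is.na(df$known_cells), "", .fmtNum(df$known_cells))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# numbers rendered without scientific notation; fractional trailing zeros
# trimmed so integers stay integers
.fmtNum <- function(x) {
  out <- trimws(formatC(x, format = "fg", digits = 15))
  frac <- grepl(".", out, fixed = TRUE)
  out[frac] <- sub("\\.?0+$", "", out[frac])
  out
}

#' Read plate layouts (well-to-sample maps)
#'
#' @param path CSV with columns `plate_id, well, sample_id, role`.
#' @param replicatesPerSample intended technical replicates per cell line
#'   (study convention: 8).
#' @return A [PlateLayoutSet-class].
#' @export
readPlateLayouts <- function(path, replicatesPerSample = 8L) {
  if (!file.exists(path)) .schemaError("layout file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .requireColumns(df, c("plate_id", "well", "sample_id", "role"),
                  "plate layout CSV")
  new("PlateLayoutSet",
      layout = df[, c("plate_id", "well", "sample_id", "role")],
      replicatesPerSample = as.integer(replicatesPerSample))
}

#' @rdname readPlateLayouts
#' @param x a [PlateLayoutSet-class].
#' @export
writePlateLayouts <- function(x, path) {
  stopifnot(is(x, "PlateLayoutSet"))
  write.csv(x@layout, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read standard-curve calibration points
#'
#' @param path CSV with columns `known_cells, rfu` and optionally
#'   `plate_id` and `sample_id` (the calibrated cell-line class).
#' @return data.frame with numeric `known_cells` and `rfu` (plus any
#'   identifying columns present).
#' @export
readStandardCurve <- function(path) {
  if (!file.exists(path)) .schemaError("standard-curve file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("known_cells", "rfu"), "standard-curve CSV")
  df$known_cells <- as.numeric(df$known_cells)
  df$rfu <- as.numeric(df$rfu)
  if (any(!is.finite(df$rfu)) || any(df$known_cells < 0, na.rm = TRUE))
    .validationError("standard-curve points must have finite rfu and known_cells >= 0")
  df
}

#' Read the twin/sibling pair manifest
#'
#' One row per pair: `pair_id, zygosity, sample_id_a, sample_id_b` plus any
#' covariate columns (`age`, `sex`, `ethnicity`, `growth_class`,
#' `transformation_time`). Zygosity tokens are parsed case-insensitively
#' (`mz`/`MZ`, `sib`/`SIB`; `DZ` is accepted as a synonym for `SIB`, full
#' siblings being treated as dizygotic twins). Missing covariates are kept
#' as `NA`, never imputed.
#'
#' @param path CSV path.
#' @return A [PairManifest-class].
#' @export
readPairManifest <- function(path) {
  if (!file.exists(path)) .schemaError("pair manifest not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("pair manifest '", path, "' contains no pairs")
    df <- data.frame(pair_id = character(), zygosity = character(),
                     sample_id_a = character(), sample_id_b = character(),
                     stringsAsFactors = FALSE)
    return(new("PairManifest", pairs = df))
  }
  .requireColumns(df, c("pair_id", "zygosity", "sample_id_a", "sample_id_b"),
                  "pair manifest CSV")
  zyg <- toupper(trimws(df$zygosity))
  zyg[zyg == "DZ"] <- "SIB"
  unknown <- !zyg %in% c("MZ", "SIB")
  if (any(unknown))
    .validationError("unknown zygosity token(s): %s",
                     .fmtSome(df$zygosity[unknown]))
  df$zygosity <- zyg
  ids <- c(df$sample_id_a, df$sample_id_b)
  if (anyDuplicated(ids))
    .validationError("sample(s) appear in more than one pair: %s",
                     .fmtSome(ids[duplicated(ids)]))
  new("PairManifest", pairs = df)
}

#' @rdname readPairManifest
#' @param x a [PairManifest-class].
#' @export
writePairManifest <- function(x, path) {
  stopifnot(is(x, "PairManifest"))
  write.csv(x@pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-check a study's readings, layouts and pairs
#'
#' Report-based validation of the assembled study: every paired sample must
#' have at least one `test` well carrying both a `pre_wash` and a `wash3`
#' reading (otherwise its adhesion cannot be quantified), and every plate
#' must declare at least one positive-control and one negative-control
#' well. All failures are collected; nothing raises on first error.
#'
#' @param readings a [PlateReadingSet-class].
#' @param layouts optional [PlateLayoutSet-class]; when supplied, its
#'   well/sample assignment is checked for agreement with the readings.
#' @param pairs optional [PairManifest-class].
#' @return A [ValidationReport-class].
#' @export
validateStudy <- function(readings, layouts = NULL, pairs = NULL) {
  stopifnot(is(readings, "PlateReadingSet"))
  df <- readings@readings
  issues <- list()
  addIssue <- function(category, id, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      category = category, id = id, message = message,
      stringsAsFactors = FALSE)

  for (pid in unique(df$plate_id)) {
    p <- df[df$plate_id == pid, ]
    if (!any(p$role == "positive_control"))
      addIssue("plate_controls", pid, "no positive-control wells on plate")
    if (!any(p$role == "negative_control"))
      addIssue("plate_controls", pid, "no negative-control wells on plate")
  }

  if (!is.null(layouts)) {
    stopifnot(is(layouts, "PlateLayoutSet"))
    lay <- layouts@layout
    keyR <- unique(paste(df$plate_id, df$well, df$sample_id, sep = "\r"))
    keyL <- paste(lay$plate_id, lay$well, lay$sample_id, sep = "\r")
    orphan <- !keyR %in% keyL
    if (any(orphan))
      addIssue("layout_mismatch", "readings",
               sprintf("wells read but absent from layout: %s",
                       .fmtSome(gsub("\r", "/", keyR[orphan]))))
  }

  if (!is.null(pairs)) {
    stopifnot(is(pairs, "PairManifest"))
    ids <- c(pairs@pairs$sample_id_a, pairs@pairs$sample_id_b)
    test <- df[df$role == "test", ]
    for (sid in ids) {
      s <- test[test$sample_id == sid, ]
      if (nrow(s) == 0L) {
        addIssue("missing_sample", sid, "paired sample has no test wells")
        next
      }
      wellKey <- paste(s$plate_id, s$well, sep = "\r")
      quantifiable <- any(vapply(unique(wellKey), function(k) {
        st <- s$read_stage[wellKey == k]
        all(c("pre_wash", "wash3") %in% st)
      }, logical(1)))
      if (!quantifiable)
        addIssue("unquantifiable", sid,
                 "no test well with both pre_wash and wash3 readings")
    }
  }

  issues <- if (length(issues)) do.call(rbind, issues)
            else data.frame(category = character(), id = character(),
                            message = character(), stringsAsFactors = FALSE)
  new("ValidationReport", ok = nrow(issues) == 0L, issues = issues)
}

#' Serialize a validation report to JSON
#'
#' @param report a [ValidationReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  stopifnot(is(report, "ValidationReport"))
  jsonlite::write_json(list(ok = report@ok, issues = report@issues),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
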