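#' Read a pipeline run configuration from YAML
#'
#' Recognized keys (all optional, with defaults):
#' \preformatted{
#' inputs:   {readings, layouts, standard_curves, pairs}   # file paths
#' output_dir: "lea-output"
#' qc:       {min_zprime: 0.5, max_cv_percent: 10}
#' quantification: {phenotype_scale: pct_input_rfu, curve_source: per_plate,
#'                  loaded_cells: 50000}
#' heritability:   {estimator: icc, scheme: individual, n_perm: 10000,
#'                  seed: 1, truncate_h2: false}
#' simulate: {...}   # GenerativeConfig fields for the simulate stage
#' }
#'
#' @param path YAML file path.
#' @return A named list (the run configuration) with defaults filled in
#'   and a `config_hash` attribute (MD5 of the canonical YAML).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .schemaError("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) .schemaError("config must be a YAML mapping")
  .fillConfigDefaults(cfg)
}

.fillConfigDefaults <- function(cfg) {
  defaults <- list(
    inputs = list(readings = NULL, layouts = NULL,
                  standard_curves = NULL, pairs = NULL),
    output_dir = "lea-output",
    qc = list(min_zprime = 0.5, max_cv_percent = 10),
    quantification = list(phenotype_scale = "pct_input_rfu",
                          curve_source = "per_plate", loaded_cells = 50000),
    heritability = list(estimator = "icc", scheme = "individual",
                        n_perm = 10000L, seed = 1L, truncate_h2 = FALSE),
    simulate = list())
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      for (kk in names(defaults[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
  }
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    .schemaError("unknown config key(s): %s", paste(unknown, collapse = ", "))
  attr(cfg, "config_hash") <- .configHash(cfg)
  cfg
}

# provenance hash: MD5 of the canonical (sorted-key) YAML rendering
.configHash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  canon <- function(x) {
    if (!is.list(x)) return(x)
    if (!is.null(names(x)) && length(x)) x <- x[order(names(x))]
    lapply(x, canon)
  }
  yaml::write_yaml(canon(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Run pipeline stages on a study
#'
#' Orchestrates the analysis in the assay's natural order:
#' `simulate` writes a synthetic fixture study; `qc` computes plate
#' quality-control reports; `quantify` produces the per-line phenotype
#' table; `heritability` runs the twin analysis; `run_all` chains
#' qc -> quantify -> heritability (after simulating first if no readings
#' path is configured). Every artifact embeds the config hash and seed.
#'
#' @param config a run-configuration list from [readRunConfig()], or a
#'   path to a YAML config file.
#' @param stage one of `"run_all"`, `"simulate"`, `"qc"`, `"quantify"`,
#'   `"heritability"`.
#' @return Invisibly, a list of the stage results
#'   (paths written, and the R objects: `qc`, `phenotypes`, `result`).
#' @seealso The thin command-line wrapper in
#'   `system.file("scripts", "lea-pipeline.R", package = "twinLEA")`.
#' @export
runPipeline <- function(config,
                        stage = c("run_all", "simulate", "qc", "quantify",
                                  "heritability")) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- readRunConfig(config)
  else config <- .fillConfigDefaults(config)
  hash <- attr(config, "config_hash")
  outDir <- config$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message(sprintf(...))
  t0 <- Sys.time()
  out <- list(config_hash = hash)

  if (stage == "simulate" ||
      (stage == "run_all" && is.null(config$inputs$readings))) {
    gcArgs <- config$simulate
    gcArgs$curveParams <- if (!is.null(gcArgs$curveParams))
      unlist(gcArgs$curveParams) else NULL
    gcArgs <- Filter(Negate(is.null), gcArgs)
    gcfg <- do.call(GenerativeConfig, gcArgs)
    fixDir <- file.path(outDir, "fixture")
    paths <- makeFixtureStudy(gcfg, fixDir)
    log("simulate: wrote fixture study to %s (seed %d)", fixDir, gcfg@seed)
    config$inputs$readings <- paths[["readings"]]
    config$inputs$layouts <- paths[["layouts"]]
    config$inputs$pairs <- paths[["pairs"]]
    out$fixture <- paths
    if (stage == "simulate") {
      out$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      return(invisible(out))
    }
  }

  for (key in c("readings")) {
    p <- config$inputs[[key]]
    if (is.null(p) || !file.exists(p))
      .schemaError("input '%s' missing or not found: %s", key,
                   if (is.null(p)) "<unset>" else p)
  }
  rds <- readPlateReadings(config$inputs$readings)
  layouts <- if (!is.null(config$inputs$layouts) &&
                 file.exists(config$inputs$layouts))
    readPlateLayouts(config$inputs$layouts) else NULL
  manifest <- if (!is.null(config$inputs$pairs) &&
                  file.exists(config$inputs$pairs))
    readPairManifest(config$inputs$pairs) else NULL

  report <- validateStudy(rds, layouts, manifest)
  writeValidationReport(report, file.path(outDir, "validation.json"))
  if (!report@ok)
    log("validation: %d issue(s); see validation.json", nrow(report@issues))

  if (stage %in% c("qc", "run_all", "quantify", "heritability")) {
    qc <- plateQC(rds, minZPrime = config$qc$min_zprime,
                  maxCVPercent = config$qc$max_cv_percent)
    writeQCReport(qc, file.path(outDir, "qc_report.json"), "json")
    writeQCReport(qc, file.path(outDir, "qc_report.tsv"), "tsv")
    out$qc <- qc
    log("qc: composite Z' = %.3f over %d plate(s)", qc$composite,
        length(qc) - 1L)
    if (stage == "qc") {
      out$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      return(invisible(out))
    }
  }

  phen <- quantifyAdhesion(rds, qc = out$qc,
                           loadedCells = config$quantification$loaded_cells,
                           curveSource = config$quantification$curve_source)
  writePhenotypeTable(phen, file.path(outDir, "phenotypes.tsv"))
  out$phenotypes <- phen
  log("quantify: %d cell line(s), mean %% input RFU %.2f",
      nrow(phen), mean(phen$pct_input_rfu_mean))
  if (stage == "quantify") {
    out$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    return(invisible(out))
  }

  if (is.null(manifest))
    .schemaError("heritability stage needs a pair manifest (inputs: pairs)")
  hcfg <- config$heritability
  result <- runHeritabilityAnalysis(
    phen, manifest,
    phenotypeScale = config$quantification$phenotype_scale,
    estimator = hcfg$estimator, scheme = hcfg$scheme,
    nPerm = hcfg$n_perm, seed = hcfg$seed, truncate = hcfg$truncate_h2,
    dropIncomplete = TRUE)
  resPath <- file.path(outDir, "heritability.json")
  writeHeritabilityResult(result, resPath)
  # append provenance: config hash alongside seed
  payload <- jsonlite::read_json(resPath)
  payload$config_hash <- hash
  jsonlite::write_json(payload, resPath, auto_unbox = TRUE, digits = NA)
  out$result <- result
  log("heritability: h2 = %.4f (p = %.4g, %d permutations)",
      result@h2, result@pEmpirical, result@nPerm)
  out$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  invisible(out)
}
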