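#' Accessors for twinLEA containers
#'
#' `readings()` returns the long-format reading table of a
#' [PlateReadingSet-class]; `layoutTable()` the well map of a
#' [PlateLayoutSet-class]; `pairTable()` the pair rows of a
#' [PairManifest-class]; `curveCoef()` the named `(a, d, c, b)` parameters
#' of a [FourPLCurve-class].
#'
#' @param x the object.
#' @return A data.frame (`readings`, `layoutTable`, `pairTable`) or a named
#'   numeric vector (`curveCoef`).
#' @aliases readings layoutTable pairTable curveCoef
#' @name accessors
#' @examples
#' cfg <- GenerativeConfig(nMZPairs = 2, nSIBPairs = 2, seed = 1)
#' sim <- simulatePairPhenotypes(cfg)
#' head(sim$samples)
NULL

#' @rdname accessors
#' @export
setGeneric("readings", function(x) standardGeneric("readings"))
#' @rdname accessors
#' @export
setMethod("readings", "PlateReadingSet", function(x) x@readings)

#' @rdname accessors
#' @export
setGeneric("layoutTable", function(x) standardGeneric("layoutTable"))
#' @rdname accessors
#' @export
setMethod("layoutTable", "PlateLayoutSet", function(x) x@layout)

#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname accessors
#' @export
setMethod("pairTable", "PairManifest", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("curveCoef", function(x) standardGeneric("curveCoef"))
#' @rdname accessors
#' @export
setMethod("curveCoef", "FourPLCurve",
          function(x) c(a = x@a, d = x@d, c = x@c, b = x@b))

#' Heritability result accessors
#'
#' @param x a [HeritabilityResult-class].
#' @return `h2()` the Falconer heritability fraction; `rMZ()`/`rSIB()` the
#'   group intra-pair correlations; `pEmpirical()` the permutation p-value;
#'   `nullDistribution()` the vector of permuted statistics.
#' @aliases h2 rMZ rSIB pEmpirical nullDistribution
#' @name heritability-accessors
NULL

#' @rdname heritability-accessors
#' @export
setGeneric("h2", function(x) standardGeneric("h2"))
#' @rdname heritability-accessors
#' @export
setMethod("h2", "HeritabilityResult", function(x) x@h2)

#' @rdname heritability-accessors
#' @export
setGeneric("rMZ", function(x) standardGeneric("rMZ"))
#' @rdname heritability-accessors
#' @export
setMethod("rMZ", "HeritabilityResult", function(x) x@rMZ)

#' @rdname heritability-accessors
#' @export
setGeneric("rSIB", function(x) standardGeneric("rSIB"))
#' @rdname heritability-accessors
#' @export
setMethod("rSIB", "HeritabilityResult", function(x) x@rSIB)

#' @rdname heritability-accessors
#' @export
setGeneric("pEmpirical", function(x) standardGeneric("pEmpirical"))
#' @rdname heritability-accessors
#' @export
setMethod("pEmpirical", "HeritabilityResult", function(x) x@pEmpirical)

#' @rdname heritability-accessors
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))
#' @rdname heritability-accessors
#' @export
setMethod("nullDistribution", "HeritabilityResult", function(x) x@nullH2)

setMethod("show", "PlateReadingSet", function(object) {
  df <- object@readings
  cat("PlateReadingSet with", nrow(df), "well readings\n")
  if (nrow(df)) {
    cat("  plates:   ", length(unique(df$plate_id)), "\n")
    cat("  samples:  ", length(unique(df$sample_id[df$role == "test"])),
        "test lines\n")
    cat("  stages:   ", paste(sort(unique(df$read_stage)), collapse = ", "),
        "\n")
  }
  invisible(NULL)
})

setMethod("show", "PlateLayoutSet", function(object) {
  cat("PlateLayoutSet:", length(unique(object@layout$plate_id)), "plate(s),",
      nrow(object@layout), "assigned wells,",
      object@replicatesPerSample, "replicates/sample\n")
  invisible(NULL)
})

setMethod("show", "PairManifest", function(object) {
  z <- table(factor(object@pairs$zygosity, levels = c("MZ", "SIB")))
  cat("PairManifest:", nrow(object@pairs), "pairs (",
      z[["MZ"]], "MZ,", z[["SIB"]], "SIB )\n")
  invisible(NULL)
})

setMethod("show", "FourPLCurve", function(object) {
  cat("FourPLCurve: f(x) = d + (a - d)/(1 + (x/c)^b)\n")
  cat(sprintf("  a = %.4g RFU, d = %.4g RFU, c = %.4g cells, b = %.4g\n",
              object@a, object@d, object@c, object@b))
  cat(sprintf("  fit: %d points, residual sd %.4g\n",
              object@nPoints, object@residualSD))
  invisible(NULL)
})

setMethod("show", "ControlSummary", function(object) {
  cat(sprintf(
    "ControlSummary: pos %.4g (sd %.4g, n=%d) | neg %.4g (sd %.4g, n=%d)\n",
    object@muPos, object@sdPos, object@nPos,
    object@muNeg, object@sdNeg, object@nNeg))
  invisible(NULL)
})

setMethod("show", "ValidationReport", function(object) {
  if (object@ok) cat("ValidationReport: OK (no issues)\n")
  else {
    cat("ValidationReport:", nrow(object@issues), "issue(s)\n")
    print(object@issues, row.names = FALSE)
  }
  invisible(NULL)
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport [plate %s]: Z' = %.3f, SNR = %.2f, %s\n",
              object@plateId, object@zprime, object@snr,
              if (object@passed) "PASSED" else "FAILED"))
  if (length(object@cvBySample))
    cat(sprintf("  per-sample CV%%: median %.2f, max %.2f (n = %d samples)\n",
                median(object@cvBySample), max(object@cvBySample),
                length(object@cvBySample)))
  invisible(NULL)
})

setMethod("show", "HeritabilityResult", function(object) {
  cat("HeritabilityResult (twin design)\n")
  cat(sprintf("  r_MZ = %.4f, r_SIB = %.4f  [%s estimator]\n",
              object@rMZ, object@rSIB, object@estimator))
  cat(sprintf("  h2 = %.4f (%.2f%%)%s\n", object@h2, 100 * object@h2,
              if (object@h2OutOfRange) "  [outside [0,1]]" else ""))
  cat(sprintf("  empirical p = %.4g (%d permutations, scheme '%s', seed %d)\n",
              object@pEmpirical, object@nPerm, object@scheme, object@seed))
  invisible(NULL)
})

setMethod("show", "GenerativeConfig", function(object) {
  cat("GenerativeConfig:\n")
  cat(sprintf("  pairs: %d MZ + %d SIB; h2 = %.4f, c2 = %.4f\n",
              object@nMZPairs, object@nSIBPairs, object@h2, object@c2))
  cat(sprintf("  phenotype: mean %.2f%%, sd %.2f%%; replicate CV %.2f%%\n",
              object@phenotypeMean, object@phenotypeSD, object@replicateCV))
  cat(sprintf("  controls: pos %.1f%%, neg %.1f%%; %d reps/sample; seed %d\n",
              object@posControlMean, object@negControlMean,
              object@replicatesPerSample, object@seed))
  invisible(NULL)
})

#' @importFrom stats median
NULL
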