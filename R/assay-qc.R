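#' Replicate coefficient of variation
#'
#' CV (%) of a set of technical replicate measurements:
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation.
#' Scale-invariant (multiplying all replicates by a positive constant
#' leaves it unchanged) but not shift-invariant.
#'
#' @param values numeric vector of at least two finite measurements with
#'   non-zero mean.
#' @return CV in percent.
#' @examples
#' coefficientOfVariation(c(90, 100, 110))  # 10
#' @export
coefficientOfVariation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values)))
    .domainError("CV needs >= 2 finite replicate values (got %d)",
                 sum(is.finite(values)))
  m <- mean(values)
  if (m == 0) .domainError("CV is undefined for replicates with mean 0")
  100 * sd(values) / m
}

#' Summarize a plate's control wells
#'
#' @param pos,neg numeric vectors of positive-control (high-adhesion) and
#'   negative-control (low-adhesion) well signals on a common scale (raw
#'   RFU or derived adhesion %). At least two wells per control are needed
#'   for the standard deviations to be defined.
#' @return A [ControlSummary-class].
#' @export
controlSummary <- function(pos, neg) {
  pos <- as.numeric(pos); neg <- as.numeric(neg)
  if (length(pos) < 1L || length(neg) < 1L)
    .domainError("both control groups must be non-empty")
  new("ControlSummary",
      muPos = mean(pos), sdPos = if (length(pos) >= 2L) sd(pos) else NA_real_,
      muNeg = mean(neg), sdNeg = if (length(neg) >= 2L) sd(neg) else NA_real_,
      nPos = length(pos), nNeg = length(neg))
}

#' Z'-factor of a screening assay
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mu_pos - mu_neg|`, the
#' Zhang-Chung-Oldenburg screening-window coefficient. At most 1 by
#' construction; `Z' = 0.5` corresponds exactly to a 12-standard-deviation
#' separation between the control bands when the two control sds are equal.
#' Values above 0.5 indicate an excellent assay. Invariant under any affine
#' rescaling `x -> a x + b` (`a != 0`) of both control signals.
#'
#' @param controls a [ControlSummary-class] with defined sds and distinct
#'   control means.
#' @return The Z'-factor (dimensionless, `<= 1`).
#' @examples
#' zPrime(controlSummary(pos = c(390, 400, 410), neg = c(95, 100, 105)))
#' @export
zPrime <- function(controls) {
  stopifnot(is(controls, "ControlSummary"))
  if (is.na(controls@sdPos) || is.na(controls@sdNeg))
    .domainError("Z' needs >= 2 wells per control for sds to be defined")
  sep <- abs(controls@muPos - controls@muNeg)
  if (sep == 0)
    .domainError("Z' is undefined: positive and negative control means coincide")
  1 - 3 * (controls@sdPos + controls@sdNeg) / sep
}

#' Signal-to-noise ratio of the control separation
#'
#' Default definition (classic screening S/N):
#' `(mu_pos - mu_neg) / sd_neg`. The alternative `"pooled"` method uses
#' `(mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2)`.
#'
#' @param controls a [ControlSummary-class].
#' @param method `"neg_sd"` (default) or `"pooled"`.
#' @return The dimensionless ratio.
#' @export
signalToNoise <- function(controls, method = c("neg_sd", "pooled")) {
  stopifnot(is(controls, "ControlSummary"))
  method <- match.arg(method)
  denom <- switch(method,
    neg_sd = controls@sdNeg,
    pooled = sqrt(controls@sdPos^2 + controls@sdNeg^2))
  if (is.na(denom) || denom == 0)
    .domainError("SNR is undefined: control sd is zero or undefined")
  (controls@muPos - controls@muNeg) / denom
}

#' Composite Z'-factor across plates
#'
#' Pools all positive-control wells and all negative-control wells across
#' plates (exact pooled means and sds reconstructed from the per-plate
#' summaries) and applies [zPrime()] to the pooled summary, giving a single
#' study-level robustness score. Between-plate drift in the control means
#' inflates the pooled sds, so the composite is never better than the
#' plates individually suggest.
#'
#' @param perPlate list of [ControlSummary-class], one per plate. Plates
#'   lacking either control (fewer than 2 wells for a sd) contribute
#'   nothing; all plates unusable is an error.
#' @return The composite Z'-factor.
#' @export
compositeZPrime <- function(perPlate) {
  if (is(perPlate, "ControlSummary")) perPlate <- list(perPlate)
  usable <- Filter(function(s) is(s, "ControlSummary") &&
                     s@nPos >= 2L && s@nNeg >= 2L &&
                     is.finite(s@sdPos) && is.finite(s@sdNeg), perPlate)
  if (length(usable) == 0L)
    .domainError("no plate contributed both controls with >= 2 wells")
  pool <- function(mu, s, n) {
    N <- sum(n)
    m <- sum(n * mu) / N
    # total SS = within SS + between SS, exactly
    ss <- sum((n - 1) * s^2) + sum(n * (mu - m)^2)
    c(mu = m, sd = sqrt(ss / (N - 1)), n = N)
  }
  p <- pool(vapply(usable, slot, numeric(1), "muPos"),
            vapply(usable, slot, numeric(1), "sdPos"),
            vapply(usable, function(x) as.numeric(x@nPos), numeric(1)))
  n <- pool(vapply(usable, slot, numeric(1), "muNeg"),
            vapply(usable, slot, numeric(1), "sdNeg"),
            vapply(usable, function(x) as.numeric(x@nNeg), numeric(1)))
  zPrime(new("ControlSummary",
             muPos = p[["mu"]], sdPos = p[["sd"]], nPos = as.integer(p[["n"]]),
             muNeg = n[["mu"]], sdNeg = n[["sd"]], nNeg = as.integer(n[["n"]])))
}

#' Plate- and study-level assay QC
#'
#' For every plate: per-sample replicate CV on the % input RFU scale,
#' Z'-factor and signal-to-noise ratio from the plate's control wells, and
#' pass/fail gating against the configured thresholds (defaults: `Z' >=
#' 0.5` and plate median per-sample CV `<= 10%`, the convention of
#' replicate variability well under 10%). The gate uses the plate-level
#' median because individual sample CVs at 8 replicates scatter widely
#' around the true replicate noise; the full per-sample CV distribution is
#' reported in each [QCReport-class] rather than reduced to one scalar.
#'
#' @param x a [PlateReadingSet-class] with `pre_wash` and `wash3` readings.
#' @param minZPrime,maxCVPercent QC gates.
#' @return A list with one [QCReport-class] per plate (named by plate id)
#'   and a `composite` element: the study-wide composite Z'-factor (or `NA`
#'   if no plate had usable controls).
#' @seealso [percentInputRFU()], [compositeZPrime()]
#' @export
plateQC <- function(x, minZPrime = 0.5, maxCVPercent = 10) {
  stopifnot(is(x, "PlateReadingSet"))
  wellPct <- .perWellPercentInput(x)
  reports <- list()
  summaries <- list()
  for (pid in unique(wellPct$plate_id)) {
    p <- wellPct[wellPct$plate_id == pid, ]
    cvs <- vapply(split(p$pct_input[p$role == "test"],
                        p$sample_id[p$role == "test"]),
                  function(v) if (length(v) >= 2L) coefficientOfVariation(v)
                              else NA_real_,
                  numeric(1))
    cvs <- cvs[!is.na(cvs)]
    pos <- p$pct_input[p$role == "positive_control"]
    neg <- p$pct_input[p$role == "negative_control"]
    zp <- snr <- NA_real_
    if (length(pos) >= 2L && length(neg) >= 2L) {
      cs <- controlSummary(pos, neg)
      zp <- zPrime(cs)
      snr <- signalToNoise(cs)
      summaries[[pid]] <- cs
    }
    passed <- isTRUE(zp >= minZPrime) &&
      (length(cvs) == 0L || median(cvs) <= maxCVPercent)
    reports[[pid]] <- new("QCReport", plateId = pid, cvBySample = cvs,
                          zprime = zp, snr = snr, passed = passed,
                          thresholds = list(min_zprime = minZPrime,
                                            max_cv_percent = maxCVPercent))
  }
  composite <- if (length(summaries)) compositeZPrime(summaries) else NA_real_
  c(reports, list(composite = composite))
}

# per-well % input RFU for every well with both pre_wash and wash3 readings
.perWellPercentInput <- function(x) {
  df <- x@readings
  pre <- df[df$read_stage == "pre_wash", ]
  post <- df[df$read_stage == "wash3", ]
  key <- function(d) paste(d$plate_id, d$well, sep = "\r")
  idx <- match(key(post), key(pre))
  keep <- !is.na(idx) & pre$rfu[idx] > 0
  post <- post[keep, ]
  data.frame(plate_id = post$plate_id, well = post$well,
             sample_id = post$sample_id, role = post$role,
             pct_input = 100 * post$rfu / pre$rfu[idx[keep]],
             stringsAsFactors = FALSE)
}

#' Write QC reports as JSON or TSV
#'
#' @param qc result of [plateQC()].
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeQCReport <- function(qc, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  plates <- Filter(function(r) is(r, "QCReport"), qc)
  rows <- lapply(plates, function(r)
    data.frame(plate_id = r@plateId, zprime = r@zprime, snr = r@snr,
               n_samples = length(r@cvBySample),
               median_cv = if (length(r@cvBySample)) median(r@cvBySample) else NA,
               max_cv = if (length(r@cvBySample)) max(r@cvBySample) else NA,
               passed = r@passed, stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(
      plates = lapply(plates, function(r)
        list(plate_id = r@plateId, zprime = r@zprime, snr = r@snr,
             cv_by_sample = as.list(r@cvBySample), passed = r@passed,
             thresholds = r@thresholds)),
      composite_zprime = qc$composite)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
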