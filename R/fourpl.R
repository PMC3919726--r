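#' Fit a four-parameter logistic standard curve
#'
#' Least-squares fit of `f(x) = d + (a - d) / (1 + (x/c)^b)` to calibration
#' points (known cells/well, measured RFU), the standard model for
#' fluorescence standard curves. The fit is deterministic: starting values
#' follow a fixed rule (`a`, `d` from the min/max observed RFU, `c` from
#' the geometric midpoint of the positive cell range, `b = 1`), and the
#' Levenberg-Marquardt optimizer does the rest.
#'
#' @param knownCells numeric, cells/well of each calibration point; at
#'   least 4 distinct values required.
#' @param rfu numeric, measured fluorescence at each point; finite.
#' @return A [FourPLCurve-class] with fit diagnostics (residual sd, number
#'   of points).
#' @examples
#' x <- c(500, 1500, 5000, 15000, 50000)
#' curve <- fitFourPL(x, 5000 + (100 - 5000) / (1 + (x / 2e4)^1.5))
#' curveCoef(curve)
#' @export
fitFourPL <- function(knownCells, rfu) {
  x <- as.numeric(knownCells); y <- as.numeric(rfu)
  if (length(x) != length(y)) .domainError("knownCells and rfu lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4L)
    .domainError("4PL fit needs >= 4 distinct cell concentrations (got %d)",
                 length(unique(x)))
  xp <- x[x > 0]
  start <- list(a = min(y), d = max(y),
                c = exp(mean(log(range(xp)))), b = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b),
                      start = start,
                      lower = c(a = -Inf, d = -Inf, c = .Machine$double.eps,
                                b = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      .domainError("4PL fit failed to converge (start a=%.4g d=%.4g c=%.4g b=1): %s",
                   start$a, start$d, start$c, conditionMessage(e)))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  rsd <- if (length(res) > 4L) sqrt(sum(res^2) / (length(res) - 4L)) else 0
  new("FourPLCurve", a = unname(cf["a"]), d = unname(cf["d"]),
      c = unname(cf["c"]), b = unname(cf["b"]),
      residualSD = rsd, nPoints = length(x))
}

#' Evaluate a four-parameter logistic curve
#'
#' @param curve a [FourPLCurve-class].
#' @param cells numeric, cells/well (non-negative).
#' @return Predicted RFU, same length as `cells`. `f(c) = (a + d)/2`: the
#'   inflection point maps to the midpoint of the asymptotes.
#' @export
evalFourPL <- function(curve, cells) {
  stopifnot(is(curve, "FourPLCurve"))
  cells <- as.numeric(cells)
  if (any(cells < 0, na.rm = TRUE)) .domainError("cells must be non-negative")
  curve@d + (curve@a - curve@d) / (1 + (cells / curve@c)^curve@b)
}

#' Invert a four-parameter logistic curve
#'
#' Closed-form unique preimage
#' `x = c * ((a - d)/(y - d) - 1)^(1/b)` of an observed fluorescence `y`
#' strictly between the curve's asymptotes. No extrapolation: values at or
#' beyond an asymptote are refused, naming the violated asymptote.
#'
#' @param curve a [FourPLCurve-class].
#' @param observedRfu numeric, RFU strictly inside the open interval
#'   between `a` and `d`.
#' @return Cells/well, same length as `observedRfu`;
#'   `invertFourPL(curve, evalFourPL(curve, x)) == x` to numerical
#'   tolerance.
#' @export
invertFourPL <- function(curve, observedRfu) {
  stopifnot(is(curve, "FourPLCurve"))
  y <- as.numeric(observedRfu)
  lo <- min(curve@a, curve@d); hi <- max(curve@a, curve@d)
  if (any(y <= lo))
    .domainError("RFU %.6g is at or below the zero-cell/lower asymptote (%.6g); cannot invert",
                 min(y), lo)
  if (any(y >= hi))
    .domainError("RFU %.6g is at or above the saturation/upper asymptote (%.6g); cannot invert",
                 max(y), hi)
  curve@c * ((curve@a - curve@d) / (y - curve@d) - 1)^(1 / curve@b)
}
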