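## One-site saturation binding and ligase-mediated circularization
## kinetics. Kd is reported in the same as-supplied units as the probe
## amounts; the paper-style readouts carry no absolute concentration
## scale, so no unit conversion is attempted.

#' Fit a one-site saturation isotherm (Bmax, Kd)
#'
#' Nonlinear least squares of `bound = bmax * x / (kd + x)` via
#' Levenberg-Marquardt, with deterministic initialization:
#' `bmax0 = max(signal)` and `kd0` = the probe amount at half-maximal
#' signal, by linear interpolation. When the fitted curve is still rising
#' at the largest probe amount at more than 90% of its initial slope the
#' data do not constrain saturation; the fit is returned with
#' `nonSaturating = TRUE`.
#'
#' @param series a [BindingSeries-class] (>= 5 points, strictly increasing
#'   probe amounts).
#' @return a [BindingFit-class].
#' @examples
#' x <- c(0.5, 1, 2, 4, 8, 16, 32)
#' fitSaturation(BindingSeries(x, x / (4.515 + x), "N10"))
#' @export
fitSaturation <- function(series) {
  stopifnot(is(series, "BindingSeries"))
  pts <- series@points
  x <- pts$probeAmount
  y <- pts$boundSignal
  if (all(y == 0))
    stop("degenerate data: all-zero bound signal")
  bmax0 <- max(y)
  half <- bmax0 / 2
  kd0 <- if (any(y >= half) && any(y < half)) {
    stats::approx(y, x, xout = half, ties = mean)$y
  } else {
    stats::median(x)
  }
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(x)
  fit <- minpack.lm::nlsLM(
    y ~ bmax * x / (kd + x),
    start = list(bmax = bmax0, kd = kd0),
    lower = c(bmax = 1e-12, kd = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  ## slope of the fitted curve: bmax*kd/(kd+x)^2; at x=0 it is bmax/kd
  slopeRatio <- (cf[["kd"]] / (cf[["kd"]] + max(x)))^2
  new("BindingFit", bmax = cf[["bmax"]], kd = cf[["kd"]],
      rss = sum(stats::resid(fit)^2),
      nonSaturating = slopeRatio > 0.9)
}

#' Fit first-order circularization kinetics
#'
#' Nonlinear least squares of
#' `pct(t) = plateau * (1 - exp(-k * t))` summarizing a minicircle
#' formation time course. A constant series returns rate 0 with the
#' plateau at that constant level. A series that falls appreciably after
#' its maximum is flagged `nonMonotone` (the first-order model is then
#' only a summary).
#'
#' @param series a [CircularizationSeries-class] with >= 4 time points
#'   including t = 0.
#' @return a [RateFit-class].
#' @examples
#' t <- seq(0, 60, 10)
#' fitCircularization(
#'   CircularizationSeries(t, 80 * (1 - exp(-0.1 * t))))
#' @export
fitCircularization <- function(series) {
  stopifnot(is(series, "CircularizationSeries"))
  pts <- series@points
  tt <- pts$time
  y <- pts$minicirclePct
  if (any(y < 0)) stop("minicircle percent must be >= 0")
  if (nrow(pts) < 4L)
    stop("insufficient data: need >= 4 time points")
  if (!any(tt == 0))
    stop("time course must include t = 0")
  nonMono <- y[length(y)] < 0.9 * max(y[-length(y)])
  if (max(y) - min(y) < .Machine$double.eps^0.5)
    return(new("RateFit", rateK = 0, plateauPct = y[1], rss = 0,
               nonMonotone = FALSE))
  plateau0 <- max(y)
  ## k0 from the time nearest half-plateau: pct = plateau/2 at t = ln2/k
  iHalf <- which.min(abs(y - plateau0 / 2))
  k0 <- if (tt[iHalf] > 0) log(2) / tt[iHalf] else 0.05
  fit <- minpack.lm::nlsLM(
    y ~ plateau * (1 - exp(-k * tt)),
    start = list(plateau = plateau0, k = k0),
    lower = c(plateau = 0, k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  new("RateFit", rateK = cf[["k"]], plateauPct = cf[["plateau"]],
      rss = sum(stats::resid(fit)^2), nonMonotone = nonMono)
}

#' Compare in-phase and out-of-phase circularization rates
#'
#' @param inFit [RateFit-class] for the in-phase probe.
#' @param outFit [RateFit-class] for the out-of-phase probe.
#' @return list with `ratio` (`rateK(in) / rateK(out)`, `Inf` when the
#'   out-of-phase rate is 0 and the in-phase rate is not) and `verdict`
#'   (`"in>out"`, `"equal"` or `"out>in"`).
#' @examples
#' comparePhaseRates(new("RateFit", rateK = 0.2, plateauPct = 75,
#'                       rss = 0, nonMonotone = FALSE),
#'                   new("RateFit", rateK = 0.1, plateauPct = 55,
#'                       rss = 0, nonMonotone = FALSE))
#' @export
comparePhaseRates <- function(inFit, outFit) {
  stopifnot(is(inFit, "RateFit"), is(outFit, "RateFit"))
  kin <- inFit@rateK
  kout <- outFit@rateK
  ratio <- if (kout == 0) {
    if (kin == 0) 1 else Inf
  } else kin / kout
  verdict <- if (ratio > 1) "in>out" else if (ratio < 1) "out>in" else "equal"
  list(ratio = ratio, verdict = verdict)
}
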