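#' Construct a PermutationSeries
#'
#' @param lanes data.frame with columns `enzyme` (optional), `siteCenter`,
#'   `freeMigration`, `complexMigration`.
#' @param probeLength probe length in bp (identical across lanes).
#' @return a [PermutationSeries-class] object.
#' @examples
#' lanes <- data.frame(siteCenter = c(23, 80, 150, 207),
#'                     freeMigration = 10,
#'                     complexMigration = c(6.1, 5.6, 6.0, 7.4))
#' PermutationSeries(lanes, probeLength = 230)
#' @export
PermutationSeries <- function(lanes, probeLength) {
  lanes <- as.data.frame(lanes)
  if (is.null(lanes$enzyme))
    lanes$enzyme <- paste0("lane", seq_len(nrow(lanes)))
  new("PermutationSeries", probeLength = as.numeric(probeLength),
      lanes = lanes)
}

#' Construct a PhasingSeries
#'
#' When `spacing` is absent it is derived from `linker` via
#' [spacingFromLinker()].
#'
#' @param lanes data.frame with columns `linker` and/or `spacing`, plus
#'   `freeMigration`, `complexMigration`.
#' @return a [PhasingSeries-class] object.
#' @export
PhasingSeries <- function(lanes) {
  lanes <- as.data.frame(lanes)
  if (is.null(lanes$spacing)) {
    if (is.null(lanes$linker))
      stop("lanes must contain a 'spacing' or a 'linker' column")
    lanes$spacing <- spacingFromLinker(lanes$linker)
  }
  new("PhasingSeries", lanes = lanes)
}

#' Construct a BindingSeries
#'
#' @param probeAmount probe amounts (as-supplied concentration units),
#'   strictly increasing.
#' @param boundSignal bound-probe signal (arbitrary intensity units).
#' @param label probe label (`"N10"`, `"SRE"`, ...).
#' @return a [BindingSeries-class] object.
#' @export
BindingSeries <- function(probeAmount, boundSignal, label = "other") {
  new("BindingSeries",
      points = data.frame(probeAmount = as.numeric(probeAmount),
                          boundSignal = as.numeric(boundSignal)),
      label = label)
}

#' Construct a CircularizationSeries
#'
#' @param time time points in minutes.
#' @param minicirclePct minicircle formation, percent of the no-protein
#'   control.
#' @param phaseLabel `"in_phase"` or `"out_of_phase"`.
#' @param proteinPresent logical.
#' @return a [CircularizationSeries-class] object.
#' @export
CircularizationSeries <- function(time, minicirclePct,
                                  phaseLabel = "in_phase",
                                  proteinPresent = TRUE) {
  new("CircularizationSeries",
      points = data.frame(time = as.numeric(time),
                          minicirclePct = as.numeric(minicirclePct)),
      phaseLabel = phaseLabel, proteinPresent = proteinPresent)
}

#' Simulation configuration with seeded ground truth
#'
#' Bundles the seed, per-assay Gaussian noise levels and the true
#' parameters used by the generators. Defaults emulate the study design:
#' an N10-class bend of 93 degrees centered mid-probe with maximal relative
#' mobility 0.8; a phasing profile with mobility minimum at 55 bp spacing
#' and helical repeat 10.5 bp/turn; one-site binding with bmax 1 and
#' Kd 4.515; circularization rates k_in = 0.10/min > k_out = 0.05/min.
#' Any `truth` entry can be overridden individually.
#'
#' @param seed single integer seed.
#' @param sigmaMobility noise SD on relative mobility (default 0.005).
#' @param sigmaBinding noise SD on bound signal as fraction of bmax
#'   (default 0.02).
#' @param sigmaCirc noise SD on minicircle percent, percentage points
#'   (default 2).
#' @param truth named list overriding any default truth parameter.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1, truth = list(bendAngleDeg = 41))
#' simTruth(cfg)$bendAngleDeg
#' @export
simulationConfig <- function(seed = 1L, sigmaMobility = 0.005,
                             sigmaBinding = 0.02, sigmaCirc = 2,
                             truth = list()) {
  default <- list(
    bendAngleDeg = 93, bendCenter = NA_real_, muE = 0.8,
    baseline = 0.6, amplitude = 0.1, s0 = 55, helicalRepeat = 10.5,
    bmax = 1, kd = 4.515,
    kIn = 0.10, kOut = 0.05, plateauIn = 75, plateauOut = 55)
  stopifnot(is.list(truth))
  default[names(truth)] <- truth
  new("SimulationConfig", seed = as.integer(seed),
      sigmaMobility = sigmaMobility, sigmaBinding = sigmaBinding,
      sigmaCirc = sigmaCirc, truth = default)
}

## ---- accessors -----------------------------------------------------------

#' Accessors for fit and series objects
#'
#' `bendAngle()` returns the fitted bend angle in degrees; `bendCenter()`
#' the bp position of the mobility minimum; `mobilityExtremes()` the fitted
#' (muM, muE) pair; `inPhaseSpacing()` the spacing of the phasing minimum;
#' `kdValue()` and `bmaxValue()` the saturation-fit parameters;
#' `rateConstant()` the first-order circularization rate; `lanes()` the
#' lane table of a series; `simTruth()` the truth list of a
#' [SimulationConfig-class].
#'
#' @param object a fitted or series object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bendAngle", function(object) standardGeneric("bendAngle"))
#' @rdname accessors
#' @export
setMethod("bendAngle", "BendFit", function(object) object@bendAngleDeg)

#' @rdname accessors
#' @export
setGeneric("bendCenter", function(object) standardGeneric("bendCenter"))
#' @rdname accessors
#' @export
setMethod("bendCenter", "BendFit", function(object) object@bendCenter)

#' @rdname accessors
#' @export
setGeneric("mobilityExtremes",
           function(object) standardGeneric("mobilityExtremes"))
#' @rdname accessors
#' @export
setMethod("mobilityExtremes", "BendFit",
          function(object) c(muM = object@muM, muE = object@muE))

#' @rdname accessors
#' @export
setGeneric("inPhaseSpacing",
           function(object) standardGeneric("inPhaseSpacing"))
#' @rdname accessors
#' @export
setMethod("inPhaseSpacing", "PhasingFit",
          function(object) object@inPhaseSpacing)

#' @rdname accessors
#' @export
setGeneric("kdValue", function(object) standardGeneric("kdValue"))
#' @rdname accessors
#' @export
setMethod("kdValue", "BindingFit", function(object) object@kd)

#' @rdname accessors
#' @export
setGeneric("bmaxValue", function(object) standardGeneric("bmaxValue"))
#' @rdname accessors
#' @export
setMethod("bmaxValue", "BindingFit", function(object) object@bmax)

#' @rdname accessors
#' @export
setGeneric("rateConstant", function(object) standardGeneric("rateConstant"))
#' @rdname accessors
#' @export
setMethod("rateConstant", "RateFit", function(object) object@rateK)

#' @rdname accessors
#' @export
setGeneric("lanes", function(object) standardGeneric("lanes"))
#' @rdname accessors
#' @export
setMethod("lanes", "PermutationSeries", function(object) object@lanes)
#' @rdname accessors
#' @export
setMethod("lanes", "PhasingSeries", function(object) object@lanes)

#' @rdname accessors
#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setMethod("simTruth", "SimulationConfig", function(object) object@truth)

## ---- show methods --------------------------------------------------------

setMethod("show", "MotifPattern", function(object) {
  cons <- vapply(object@positions, function(p)
    if (length(p) == 1L) p else sprintf("(%s)", paste(p, collapse = "/")),
    character(1))
  cat(sprintf("MotifPattern '%s' (length %d, maxAtypical %d): %s\n",
              object@name, length(object@positions), object@maxAtypical,
              paste(cons, collapse = "")))
})

setMethod("show", "PermutationSeries", function(object) {
  cat(sprintf("PermutationSeries: %d lanes, probe length %g bp\n",
              nrow(object@lanes), object@probeLength))
})

setMethod("show", "BendFit", function(object) {
  cat(sprintf(
    "BendFit: muM = %.4f, muE = %.4f, bend center = %s bp, angle = %.1f deg (rss %.3g)\n",
    object@muM, object@muE,
    if (is.na(object@bendCenter)) "NA" else sprintf("%.1f", object@bendCenter),
    object@bendAngleDeg, object@rss))
})

setMethod("show", "PhasingSeries", function(object) {
  cat(sprintf("PhasingSeries: %d lanes, spacings %g-%g bp\n",
              nrow(object@lanes), min(object@lanes$spacing),
              max(object@lanes$spacing)))
})

setMethod("show", "PhasingFit", function(object) {
  cat(sprintf(
    "PhasingFit: baseline %.4f, amplitude %.4f, in-phase spacing %s bp (%s turns at %.2f bp/turn, rss %.3g)\n",
    object@baseline, object@amplitude,
    if (is.na(object@inPhaseSpacing)) "NA"
    else sprintf("%.2f", object@inPhaseSpacing),
    if (is.na(object@turnsAtMin)) "NA" else sprintf("%.1f", object@turnsAtMin),
    object@helicalRepeat, object@rss))
})

setMethod("show", "BindingSeries", function(object) {
  cat(sprintf("BindingSeries '%s': %d points, probe amount %g-%g\n",
              object@label, nrow(object@points),
              min(object@points$probeAmount),
              max(object@points$probeAmount)))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit: bmax = %.4g, Kd = %.4g (rss %.3g)%s\n",
              object@bmax, object@kd, object@rss,
              if (object@nonSaturating) " [warning: non-saturating data]"
              else ""))
})

setMethod("show", "CircularizationSeries", function(object) {
  cat(sprintf("CircularizationSeries (%s%s): %d time points, %g-%g min\n",
              object@phaseLabel,
              if (object@proteinPresent) "" else ", no protein",
              nrow(object@points), min(object@points$time),
              max(object@points$time)))
})

setMethod("show", "RateFit", function(object) {
  cat(sprintf("RateFit: k = %.4g /min, plateau = %.4g%% (rss %.3g)%s\n",
              object@rateK, object@plateauPct, object@rss,
              if (object@nonMonotone) " [warning: non-monotone series]"
              else ""))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: seed %d, sigma(mobility) %g, sigma(binding) %g, sigma(circ) %g\n",
    object@seed, object@sigmaMobility, object@sigmaBinding,
    object@sigmaCirc))
})
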