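#' @import methods
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' MotifPattern: a degenerate CArG-box consensus
#'
#' A consensus pattern is a list of allowed-base sets, one per position,
#' plus a default mismatch ("atypical base") budget used when scanning.
#'
#' @slot name pattern label, one of `"canonical"`, `"srf_like"`,
#'   `"n10_like"`, `"intermediate"`.
#' @slot positions list of character vectors; element `j` is the set of
#'   bases allowed at position `j`.
#' @slot maxAtypical non-negative integer; default mismatch budget for
#'   "atypical" calls.
#'
#' @seealso [builtinPatterns()], [scanSequence()]
#' @export
setClass("MotifPattern",
  representation(name = "character", positions = "list",
                 maxAtypical = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L ||
        !object@name %in% c("canonical", "srf_like", "n10_like",
                            "intermediate"))
      msg <- c(msg, "'name' must be one of canonical, srf_like, n10_like, intermediate")
    ok <- vapply(object@positions, function(p) {
      length(p) >= 1L && all(p %in% DNA_BASES4) && !anyDuplicated(p)
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "every position set must be a nonempty subset of {A,C,G,T}")
    if (length(object@maxAtypical) != 1L || is.na(object@maxAtypical) ||
        object@maxAtypical < 0L)
      msg <- c(msg, "'maxAtypical' must be a single integer >= 0")
    if (object@name %in% c("canonical", "n10_like", "srf_like") &&
        length(object@positions) != 10L)
      msg <- c(msg, sprintf("pattern '%s' must have length 10", object@name))
    if (length(msg)) msg else TRUE
  })

#' PermutationSeries: circular-permutation EMSA lane table
#'
#' One lane per restriction digest: probes of identical length carry the
#' binding site at a different position; the complex migration varies with
#' the position of the induced bend.
#'
#' @slot probeLength probe length in bp, identical for all lanes.
#' @slot lanes data.frame with columns `enzyme`, `siteCenter` (bp from the
#'   probe 5' end to the binding-site center), `freeMigration` and
#'   `complexMigration` (gel migration distances, arbitrary units,
#'   larger = faster).
#'
#' @seealso [fitPermutation()], [genPermutationSeries()]
#' @export
setClass("PermutationSeries",
  representation(probeLength = "numeric", lanes = "data.frame"),
  validity = function(object) {
    msg <- character()
    L <- object@probeLength
    if (length(L) != 1L || !is.finite(L) || L <= 0)
      msg <- c(msg, "'probeLength' must be a single positive number")
    need <- c("siteCenter", "freeMigration", "complexMigration")
    miss <- setdiff(need, names(object@lanes))
    if (length(miss))
      return(sprintf("lanes is missing column(s): %s",
                     paste(miss, collapse = ", ")))
    ln <- object@lanes
    if (any(ln$siteCenter <= 0 | ln$siteCenter >= L))
      msg <- c(msg, "all siteCenter values must lie strictly inside (0, probeLength)")
    if (anyDuplicated(ln$siteCenter))
      msg <- c(msg, "siteCenter values must be distinct")
    if (any(ln$freeMigration <= 0) || any(ln$complexMigration <= 0))
      msg <- c(msg, "migrations must be > 0")
    if (any(ln$complexMigration > ln$freeMigration))
      msg <- c(msg, "complexMigration must not exceed freeMigration")
    if (length(msg)) msg else TRUE
  })

#' BendFit: result of circular-permutation cosine fitting
#'
#' @slot muM minimum relative mobility (slowest complex, dimensionless).
#' @slot muE maximum relative mobility (fastest complex).
#' @slot bendCenter bp position of the mobility minimum; `NA` for a flat
#'   profile (no bend).
#' @slot bendAngleDeg induced bend angle alpha in degrees, from
#'   muM/muE = cos(alpha/2).
#' @slot probeLength probe length in bp.
#' @slot rss residual sum of squares of the cosine fit.
#' @export
setClass("BendFit",
  representation(muM = "numeric", muE = "numeric", bendCenter = "numeric",
                 bendAngleDeg = "numeric", probeLength = "numeric",
                 rss = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@muM > 0 && object@muM <= object@muE))
      msg <- c(msg, "must have 0 < muM <= muE")
    if (object@bendAngleDeg < 0 || object@bendAngleDeg >= 180)
      msg <- c(msg, "bendAngleDeg must lie in [0, 180)")
    if (length(msg)) msg else TRUE
  })

#' PhasingSeries: helical phasing EMSA lane table
#'
#' Lanes differ in the linker (hence helical spacing) between an intrinsic
#' A-tract bend and the protein-induced bend at the CArG/N10 site.
#'
#' @slot lanes data.frame with columns `linker` (bp), `spacing` (bp between
#'   bend centers), `freeMigration`, `complexMigration`.
#' @seealso [fitPhasing()], [spacingFromLinker()], [genPhasingSeries()]
#' @export
setClass("PhasingSeries",
  representation(lanes = "data.frame"),
  validity = function(object) {
    need <- c("spacing", "freeMigration", "complexMigration")
    miss <- setdiff(need, names(object@lanes))
    if (length(miss))
      return(sprintf("lanes is missing column(s): %s",
                     paste(miss, collapse = ", ")))
    ln <- object@lanes
    msg <- character()
    if (any(ln$freeMigration <= 0) || any(ln$complexMigration <= 0))
      msg <- c(msg, "migrations must be > 0")
    if (any(ln$spacing < 0))
      msg <- c(msg, "spacings must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' PhasingFit: result of sinusoidal phasing fit
#'
#' @slot amplitude modulation amplitude of relative mobility
#'   (dimensionless, >= 0).
#' @slot baseline mean relative mobility.
#' @slot inPhaseSpacing bp spacing at the mobility minimum (the in-phase
#'   geometry); `NA` when the profile is flat (amplitude 0).
#' @slot helicalRepeat bp per helical turn used or fitted.
#' @slot turnsAtMin `inPhaseSpacing / helicalRepeat`, rounded to 1 decimal.
#' @slot rss residual sum of squares.
#' @export
setClass("PhasingFit",
  representation(amplitude = "numeric", baseline = "numeric",
                 inPhaseSpacing = "numeric", helicalRepeat = "numeric",
                 turnsAtMin = "numeric", rss = "numeric"),
  validity = function(object) {
    if (object@amplitude < 0) "amplitude must be >= 0" else TRUE
  })

#' BindingSeries: saturation binding points
#'
#' @slot points data.frame with columns `probeAmount` (concentration in
#'   as-supplied units, strictly increasing, >= 0) and `boundSignal`
#'   (arbitrary intensity units).
#' @slot label probe label, e.g. `"N10"` or `"SRE"`.
#' @seealso [fitSaturation()], [genBindingSeries()]
#' @export
setClass("BindingSeries",
  representation(points = "data.frame", label = "character"),
  validity = function(object) {
    pts <- object@points
    miss <- setdiff(c("probeAmount", "boundSignal"), names(pts))
    if (length(miss))
      return(sprintf("points is missing column(s): %s",
                     paste(miss, collapse = ", ")))
    msg <- character()
    if (nrow(pts) < 5L)
      msg <- c(msg, "need >= 5 points")
    if (any(pts$probeAmount < 0))
      msg <- c(msg, "probeAmount must be >= 0")
    if (is.unsorted(pts$probeAmount, strictly = TRUE))
      msg <- c(msg, "probeAmount must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' BindingFit: one-site saturation fit (Bmax, Kd)
#'
#' @slot bmax maximal binding, same units as the input signal.
#' @slot kd dissociation constant, same units as `probeAmount`.
#' @slot rss residual sum of squares.
#' @slot nonSaturating `TRUE` when the curve is still rising steeply at the
#'   largest probe amount (fit returned, but Kd poorly constrained).
#' @export
setClass("BindingFit",
  representation(bmax = "numeric", kd = "numeric", rss = "numeric",
                 nonSaturating = "logical"),
  validity = function(object) {
    if (object@bmax <= 0 || object@kd <= 0) "bmax and kd must be > 0" else TRUE
  })

#' CircularizationSeries: ligase-mediated minicircle time course
#'
#' Minicircle formation is expressed as percent of the no-protein control
#' (which defines 100%).
#'
#' @slot points data.frame with columns `time` (minutes, non-decreasing)
#'   and `minicirclePct` (percent, >= 0).
#' @slot phaseLabel `"in_phase"` or `"out_of_phase"`.
#' @slot proteinPresent logical flag.
#' @seealso [fitCircularization()], [genCircularization()]
#' @export
setClass("CircularizationSeries",
  representation(points = "data.frame", phaseLabel = "character",
                 proteinPresent = "logical"),
  validity = function(object) {
    pts <- object@points
    miss <- setdiff(c("time", "minicirclePct"), names(pts))
    if (length(miss))
      return(sprintf("points is missing column(s): %s",
                     paste(miss, collapse = ", ")))
    msg <- character()
    if (is.unsorted(pts$time))
      msg <- c(msg, "time must be non-decreasing")
    if (any(pts$minicirclePct < 0))
      msg <- c(msg, "minicirclePct must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' RateFit: first-order circularization kinetics
#'
#' @slot rateK first-order rate constant, per minute (>= 0).
#' @slot plateauPct plateau minicircle level, percent of control (>= 0).
#' @slot rss residual sum of squares.
#' @slot nonMonotone `TRUE` when the series decreases appreciably after its
#'   maximum (the first-order model is then only a summary).
#' @export
setClass("RateFit",
  representation(rateK = "numeric", plateauPct = "numeric", rss = "numeric",
                 nonMonotone = "logical"),
  validity = function(object) {
    if (object@rateK < 0 || object@plateauPct < 0)
      "rateK and plateauPct must be >= 0" else TRUE
  })

#' SimulationConfig: seed, noise levels and ground truth for the generators
#'
#' @slot seed single integer; generators are deterministic functions of
#'   the config and their arguments.
#' @slot sigmaMobility Gaussian noise SD on relative mobility (permutation
#'   and phasing lanes).
#' @slot sigmaBinding noise SD on bound signal, as a fraction of bmax.
#' @slot sigmaCirc noise SD on minicircle percent, in percentage points.
#' @slot truth named list of true parameters; see [simulationConfig()] for
#'   the defaults and their provenance.
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", sigmaMobility = "numeric",
                 sigmaBinding = "numeric", sigmaCirc = "numeric",
                 truth = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
      msg <- c(msg, "'seed' must be a single integer")
    if (object@sigmaMobility < 0 || object@sigmaBinding < 0 ||
        object@sigmaCirc < 0)
      msg <- c(msg, "noise sigmas must be >= 0")
    if (length(msg)) msg else TRUE
  })
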