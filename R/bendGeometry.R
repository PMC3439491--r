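## Circular-permutation analysis.
##
## Identical-length probes carry the binding site at varying positions;
## the protein-DNA complex migrates slowest when the induced bend sits at
## the probe center. Relative mobility traces a cosine in site position;
## the extremes muM (slowest) and muE (fastest) give the bend angle via
## muM/muE = cos(alpha/2).

#' Relative mobility of a lane
#'
#' Normalizes the complex migration by the free-probe migration of the
#' same lane, giving a dimensionless mobility in (0, 1].
#'
#' @param freeMigration free-probe migration distance (> 0).
#' @param complexMigration complex migration distance (> 0).
#' @return `complexMigration / freeMigration`.
#' @examples
#' relativeMobility(8.4, 6.3)  # 0.75
#' @export
relativeMobility <- function(freeMigration, complexMigration) {
  if (any(freeMigration <= 0) || any(complexMigration <= 0))
    stop("migration distances must be > 0")
  complexMigration / freeMigration
}

#' Bend angle from mobility extremes
#'
#' Applies muM/muE = cos(alpha/2): the ratio of the slowest to the fastest
#' relative complex mobility determines the induced bend angle.
#'
#' @param muM minimum relative mobility (0 < muM <= muE).
#' @param muE maximum relative mobility.
#' @return bend angle alpha in degrees, in [0, 180).
#' @examples
#' bendAngleFromRatio(0.35, 0.70)  # 120 degrees
#' @export
bendAngleFromRatio <- function(muM, muE) {
  if (any(muE <= 0)) stop("muE must be > 0")
  if (any(muM <= 0)) stop("muM must be > 0")
  if (any(muM > muE))
    stop("muM must not exceed muE (a mobility ratio > 1 has no real angle)")
  2 * acos(muM / muE) * 180 / pi
}

#' Fit the circular-permutation cosine profile
#'
#' Least-squares fit of relative mobility against binding-site position:
#' `r(p) = a + b * cos(pi * (p - p0) / L)` with `L` the probe length and
#' `b <= 0`, so the mobility minimum (slowest complex) sits at the bend
#' center `p0`. The model is linear in `(a, b*cos, b*sin)` after harmonic
#' expansion, so the global least-squares optimum is found in closed form —
#' the fit is exact and deterministic. Extremes are read from the fitted
#' curve, `muM = a + b`, `muE = a - b`, and the angle follows from
#' [bendAngleFromRatio()].
#'
#' @param series a [PermutationSeries-class] with >= 4 lanes at distinct
#'   site positions.
#' @return a [BendFit-class]. A flat profile returns `muM == muE`, angle 0
#'   and `bendCenter = NA`.
#' @examples
#' cfg <- simulationConfig(seed = 1, sigmaMobility = 0)
#' sim <- genPermutationSeries(cfg)
#' fitPermutation(sim$series)
#' @export
fitPermutation <- function(series) {
  stopifnot(is(series, "PermutationSeries"))
  ln <- series@lanes
  if (nrow(ln) < 4L)
    stop("insufficient data: need >= 4 lanes with distinct site centers")
  L <- series@probeLength
  r <- relativeMobility(ln$freeMigration, ln$complexMigration)
  theta <- pi * ln$siteCenter / L
  X <- cbind(1, cos(theta), sin(theta))
  cf <- unname(stats::lm.fit(X, r)$coefficients)
  a <- cf[1]; B <- cf[2]; C <- cf[3]
  amp <- sqrt(B^2 + C^2)
  rss <- sum((r - X %*% cf)^2)
  if (amp < 1e-12) {             # flat profile: no detectable bend
    if (a <= 0) stop("degenerate fit: non-positive mobility level")
    return(new("BendFit", muM = a, muE = a, bendCenter = NA_real_,
               bendAngleDeg = 0, probeLength = L, rss = rss))
  }
  b <- -amp                      # minimum at the bend center
  p0 <- (L / pi) * atan2(C / b, B / b)
  p0 <- p0 %% (2 * L)            # model period is 2L
  muM <- a + b
  muE <- a - b
  if (muM <= 0)
    stop("degenerate fit: fitted minimum mobility a + b <= 0")
  new("BendFit", muM = unname(muM), muE = unname(muE),
      bendCenter = unname(p0),
      bendAngleDeg = bendAngleFromRatio(muM, muE),
      probeLength = L, rss = rss)
}
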