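## Seeded synthetic-data generators.
##
## Every generator is a deterministic function of (config, arguments):
## the config seed initializes R's RNG locally and the previous RNG state
## is restored on exit. With sigma = 0 the outputs lie exactly on the
## corresponding model curves, so generator -> fit round-trips recover
## the truth to numerical precision.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a circular-permutation EMSA series
#'
#' Site centers are evenly spaced over 10-90% of the probe; relative
#' mobilities follow the cosine flexure model
#' `r(p) = a + b cos(pi (p - p0)/L)` with `muM = muE cos(alpha/2)`,
#' plus Gaussian noise of SD `sigmaMobility`. The free-probe migration is
#' fixed at 10 arbitrary units in every lane.
#'
#' @param cfg a [SimulationConfig-class]; truth entries used:
#'   `bendAngleDeg`, `bendCenter` (`NA` = probe midpoint), `muE`.
#' @param nLanes number of lanes (>= 4, default 8).
#' @param probeLength probe length in bp (default 230).
#' @return list with `series` ([PermutationSeries-class]) and `truth`
#'   (list of the generating parameters).
#' @examples
#' sim <- genPermutationSeries(simulationConfig(seed = 7))
#' fitPermutation(sim$series)
#' @export
genPermutationSeries <- function(cfg, nLanes = 8L, probeLength = 230) {
  stopifnot(is(cfg, "SimulationConfig"), nLanes >= 4L)
  tr <- cfg@truth
  L <- probeLength
  p0 <- if (is.na(tr$bendCenter)) L / 2 else tr$bendCenter
  muE <- tr$muE
  muM <- muE * cos(tr$bendAngleDeg / 2 * pi / 180)
  a <- (muM + muE) / 2
  b <- (muM - muE) / 2
  centers <- seq(0.1 * L, 0.9 * L, length.out = nLanes)
  r <- .withSeed(cfg@seed,
    a + b * cos(pi * (centers - p0) / L) +
      stats::rnorm(nLanes, 0, cfg@sigmaMobility))
  free <- 10
  lanes <- data.frame(enzyme = paste0("lane", seq_len(nLanes)),
                      siteCenter = centers,
                      freeMigration = free,
                      complexMigration = pmin(r, 1) * free)
  list(series = PermutationSeries(lanes, L),
       truth = list(bendAngleDeg = tr$bendAngleDeg, bendCenter = p0,
                    muM = muM, muE = muE))
}

#' Simulate a helical phasing series
#'
#' Spacings derive from the linkers via [spacingFromLinker()]; relative
#' mobilities follow
#' `r(s) = baseline - amplitude cos(2 pi (s - s0)/repeat)` plus Gaussian
#' noise of SD `sigmaMobility`.
#'
#' @param cfg a [SimulationConfig-class]; truth entries used: `baseline`,
#'   `amplitude`, `s0`, `helicalRepeat`.
#' @param linkers linker lengths in bp (default 12, 14, 16, 18, 20).
#' @return list with `series` ([PhasingSeries-class]) and `truth`.
#' @export
genPhasingSeries <- function(cfg, linkers = c(12, 14, 16, 18, 20)) {
  stopifnot(is(cfg, "SimulationConfig"), length(linkers) >= 5L)
  tr <- cfg@truth
  s <- spacingFromLinker(linkers)
  r <- .withSeed(cfg@seed,
    tr$baseline -
      tr$amplitude * cos(2 * pi * (s - tr$s0) / tr$helicalRepeat) +
      stats::rnorm(length(s), 0, cfg@sigmaMobility))
  free <- 10
  lanes <- data.frame(linker = linkers, spacing = s,
                      freeMigration = free,
                      complexMigration = pmin(r, 1) * free)
  list(series = PhasingSeries(lanes),
       truth = list(baseline = tr$baseline, amplitude = tr$amplitude,
                    s0 = tr$s0, helicalRepeat = tr$helicalRepeat))
}

#' Simulate a one-site saturation binding series
#'
#' Bound signal follows the hyperbola `bmax * x / (kd + x)` plus Gaussian
#' noise of SD `sigmaBinding * bmax`.
#'
#' @param cfg a [SimulationConfig-class]; truth entries used: `bmax`, `kd`.
#' @param xGrid probe amounts; default 8 points log-spaced from 0.5 to 32.
#' @param label probe label for the series.
#' @return list with `series` ([BindingSeries-class]) and `truth`.
#' @export
genBindingSeries <- function(cfg,
                             xGrid = 2^seq(log2(0.5), log2(32),
                                           length.out = 8L),
                             label = "N10") {
  stopifnot(is(cfg, "SimulationConfig"))
  tr <- cfg@truth
  y <- .withSeed(cfg@seed,
    tr$bmax * xGrid / (tr$kd + xGrid) +
      stats::rnorm(length(xGrid), 0, cfg@sigmaBinding * tr$bmax))
  list(series = BindingSeries(xGrid, y, label),
       truth = list(bmax = tr$bmax, kd = tr$kd))
}

#' Simulate paired in-phase / out-of-phase circularization time courses
#'
#' Minicircle percent follows `plateau * (1 - exp(-k t))` plus Gaussian
#' noise of SD `sigmaCirc` percentage points (clamped at 0; the t = 0
#' point is noise-free by construction of the assay normalization). The
#' default truth has `kIn > kOut`, mirroring faster circularization of
#' the in-phase probe.
#'
#' @param cfg a [SimulationConfig-class]; truth entries used: `kIn`,
#'   `kOut`, `plateauIn`, `plateauOut`.
#' @param times time points in minutes (default 0 to 60 by 10).
#' @return list with `inPhase` and `outPhase`
#'   ([CircularizationSeries-class]) and `truth`.
#' @export
genCircularization <- function(cfg, times = seq(0, 60, by = 10)) {
  stopifnot(is(cfg, "SimulationConfig"))
  tr <- cfg@truth
  make <- function(plateau, k, noise) {
    y <- plateau * (1 - exp(-k * times)) + noise
    y[times == 0] <- 0
    pmax(y, 0)
  }
  noises <- .withSeed(cfg@seed,
    matrix(stats::rnorm(2 * length(times), 0, cfg@sigmaCirc), ncol = 2))
  list(inPhase = CircularizationSeries(
         times, make(tr$plateauIn, tr$kIn, noises[, 1]),
         phaseLabel = "in_phase"),
       outPhase = CircularizationSeries(
         times, make(tr$plateauOut, tr$kOut, noises[, 2]),
         phaseLabel = "out_of_phase"),
       truth = list(kIn = tr$kIn, kOut = tr$kOut,
                    plateauIn = tr$plateauIn, plateauOut = tr$plateauOut))
}

#' Simulate promoter sequences with planted CArG motifs
#'
#' Generates uniform-random ACGT background and plants motif instances
#' drawn from the requested consensus class, with the requested number of
#' atypical (deviating) positions, at non-overlapping recorded positions.
#' The returned truth contains both the planted table and the full
#' budget-0 scan of the emitted sequences (so background windows that
#' match a consensus by chance are accounted for).
#'
#' @param cfg a [SimulationConfig-class] (seed only).
#' @param nSeqs number of sequences.
#' @param length sequence length in bp.
#' @param plantSpec data.frame with columns `patternName` and `nAtypical`,
#'   one row per motif to plant; motifs are distributed round-robin over
#'   the sequences.
#' @return list with `sequences` (`DNAStringSet`), `planted` (data.frame:
#'   seqId, start 0-based, end, strand `"+"`, plantedSeq, patternName,
#'   nAtypical) and `exactHits` (budget-0 [scanFasta()] table of the
#'   emitted sequences).
#' @export
genPromoters <- function(cfg, nSeqs = 5L, length = 500L,
                         plantSpec = data.frame(
                           patternName = c("canonical", "srf_like",
                                           "n10_like"),
                           nAtypical = c(0L, 0L, 0L))) {
  stopifnot(is(cfg, "SimulationConfig"))
  pats <- builtinPatterns()
  if (nSeqs == 0L) {
    return(list(sequences = Biostrings::DNAStringSet(),
                planted = data.frame(), exactHits = scanSequence("x", "")))
  }
  perSeq <- table(factor(rep(seq_len(nSeqs),
                             length.out = nrow(plantSpec)),
                         levels = seq_len(nSeqs)))
  maxLen <- if (nrow(plantSpec))
    max(vapply(plantSpec$patternName,
               function(n) base::length(pats[[n]]@positions), integer(1)))
  else 0L
  if (max(perSeq) * (maxLen + 1L) > length)
    stop("over-packed plant spec: motifs cannot fit without overlap")
  res <- .withSeed(cfg@seed, {
    seqs <- character(nSeqs)
    planted <- list()
    specIdx <- split(seq_len(nrow(plantSpec)),
                     factor(rep(seq_len(nSeqs),
                                length.out = nrow(plantSpec)),
                            levels = seq_len(nSeqs)))
    for (i in seq_len(nSeqs)) {
      s <- sample(DNA_BASES4, length, replace = TRUE)
      used <- integer(0)  # occupied positions
      for (j in specIdx[[as.character(i)]] %||% integer(0)) {
        pat <- pats[[plantSpec$patternName[j]]]
        k <- base::length(pat@positions)
        motif <- vapply(pat@positions, function(p)
          if (base::length(p) == 1L) p else sample(p, 1L), character(1))
        nat <- plantSpec$nAtypical[j]
        if (nat > 0L) {
          mut <- sample(seq_len(k), nat)
          for (m in mut)
            motif[m] <- sample(setdiff(DNA_BASES4,
                                       pat@positions[[m]]), 1L)
        }
        ## rejection-sample a non-overlapping start
        for (try in 1:1000) {
          st <- sample(seq_len(length - k + 1L), 1L)
          if (!any((st:(st + k - 1L)) %in% used)) break
          if (try == 1000L)
            stop("over-packed plant spec: could not place motif")
        }
        used <- c(used, st:(st + k - 1L))
        s[st:(st + k - 1L)] <- motif
        planted[[base::length(planted) + 1L]] <- data.frame(
          seqId = paste0("promoter", i), start = st - 1L,
          end = st - 1L + k, strand = "+",
          plantedSeq = paste(motif, collapse = ""),
          patternName = pat@name, nAtypical = nat,
          stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    list(seqs = seqs, planted = planted)
  })
  dss <- Biostrings::DNAStringSet(res$seqs)
  names(dss) <- paste0("promoter", seq_len(nSeqs))
  planted <- if (base::length(res$planted))
    do.call(rbind, res$planted) else data.frame()
  list(sequences = dss, planted = planted,
       exactHits = scanFasta(dss, pats, maxAtypical = 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
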