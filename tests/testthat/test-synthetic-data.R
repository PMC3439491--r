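test_that("generators are deterministic functions of the config", {
  cfg <- simulationConfig(seed = 21)
  expect_identical(lanes(genPermutationSeries(cfg)$series),
                   lanes(genPermutationSeries(cfg)$series))
  expect_identical(lanes(genPhasingSeries(cfg)$series),
                   lanes(genPhasingSeries(cfg)$series))
  expect_identical(genBindingSeries(cfg)$series@points,
                   genBindingSeries(cfg)$series@points)
  expect_identical(genCircularization(cfg)$inPhase@points,
                   genCircularization(cfg)$inPhase@points)
  p1 <- genPromoters(cfg, nSeqs = 2, length = 200)
  p2 <- genPromoters(cfg, nSeqs = 2, length = 200)
  expect_identical(as.character(p1$sequences), as.character(p2$sequences))
  # different seeds give different noise
  cfg2 <- simulationConfig(seed = 22)
  expect_false(identical(lanes(genPermutationSeries(cfg)$series),
                         lanes(genPermutationSeries(cfg2)$series)))
})

test_that("sigma = 0 permutation lanes lie exactly on the cosine model", {
  # 120-degree bend, muE 0.8: the lane at the bend center runs at 0.4
  cfg <- simulationConfig(seed = 1, sigmaMobility = 0,
                          truth = list(bendAngleDeg = 120, muE = 0.8))
  sim <- genPermutationSeries(cfg, nLanes = 9)  # odd count samples L/2
  ln <- lanes(sim$series)
  rel <- ln$complexMigration / ln$freeMigration
  expect_equal(rel[5], 0.4, tolerance = 1e-12)
  expect_equal(max(ln$siteCenter), 0.9 * 230)
  expect_equal(min(ln$siteCenter), 0.1 * 230)
})

test_that("sigma = 0 phasing and binding outputs lie on their models", {
  cfg <- simulationConfig(seed = 1, sigmaMobility = 0, sigmaBinding = 0)
  ph <- genPhasingSeries(cfg)
  ln <- lanes(ph$series)
  expect_equal(ln$spacing, spacingFromLinker(c(12, 14, 16, 18, 20)))
  expect_equal(ln$complexMigration / ln$freeMigration,
               0.6 - 0.1 * cos(2 * pi * (ln$spacing - 55) / 10.5))
  b <- genBindingSeries(cfg)
  pts <- b$series@points
  expect_equal(pts$boundSignal,
               pts$probeAmount / (4.515 + pts$probeAmount))
})

test_that("circularization time courses start at 0% and order in > out", {
  cfg <- simulationConfig(seed = 4)
  cc <- genCircularization(cfg)
  expect_equal(cc$inPhase@points$minicirclePct[1], 0)
  expect_equal(cc$outPhase@points$minicirclePct[1], 0)
  expect_gt(cc$truth$kIn, cc$truth$kOut)
  verdict <- comparePhaseRates(fitCircularization(cc$inPhase),
                               fitCircularization(cc$outPhase))
  expect_equal(verdict$verdict, "in>out")
})

test_that("generator -> fit round trips recover the truth", {
  cfg <- simulationConfig(seed = 1, sigmaMobility = 0, sigmaBinding = 0,
                          sigmaCirc = 0)
  pf <- fitPermutation(genPermutationSeries(cfg)$series)
  expect_equal(bendAngle(pf), 93, tolerance = 1e-6)
  expect_equal(bendCenter(pf), 115, tolerance = 1e-6)
  hf <- fitPhasing(genPhasingSeries(cfg)$series)
  expect_equal(inPhaseSpacing(hf), 55, tolerance = 1e-6)
  bf <- fitSaturation(genBindingSeries(cfg)$series)
  expect_equal(kdValue(bf), 4.515, tolerance = 1e-6)
  cc <- genCircularization(cfg)
  expect_equal(rateConstant(fitCircularization(cc$inPhase)), 0.10,
               tolerance = 1e-6)
  expect_equal(rateConstant(fitCircularization(cc$outPhase)), 0.05,
               tolerance = 1e-6)
})

test_that("planted promoter motifs are recovered at exact coordinates", {
  cfg <- simulationConfig(seed = 33)
  spec <- data.frame(patternName = c("canonical", "srf_like", "n10_like",
                                     "canonical", "intermediate"),
                     nAtypical = 0L)
  sim <- genPromoters(cfg, nSeqs = 3, length = 300, plantSpec = spec)
  hits <- scanFasta(sim$sequences, maxAtypical = 0)
  for (i in seq_len(nrow(sim$planted))) {
    pl <- sim$planted[i, ]
    found <- hits[hits$seqId == pl$seqId & hits$start == pl$start &
                    hits$patternName == pl$patternName &
                    hits$strand == "+", ]
    expect_equal(nrow(found), 1L)
    expect_equal(found$matchedSeq, pl$plantedSeq)
  }
})

test_that("promoter truth table equals an independent brute-force scan", {
  cfg <- simulationConfig(seed = 8)
  sim <- genPromoters(cfg, nSeqs = 2, length = 250)
  want <- do.call(rbind, lapply(seq_along(sim$sequences), function(i)
    oracle_scan(names(sim$sequences)[i],
                as.character(sim$sequences[[i]]),
                c("canonical", "srf_like", "n10_like", "intermediate"),
                budget = 0, bothStrands = TRUE)))
  rownames(want) <- NULL
  expect_equal(sim$exactHits, want)
})

test_that("promoter generator contracts", {
  cfg <- simulationConfig(seed = 2)
  empty <- genPromoters(cfg, nSeqs = 0)
  expect_length(empty$sequences, 0)
  expect_error(genPromoters(cfg, nSeqs = 1, length = 30,
                            plantSpec = data.frame(
                              patternName = rep("canonical", 5),
                              nAtypical = 0L)),
               "over-packed")
  # planted atypical sites carry the requested deviation count
  spec <- data.frame(patternName = "canonical", nAtypical = 2L)
  sim <- genPromoters(cfg, nSeqs = 1, length = 100, plantSpec = spec)
  got <- classifyCarg(sim$planted$plantedSeq[1], maxAtypical = 2)
  expect_lte(got$nAtypical, 2)
})
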