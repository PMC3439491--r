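# cargbend

Quantitative analysis of MADS-domain transcription factor interactions
with CArG-box DNA elements, built around four assays used to characterize
an AGAMOUS-clade MADS-box protein from ripening banana fruit:

- **Degenerate CArG-box scanning.** MADS-domain proteins bind the CArG
  box, a degenerate element with canonical decamer consensus
  C(C/T)(A/T)<sub>6</sub>(A/G)G. The package scans promoter sequences for
  the canonical, SRF/SRE-like (CC(A/T)<sub>6</sub>GG), MEF2/N10-like
  (CTA(A/T)<sub>4</sub>TAG) and intermediate (C(A/T)<sub>6</sub>AG)
  classes, with a configurable budget of "atypical" (deviating) positions.
- **Circular-permutation analysis.** Identical-length EMSA probes carry
  the binding site at different positions; the protein–DNA complex runs
  slowest when the induced bend is centered. Relative mobility follows a
  cosine in site position, and the extremes give the bend angle via
  µ<sub>M</sub>/µ<sub>E</sub> = cos(α/2).
- **Helical phasing analysis.** Varying the spacing between an intrinsic
  A-tract bend and the protein-induced bend makes complex mobility
  oscillate with the B-DNA helical repeat (10.5 bp/turn); the mobility
  minimum identifies the in-phase geometry and distinguishes directed
  bending from flexibility.
- **Binding and circularization kinetics.** One-site saturation binding
  (bound = B<sub>max</sub>·x/(K<sub>D</sub> + x)) and first-order
  ligase-mediated minicircle formation
  (pct(t) = plateau·(1 − e<sup>−kt</sup>)), with an in-phase vs
  out-of-phase rate comparison.

Because gel and binding measurements are lab-specific, the package ships
seeded synthetic-data generators with known ground truth for every assay,
so each estimator is validated end-to-end by parameter recovery.

## Worked example

```r
library(cargbend)

## The SRE probe core is a perfect SRF-class (and canonical) CArG box.
scanSequence("SRE_probe", "ATGTCCATATTAGGACAT", maxAtypical = 0)
#>       seqId start end strand matchedSeq patternName nAtypical
#> 1 SRE_probe     4  14      - CCTAATATGG   canonical         0
#> 2 SRE_probe     4  14      - CCTAATATGG    srf_like         0
#> 3 SRE_probe     4  14      + CCATATTAGG   canonical         0
#> 4 SRE_probe     4  14      + CCATATTAGG    srf_like         0

## Simulate a circular-permutation series (default truth: 93 deg bend
## centered mid-probe) and estimate the bend angle from the cosine fit.
cfg <- simulationConfig(seed = 42)
fitPermutation(genPermutationSeries(cfg)$series)
#> BendFit: muM = 0.5523, muE = 0.8056, bend center = 115.0 bp,
#>          angle = 93.4 deg (rss 8.91e-05)

## Phasing: the fitted mobility minimum sits at 55 bp spacing,
## i.e. 5.2 helical turns at 10.5 bp/turn -- the in-phase geometry.
fitPhasing(genPhasingSeries(cfg)$series)
#> PhasingFit: baseline 0.6023, amplitude 0.1022, in-phase spacing
#>             54.99 bp (5.2 turns at 10.50 bp/turn, rss 3.46e-05)

## Saturation binding (default truth Kd = 4.515, as-supplied units).
fitSaturation(genBindingSeries(cfg)$series)
#> BindingFit: bmax = 1.005, Kd = 4.386 (rss 0.00156)

## In-phase probes circularize faster than out-of-phase probes.
cc <- genCircularization(cfg)
comparePhaseRates(fitCircularization(cc$inPhase),
                  fitCircularization(cc$outPhase))
#> $ratio
#> [1] 1.522711
#> $verdict
#> [1] "in>out"
```

The scan table uses 0-based half-open coordinates (BED convention); the
minus-strand rows are the quasi-palindromic reverse-complement reading of
the same site. The bend-angle estimate (93.4°) recovers the generator
truth (93°) from one noisy eight-lane series; K<sub>D</sub> estimates
from single series scatter a few percent about the truth and are
validated in the mean over replicates.

## Package tour

| Area | Functions |
| --- | --- |
| Motif scanning | `builtinPatterns`, `classifyCarg`, `scanSequence`, `scanFasta`, `writeHitsBed` |
| Bend geometry | `relativeMobility`, `bendAngleFromRatio`, `fitPermutation` |
| Phasing | `spacingFromLinker`, `helicalTurns`, `fitPhasing`, `classifyPhase` |
| Kinetics | `fitSaturation`, `fitCircularization`, `comparePhaseRates` |
| Simulation | `simulationConfig`, `genPermutationSeries`, `genPhasingSeries`, `genBindingSeries`, `genCircularization`, `genPromoters` |
| I/O & utilities | `readFasta`, `writeFasta`, `readLaneTable`, `revcomp`, `orfProteinLength` |

The methods vignette (`vignettes/carg-bending.Rmd`) documents the models,
parameter choices, numerical strategy and limitations.
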