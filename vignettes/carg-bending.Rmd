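---
title: "Models and methods: CArG-box scanning and protein-induced DNA bending"
author: "cargbend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CArG-box scanning and protein-induced DNA bending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cargbend)
```

# Scope

MADS-domain transcription factors — SRF and MEF2 in animals, the
AGAMOUS clade in plants — recognize the CArG box, a degenerate A/T-rich
element, and sharply bend the DNA they bind. This package implements the
four desk-side analyses used to characterize such a factor: consensus
scanning of promoter sequence, bend-angle estimation from
circular-permutation electrophoresis, helical phasing analysis, and
binding/circularization kinetics. A seeded simulation layer generates
every input with known ground truth, so each estimator is exercised by
parameter recovery rather than by irreproducible gel images.

# Consensus classes and the atypical-base budget

Four classes are built in (`builtinPatterns()`):

| class | consensus | length |
| --- | --- | --- |
| `canonical` | C(C/T)(A/T)~6~(A/G)G | 10 |
| `srf_like` (SRE) | CC(A/T)~6~GG | 10 |
| `n10_like` (MEF2) | CTA(A/T)~4~TAG | 10 |
| `intermediate` | C(A/T)~6~AG | 9 |

Functional "atypical" CArG boxes deviate from the canonical consensus at
one or two positions. No consensus-wide mismatch rule is standard, so
the package adopts the minimal rule consistent with known functional
atypical sites (e.g. the tomato ripening-gene promoter decamers
CATTTATATG and CTAGTTAAAG): **at most 2 deviating positions**, with the
budget configurable per call. `classifyCarg()` reports the best-matching
decamer class (fewest deviations, ties broken canonical > srf_like >
n10_like); the 9-bp intermediate class takes part in scanning but not in
decamer classification. The intermediate class is implemented at the
length at which it is conventionally written (C(A/T)~6~AG, nine
positions); whether a padded decamer form CC(A/T)~6~AG was ever intended
is ambiguous in the literature, so the short form is used and noted here.

Scanning (`scanSequence()`) slides every pattern over every window on
both strands by default — CArG boxes are quasi-palindromic, and a site is
a site whichever strand it is read from. Exactly palindromic windows
would otherwise appear twice and are reported once, on the plus strand.
Overlapping hits are all reported: the biology enumerates sites, it does
not tile them. Coordinates are 0-based half-open (BED convention) for
painless interchange. No position-weight matrices, background models or
p-values are involved: near-exact consensus matching is the method being
reproduced, and the mismatch count itself is the score.

# Circular permutation: from mobility to bend angle

Probes of identical length and sequence composition carry the binding
site at varying positions (restriction-digest permutations of a tandem
duplication). A protein-induced bend retards the complex most when it
sits mid-probe. With relative mobility $r$ = complex migration / free
migration (same lane — per-lane normalization removes loading and field
inhomogeneity), the profile is modeled as

$$ r(p) = a + b\,\cos\!\left(\frac{\pi (p - p_0)}{L}\right), \qquad b \le 0, $$

one half-period across the probe of length $L$, minimum at the bend
center $p_0$. The fitted extremes $\mu_M = a + b$ (slowest) and
$\mu_E = a - b$ (fastest) give the bend angle through the standard
relation

$$ \frac{\mu_M}{\mu_E} = \cos\left(\frac{\alpha}{2}\right). $$

Extremes are read from the fitted curve, not from the raw extreme lanes,
so single-lane noise does not propagate directly into the angle.

**Numerical strategy.** The model is nonlinear in $p_0$ but exactly
linear in the harmonic basis
$\{1, \cos(\pi p / L), \sin(\pi p / L)\}$:
$r(p) = a + B\cos(\pi p/L) + C\sin(\pi p/L)$ with
$b = -\sqrt{B^2 + C^2}$ and $p_0 = (L/\pi)\,\mathrm{atan2}(C/b,\, B/b)$.
Ordinary least squares in that basis therefore yields the *global*
optimum of the nonlinear objective in closed form — no starting values,
no local minima, fully deterministic. An amplitude numerically at zero
(flat profile) means no detectable bend: the fit reports
$\mu_M = \mu_E$, angle 0, and an undefined (`NA`) bend center. A fitted
$a + b \le 0$ would imply a non-physical negative mobility minimum and is
rejected as degenerate. At least 4 lanes at distinct positions are
required (3 parameters plus one residual degree of freedom).

Angles are conventionally quoted to one decimal place; values near 0°
(no bend) and approaching 180° are limiting cases of the arccosine and
increasingly noise-sensitive at both extremes.

# Phasing analysis

Constructs place an intrinsic A-tract bend at a variable helical spacing
$s$ from the protein-bound site (linker 12–20 bp; the construct geometry
adds a fixed 39 bp, giving $s$ = 51–59 bp). When the two bends lie on
the same helical face they add and the complex migrates slowest; half a
turn away they oppose. Mobility is modeled as

$$ r(s) = \text{baseline} - \text{amplitude}\cdot
   \cos\!\left(\frac{2\pi (s - s_0)}{h}\right), \qquad
   \text{amplitude} \ge 0, $$

with $h$ the helical repeat, fixed at 10.5 bp/turn by default. The
mobility minimum $s_0$ — not integer-turn arithmetic — defines the
in-phase spacing, because the in-phase geometry at 55 bp corresponds to
5.2 turns, not an integer. The same harmonic-basis linearization gives
the exact least-squares solution for fixed $h$; with `freeRepeat = TRUE`
the repeat is profiled over a deterministic 0.01 bp grid on
[9, 12] bp/turn and polished with a bounded one-dimensional optimizer,
and the spacing span must then cover at least half a repeat to pin the
period. With $h$ fixed, the 3-parameter fit is identifiable even on the
8 bp experimental span, which is why five lanes suffice.

`classifyPhase()` converts the circular distance between a spacing and
$s_0$ (in turns) into a call: within 1/8 turn of the minimum is
`in_phase`, within 1/8 turn of the half-turn point `out_of_phase`,
otherwise `intermediate`. The 1/8-turn tolerance splits the helical
circle into equal in/intermediate/out sectors; it is a package
convention, chosen once, not an experimental constant.

# Binding and circularization kinetics

**Saturation binding.** Bound signal versus probe amount is fit to the
one-site isotherm $y = B_{max}\,x/(K_D + x)$ by Levenberg–Marquardt with
deterministic initialization ($B_{max,0}$ = maximal signal, $K_{D,0}$ =
interpolated half-maximal probe amount). The probe amounts carry no
absolute concentration scale in this assay family, so **$K_D$ is
reported in the same as-supplied units as the input** — comparisons
between probes (N10 vs SRE) are meaningful, absolute affinities are not.
If the fitted curve is still rising at the largest probe amount at more
than 90% of its initial slope, the data never approached saturation and
the fit is flagged `nonSaturating` rather than silently trusted.

**Ligase-mediated circularization.** Minicircle formation (percent of
the no-protein control, which defines 100%) is summarized by first-order
kinetics $pct(t) = \text{plateau}\,(1 - e^{-kt})$. The underlying
readout is qualitative; the kinetic summary is imposed to make the
in-phase > out-of-phase rate ordering quantitative and testable.
A constant series returns rate 0 at that plateau; a series that decays
after its maximum is fitted but flagged `nonMonotone`.

# The simulation layer

Every generator is a deterministic function of a `simulationConfig()`
(seed, per-assay noise SDs, truth parameters) and its arguments; the RNG
state is set locally and restored, and σ = 0 outputs lie exactly on the
model curves, making noiseless generator → fit round-trips exact to
numerical precision (the package's core regression tests assert 10⁻⁶).

Default study conditions, chosen once:

- *Permutation*: 8 lanes, 230 bp probe, site centers evenly spaced over
  10–90% of the probe; truth bend 93° (the N10-class value) centered
  mid-probe, fastest relative mobility µ~E~ = 0.8; free-probe migration
  fixed at 10 arbitrary units. Gaussian noise SD 0.005 on relative
  mobility — the scale of densitometric replicate scatter on a
  well-resolved native gel.
- *Phasing*: linkers 12–20 bp in steps of 2 (spacings 51–59 bp);
  baseline 0.6, amplitude 0.1, minimum at s₀ = 55 bp, repeat
  10.5 bp/turn.
- *Binding*: B~max~ = 1, K~D~ = 4.515, 8 probe amounts log-spaced
  0.5–32 (spanning well below to ~7× K~D~), noise SD 2% of B~max~.
- *Circularization*: times 0–60 min by 10; k~in~ = 0.10/min >
  k~out~ = 0.05/min with plateaus 75% and 55% of the no-protein control
  (the protein inhibits circularization overall while favoring the
  in-phase probe), noise SD 2 percentage points, t = 0 pinned at 0%.
- *Promoters*: uniform-random ACGT background with consensus-drawn
  motifs (optionally mutated to a requested atypical count) planted at
  recorded, non-overlapping positions; the truth bundle also includes a
  budget-0 scan of the emitted sequences so chance background matches
  are accounted for.

What the simulations do **not** emulate: gel-image artifacts (smiling,
lane-to-lane field variation, partial occupancy supershifts), sequence-
dependent intrinsic curvature of the background DNA, cooperative or
multi-site binding, and ligase-concentration effects. Passing recovery
tests therefore demonstrates estimator correctness under the stated
error model, not robustness to every gel pathology.

# Validation protocol and problem sizes

The regression suite checks, among others: scanner equivalence with an
independent brute-force window checker on random sequences (budgets
0–2, both strands), strand-symmetry and palindrome deduplication,
closed-form geometry identities (55 bp → 5.2 turns; equal mobilities →
0°), noiseless round-trips at 10⁻⁶, and stochastic recovery — 200
replicate permutation series at each of 93° and 41° (mean angle within
±2°) and 100 replicate binding series at each K~D~ of 4.515 and 10.63
(mean within 5%). These replicate counts give sub-0.2° and sub-2%
standard errors on the means while keeping the whole suite in seconds.
`scripts/acceptance.R` re-runs the same recovery protocol from the
installed package and writes the four summary numbers as JSON.

# Known limitations

- The bend-angle formula treats the complex as a rigid, planar bend;
  protein mass effects on mobility are absorbed into µ~E~ and cancel
  only in the ratio.
- Probe lengths and per-lane site positions of the original digests are
  not tabulated anywhere recoverable, so the synthetic defaults use the
  evenly spaced 8-lane design; analyses of real tables accept arbitrary
  positions.
- K~D~ values are unit-relative (see above).
- The phasing model excludes the second A-tract and total PCR-product
  length bookkeeping, which cannot be reconciled from the available
  construct descriptions; only bend-center spacing enters the model.
- `orfProteinLength()` is deliberately simple arithmetic (ORF length
  including stop ÷ 3, minus 1) — it does not validate start/stop codon
  content.
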