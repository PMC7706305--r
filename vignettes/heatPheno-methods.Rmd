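---
title: "Models and methods behind heatPheno"
author: "heatPheno maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heatPheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatPheno)
```

# Scope

heatPheno re-implements, as a tested and reusable pipeline, the analysis of
a high-throughput heat-stress phenotyping screen of Arabidopsis rosettes:
two genotypes (wild type and the thermotolerance-impaired *hsp101* mutant)
under four regimes (control and 3, 6 or 9 hours at 45 °C), imaged daily
with kinetic chlorophyll fluorescence, top-view colour and thermal cameras
from one day before stress (DAS −1) to seven days after (DAS 7). Because
such raw datasets are not generally available, the package ships a
first-class synthetic-data generator that emulates the experiment's
statistical structure; every analysis stage is exercised and validated on
its output.

# The synthetic experiment

## Design

`buildDesign(nReps)` enumerates the 2 × 4 × nReps factorial (160 plants at
the default 20 replicates) on trays of 20 positions with genotypes
interleaved within each treatment block, mirroring the balanced two-tray
layout per treatment of the screening design.

## Latent dynamics

`simulateExperiment()` evolves each plant through the imaging days. The
choices below aim at the smallest mechanism that reproduces each observed
qualitative dynamic:

* **Growth** — projected rosette area follows a discrete-daily logistic
  curve, `A' = A + r A (1 − A/K)`, with `r = 0.35 / day` and
  `K = 2500 mm²`; initial areas are lognormal around 150 mm² (CV 15%),
  plausible for three-week-old rosettes. From the stress day onward the
  growth rate is multiplied by `1 − 0.08 · h` for `h` stress hours, giving
  the stress-proportional size reduction, and a two-parameter form keeps
  the model identifiable.
* **Acute shrink** — heated plants wilt and move their leaves, visibly
  shrinking the top-view area within an hour of stress; this is modelled
  as a multiplicative projected-area factor `1 − 0.05 · h` on the stress
  day that decays linearly over two days. The rate is calibrated so that
  the day-0 size reduction is clearly detectable at n = 20 even for the
  mildest (3 h) regime, as the protocol is designed to show.
* **Quantum yield** — dark-adapted Fv/Fm sits at 0.80 (plant SD 0.005)
  and dips on the stress day by `0.022 · h`, more deeply for *hsp101*.
  The deficit decays linearly and reaches zero after a per-genotype delay:
  1 day for WT, 2 for *hsp101* — the recovery asymmetry that motivates the
  mutant comparison.
* **Quenching and the latent tolerance** — each plant carries a latent
  tolerance `u ~ U(0, 1)` that scales both the retention of photochemical
  quenching (qP) on the stress day and the post-stress growth penalty.
  This single shared variable is the minimal mechanism that produces the
  package's central correlation structure: early Fq (= Fm′ − Ft′)
  correlates with rosette area a week later more strongly than with
  same-day area, but only in stressed groups. Setting either coupling to
  zero severs the link (a tested property).
* **Genotype gap** — every *hsp101*-specific term is scaled by a
  per-treatment factor (0, 0.5, 1, 0.15 for control, 3 h, 6 h, 9 h): the
  genotypes are indistinguishable without stress, separate most clearly at
  6 h, and are both overwhelmed at 9 h. This one vector encodes the
  "intermediate stress is most informative" phenomenon the classification
  stage is meant to rediscover.
* **Mortality and runts** — plants under the 9 h regime die on the stress
  day with probability 0.1 (about 4 of 40 at default size) and emit no
  further records; any plant fails to grow with probability 0.02. Both are
  flagged for the exclusion filter.
* **Temperature** — rosette pixels sit at ambient (22 °C) minus 1.5 °C of
  transpiration cooling; stressed plants gain `0.25 °C · h` on the stress
  day, decaying by ×0.4 per day, with no genotype difference.
* **Morphology** — leaves lose aspect ratio (→ lower slenderness) and gain
  length irregularity (→ lower compactness) under stress, persistently and
  more strongly in *hsp101*.

## Rendering

`renderRosetteMask()` draws a centre disk plus elliptic leaf lobes with
seeded angular/length jitter and rescales the figure until the pixel count
matches the latent area (converges to ≈1%, well inside the 5% contract).
`simulateFluorescenceDay()` derives the raw light curve from the latent
state: Fm′ declines across the six actinic steps through a saturating NPQ
light response (`NPQ(I) = 2 I / (I + 300)`), F0′ is scaled down with the
quenching, and Ft′ is placed between F0′ and Fm′ by
`qP(I) = 1/(1 + I/500)` times the stress-day retention. Multiplicative
Gaussian noise (2% per signal, 3% per curve) is added and the physical
orderings (Fm > F0, Fm′ > Ft′ ≥ F0′, Fm′ decreasing in I) are re-imposed
afterwards, so derived parameters never hit invalid denominators in
simulated data while user-supplied data are still validated and rejected
explicitly.

What the generator does **not** emulate: pixel-level fluorescence
heterogeneity (plant-mean signals only), petiole/leaf-angle geometry (a
top-view limitation), humidity or CO₂ covariates, within-day kinetics
beyond the light-curve snapshot, and any real biological covariance
between traits beyond the single latent tolerance. Passing tests therefore
demonstrate the correctness and sensitivity of the *analysis machinery*
under the stated statistical structure — not biological fidelity of any
particular numeric value.

# Trait derivation

Fluorescence parameters follow the standard PAM definitions: Fv = Fm − F0,
QY max = Fv/Fm, Fv′ = Fm′ − F0′, QY′ = (Fm′ − Ft′)/Fm′,
NPQ = (Fm − Fm′)/Fm′, qN = (Fm − Fm′)/(Fm − F0′),
qP = (Fm′ − Ft′)/(Fm′ − F0′), Fq′ = Fm′ − Ft′ per light step. Two
notational decisions: the light-adapted steady state is written Ft′
throughout (sources often alternate between Ft and Ft′ for the same
quantity), and Fq and Fq′ are treated as one quantity per light step. NPQ
and qN use the same-day dark-adapted Fm as reference. The algebraic
identity QY′ = qP · Fv′/Fm′ is enforced to 10⁻¹² by property tests, and
invalid signals raise errors at derivation instead of being clamped, so
data problems surface during QA rather than as silent trait shifts.

Morphology traits are computed from the binary mask under conventions
chosen to be standard, exactly testable, and monotone in the directions
the stress responses require:

* area = foreground pixels × scale²; perimeter = crack (exposed-edge)
  length, which has exact closed forms on rectangles;
* compactness = area / convex-hull area, with the hull taken over pixel
  corners so a filled rectangle scores exactly 1;
* roundness = 4π·area/perimeter², clipped at 1;
* eccentricity and isotropy from the eigenvalues λ₁ ≥ λ₂ of the
  second-moment tensor: `sqrt(1 − λ₂/λ₁)` and `λ₂/λ₁`;
* RMS (rotational mass symmetry) = mean Jaccard overlap with the k = 8
  centroid rotations (nearest-neighbour resampling);
* SOL (slenderness of leaves) = (skeleton length)²/area with a Zhang–Suen
  topological skeleton; length counts orthogonal links as 1, diagonal
  links as √2, plus 1 per connected piece, so an n-pixel straight run has
  length n and a single pixel has SOL 1 by convention.

The commercial phenotyping software that inspired these traits does not
publish its formulas; numerical agreement with it is therefore not claimed,
and each definition is documented here so an alternative dialect can be
substituted deliberately. Components use 8-connectivity, cracks
4-neighbour edges; all dimensionless traits are computed in pixel units and
are exactly scale invariant. Every trait is verified against an
independent brute-force pixel-loop implementation on random masks.

# Statistics

Per-day group comparisons use the classic equal-variance two-sample
Student's t-test (Welch behind a flag), starred at p < 0.05, 0.01, 0.001,
0.0001 with no multiple-testing correction by default — matching the
per-day starring convention of this analysis style; a Benjamini–Hochberg
option exists in `compareByDay(adjust =)`. Interaction models fit
`value ~ genotype + treatment + genotype:treatment` by OLS separately for
each stress level against control, with WT/control reference coding; the
"treatment" factor is therefore two-level within each fit. Correlations
are Pearson with p from the t-distribution on n − 2 df; dead plants drop
out listwise. Tray effects are deliberately not modelled (fixed-effects
lm only), matching the analysis this package re-implements.

One statistical subtlety the test suite respects: within one simulated
experiment the many trait × day tests share plant-level latent variables,
so their p-values are strongly correlated and a binomial confidence band
across those tests is invalid. Calibration of the type-I error is
therefore checked across *independent replicate experiments*.

# Classification

The genotype classifier minimises mean logistic loss plus λ‖w‖₁ with an
unpenalized intercept, from a zero start. Two authored optimizers are
provided — cyclic coordinate descent with a ¼-bound quadratic majorization
(default) and proximal gradient with a spectral step — both monotone in
the objective and both stopped on the KKT residual, so they agree at the
unique optimum; an external solver is used only as a cross-check in the
tests. Design decisions where the analysis description was open:

* the sample unit is the plant-day with time pooled (no per-day models);
* cross-validation is stratified 5-fold *grouped by plant* — every imaging
  day of a plant stays in one fold, eliminating temporal leakage, which
  would otherwise inflate accuracy substantially;
* λ is chosen per outer fold by an inner 3-fold grouped grid search over
  eight log-spaced values below the analytic all-zero threshold
  `lambdaMax()`; ties go to the sparser model;
* standardization (z-scoring) is refit on each training partition only;
* reported accuracy is the mean outer-fold accuracy and is labelled a
  cross-validation estimate;
* the task is strictly binary (WT vs *hsp101*).

Trait ranking orders traits by absolute standardized weight, breaking ties
lexicographically and dropping exact zeros.

# Numerical choices

* Determinism: every stochastic function takes an explicit seed, restores
  the caller's RNG state, and derives per-plant-day child seeds by a
  Lehmer step kept below 2³¹; identical seeds give byte-identical outputs
  including rendered rasters.
* Optimizer tolerances: KKT residual ≤ 10⁻⁷ by default (10⁻⁵ inside
  cross-validation, where accuracy is insensitive to the last digits);
  non-convergence returns a flagged partial model with a warning rather
  than an error.
* Degenerate inputs: empty masks, all-constant feature columns,
  zero-variance samples, and collinear pixel sets each have a defined
  behaviour (error, drop-with-warning, or flagged limit value) exercised
  by tests.
* Thermal rasters are stored in TIFF as °C/100 because 32-bit float TIFF
  samples only round-trip reliably inside [0, 1]; readers undo the scale.
* Problem sizes: the validation suite runs the full 160-plant experiment
  once for the headline-pattern checks and uses 6–10 replicates per group
  elsewhere; oracle-equivalence checks use 200 random masks up to 64 × 64
  pixels. These sizes were chosen to give stable statistics while keeping
  a complete run comfortably reproducible on a laptop.

# Known limitations

The generator's trait covariance is mediated by one latent tolerance
variable; real rosettes correlate through many more channels, so absolute
classification accuracies on synthetic data are not comparable to
published accuracies on real screens (the qualitative ordering across
treatment groups is the tested claim). The morphology trait definitions
are one defensible dialect among several. The fluorescence model treats
F0′ as measured rather than estimated from F0 and quenching; instruments
differ here. Leaf-angle responses are only visible through their projected
side effects (RMS, acute area shrink), as in any top-view-only protocol.
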