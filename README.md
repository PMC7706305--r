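# heatPheno

Analysis pipeline for image-based **heat-stress phenotyping of Arabidopsis
rosettes**, aimed at plant phenomics groups who screen genotypes for
acquired thermotolerance with automated platforms combining kinetic
chlorophyll fluorescence, top-view RGB and thermal imaging.

The package covers the full chain for a factorial screen — two genotypes
(wild type and the heat-susceptible *hsp101* mutant) × four regimes
(control, 3 h, 6 h, 9 h at 45 °C) × 20 replicates, imaged daily from one
day before stress (DAS −1) to seven days after:

* **Synthetic experiment generator** — raw fluorescence light curves,
  parametric binary rosette masks, thermal rasters and an experiment
  registry with the statistical structure the analysis assumes (growth
  penalties proportional to stress hours, genotype-dependent recovery,
  heat-induced mortality, and a latent per-plant tolerance coupling early
  quenching to later growth). The raw data of such screens are typically
  not public; the generator makes every stage testable end to end.
* **Fluorescence traits** — the standard PAM parameters per light step
  (Lss1–Lss6): Fv = Fm − F0, QY max = Fv/Fm, Fv′, QY′ = (Fm′ − Ft′)/Fm′,
  NPQ = (Fm − Fm′)/Fm′, qN = (Fm − Fm′)/(Fm − F0′),
  qP = (Fm′ − Ft′)/(Fm′ − F0′), Fq′ = Fm′ − Ft′.
* **Morphometry** — area, crack perimeter, convex-hull compactness,
  roundness, moment eccentricity/isotropy, rotational mass symmetry (RMS),
  skeleton-based slenderness of leaves (SOL), and mask-guided mean leaf
  temperature.
* **Statistics** — per-day Student's t comparisons with significance
  stars, `trait ~ genotype * treatment` interaction models per stress
  level, Pearson correlograms, and cross-time trait correlations (e.g.
  Fq on the stress day vs rosette area a week later, per stratum).
* **Classification** — L1-regularized logistic regression (authored
  coordinate-descent and proximal-gradient solvers with KKT-based
  convergence), cross-validated with plant-grouped stratified folds, and
  coefficient-based trait ranking.

## Worked example

```r
library(heatPheno)

design <- buildDesign(nReps = 20, seed = 1)       # 160 plants, 8 trays
res    <- simulateTraitTable(design, SimulationParams(), seed = 1)
table  <- applyExclusionFilter(res$table, plantRegistry(res$experiment))

# When does quantum yield recover after 6 h of heat?
qymaxRecoveryDay(table, "WT", "HS6h")      # 1  (one day after stress)
qymaxRecoveryDay(table, "hsp101", "HS6h")  # 2  (the mutant lags a day)

# Does early quenching predict later size? (6 h, WT stratum)
crossTimeCorrelation(table, "Fq_Lss5", 0, "area", 7)
#   genotype treatment     r      p  n
# ...    WT      HS6h  0.63  0.0028 20   (r is ~0.07 for same-day area)

# Which regime separates the genotypes best?
fm <- buildFeatures(table, "HS6h")
cvAccuracy(fm, k = 5, seed = 10)$accuracy  # ~0.85; control stays near 0.5
```

The printed numbers read as: the wild type's dark-adapted Fv/Fm is back at
control level one day after stress while *hsp101* needs two; photochemical
quenching measured on the stress day correlates with rosette area a week
later (but not with same-day area) in stressed plants; and the 6 h regime
yields the highest genotype classification accuracy of the four groups —
the intermediate stress is the most informative.

`runPipeline(defaultRunConfig(outDir = "run", seed = 1))` executes the
whole chain (simulate → extract → filter → stats → classify) and writes
trait, statistics, correlogram and classification CSVs plus a hashed
manifest; `inst/scripts/phenoheat.R` wraps the same functions as a command
line.

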