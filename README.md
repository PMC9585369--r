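# instarcluster

Density-based determination of insect larval instars from morphometric
measurements, built around the tomato leafminer *Tuta absoluta*.

Larvae of *T. absoluta* mine leaves, stems and fruit, and their instars look
alike — yet instar-specific biology (susceptibility to *Beauveria bassiana*
and Bt, predator preference for first instars) makes knowing the instar
essential for control. The sclerotized head capsule and mandibles grow only
at molts, so a sample of larvae covering the larval period forms discrete
clusters in the space of head capsule length, head capsule width and
mandible width (cm). This package:

* clusters the three features with **OPTICS** (density-based cluster
  ordering: core-distance, reachability-distance, reachability-plot valleys,
  flat extraction by threshold or ξ-steep areas), with **DBSCAN**,
  **k-means** (Lloyd) and **Gaussian mixtures** (EM over six covariance
  families, selected by `BIC = 2 log L − m log n`, larger is better) as
  comparative backends, and measures pairwise agreement by adjusted Rand
  index;
* validates any instar partition with the classical battery:
  **Brooks–Dyar indices** `b_i = x̄_i / x̄_{i−1}` (Dyar's rule of geometric
  growth), **Crosby indices** `C_i = (b_{i+1} − b_i)/b_i` with the |C| < 0.10
  rule, the **growth regression** `ln(size in mm) = a + b · instar` whose
  `e^b` is the growth-rate constant, size-frequency overlap analysis and a
  PCA projection;
* generates **synthetic measurement tables** reproducing the published
  four-instar study conditions (240 specimens in groups of 69/42/35/94,
  published per-instar means, CVs and variation ranges, truncated trivariate
  normal with inter-feature correlation 0.8), so every stage is reproducible
  without raw specimen data.

## Worked example

```r
library(instarcluster)
tab <- generate_instar_dataset(generator_config(seed = 1))
report <- run_pipeline(tab, "optics", seed = 1)
report
```

```
instar pipeline run: optics  seed = 1
K = 4  sizes: 69, 42, 35, 94  noise: 0
ARI vs generated truth: 1
ln(head_capsule_length, mm) = 0.479 * instar -0.240
growth rate e^b = 1.614  R^2 = 0.986  RSS = 1.212  df = 238
ln(head_capsule_width, mm) = 0.448 * instar +0.212
growth rate e^b = 1.564  R^2 = 0.993  RSS = 0.523  df = 238
ln(mandible_width, mm) = 0.430 * instar -0.515
growth rate e^b = 1.538  R^2 = 0.984  RSS = 1.136  df = 238
Crosby rule pass (|C| < 0.10): TRUE  frequency overlap: FALSE
```

OPTICS at `minPts = 5` finds four instars with exactly the generating group
sizes and no noise; each feature grows geometrically across instars
(growth-rate constants ≈ 1.5–1.6 per molt, R² ≥ 0.98), successive
Brooks–Dyar ratios change by less than 10% (Crosby rule satisfied), and
adjacent instars' size ranges do not overlap. Running the comparison
backends at their standard settings,

```r
cmp <- compare_methods(tab, configs = list(
  optics = list(method = "optics"),
  dbscan = list(method = "dbscan"),   # eps = 0.04 cm, minPts = 4
  kmeans = list(method = "kmeans"),   # k = 4
  gmm    = list(method = "gmm")))     # BIC over 1..9 components, 6 families
cmp$ari
```

gives an all-ones adjusted-Rand matrix: all four methods produce identical
instar clusters, and BIC selects the unconstrained (VVV) mixture with four
components.

The `analysis/` directory replays this as a narrative workflow —
`01_simulate.R`, `02_cluster_optics.R`, `03_compare_methods.R`,
`04_validate_instars.R` — writing the measurement table, reachability
profile, BIC table, agreement matrix, per-instar summary and regression
fits under `results/`.

The methods vignette (`vignettes/instar-determination.Rmd`) documents the
clustering model, the extraction-threshold choice, the validation rules and
what the synthetic generator does and does not emulate.

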