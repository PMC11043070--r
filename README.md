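# ghostmap

Analysis pipeline for lineage-traced neuronal populations containing
"Ghost" cells — reporter-positive neurons that no longer express the
identity marker whose promoter drove the trace (e.g. *Pomc* neurons of the
hypothalamic arcuate nucleus after tamoxifen-induced CreERT2 labelling).
Because promoter-based detection misses these cells by construction, their
characterisation runs on four data modalities, all covered here:

* **Image quantification** — segmentation of reporter-positive cells in
  multichannel stacks (thresholded connected components, 2D projections or
  full 3D), per-cell mean/max channel intensities, typical-vs-ghost
  classification on the identity-marker channel (`mean` intensity,
  `statistic >= threshold` positive), marker co-positivity calls (`max`
  intensity), and per-animal cohort statistics (Student's t, Shapiro-gated
  one-way ANOVA + Tukey, Pearson correlation with covariates such as body
  weight).
* **3D spatial statistics** — Gaussian-product-kernel density fields of
  cell centroids on regular grids, super-level-set (isosurface) summaries,
  a node-wise paired t-test between subpopulations over the occupied
  region (the "p-value spheres" analysis, with a calibrated permutation
  variant), and rostro-caudal cumulative distributions compared via
  Gaussian-CDF least-squares fits,
  `F = ((RSS_pooled − RSS_sep)/(df_pooled − df_sep)) / (RSS_sep/df_sep)`.
* **Electrophysiology** — input resistance from hyperpolarizing step
  trains (slope of ΔV vs I), rheobase and spike-shape features
  (threshold at dV/dt > 20 mV/ms, amplitude, halfwidth, fAHP, mAHP),
  pre/post hormone deltas from monitor pulses, and the response rule:
  activated iff ΔRMP ≥ +2 mV and |ΔRi| ≥ 10 %, inhibited iff
  ΔRMP ≤ −2 mV and |ΔRi| ≥ 10 %, otherwise non-responsive; category
  tables compared by Pearson's chi-squared.
* **Patch-seq clustering** — log1p counts-per-10⁴ normalisation, PCA +
  kNN-graph Leiden clustering with silhouette-based resolution selection,
  relative-expression and marker-panel summaries, per-cluster QC, and
  cluster-composition shift tests between diet conditions.

A first-class synthetic-data module (`gen_image_stack()`,
`gen_point_cloud()`, `gen_ephys_cohort()`, `gen_step_train()`,
`gen_count_matrix()`) generates all inputs with known ground truth, so the
whole pipeline is exercisable and testable offline.

## Worked example

Classify two simulated patched cohorts' leptin responses and compare their
category distributions:

```r
library(ghostmap)

pomc <- gen_ephys_cohort(n_per_class = c(activated = 8, inhibited = 9,
                                         nonresponsive = 7),
                         noise_sd = 0, seed = 1)
ghost <- gen_ephys_cohort(n_per_class = c(activated = 5, inhibited = 2,
                                          nonresponsive = 17),
                          noise_sd = 0, seed = 2)
cat_levels <- c("activated", "inhibited", "nonresponsive")
tab <- rbind(
  pomc  = table(factor(call_hormone_responses(pomc$traces,  600)$category, cat_levels)),
  ghost = table(factor(call_hormone_responses(ghost$traces, 600)$category, cat_levels))
)
response_contingency_test(tab)
#> <contingency_test> chi2(2) = 9.314, p = 0.009497
#> # A tibble: 6 × 5
#>   population category          n   pct pct_int
#>   <chr>      <chr>         <int> <dbl>   <dbl>
#> 1 pomc       activated         8 33.3       33
#> 2 pomc       inhibited         9 37.5       38
#> 3 pomc       nonresponsive     7 29.2       29
#> 4 ghost      activated         5 20.8       21
#> 5 ghost      inhibited         2  8.33       8
#> 6 ghost      nonresponsive    17 70.8       71
```

Each trace is processed from raw voltage samples: the membrane potential is
averaged over 30 s windows before and 5 min after application (spikes and
monitor pulses masked), the input resistance is measured from the −5 pA
monitor-pulse deflections in each phase, and the ≥2 mV / ≥10 % rule is
applied. The typical (`pomc`) cohort splits 33/38/29 % across
activated/inhibited/non-responsive, while 71 % of the ghost cohort is
non-responsive; the chi-squared test (χ² = 9.31, df = 2, p ≈ 0.0095) says
the two populations respond differently.

The other stages chain the same way, e.g.

```r
sim <- gen_image_stack(n_cells = 200, ghost_fraction = 0.10, seed = 1)
cells <- segment_cells_3d(sim$stack, "reporter") |>
  quantify_rois(stack = sim$stack) |>
  classify_lineage_cells() |>
  dplyr::mutate(animal_id = "mouse1")
summarize_cohort(cells, by = character())
#> # A tibble: 2 × 5
#>   animal_id class_label     n   pct pct_int
#>   <chr>     <chr>       <int> <dbl>   <dbl>
#> 1 mouse1    ghost          20  10.2      10
#> 2 mouse1    typical       176  89.8      90
```

See `vignettes/ghost-neuron-analysis.Rmd` for the models, parameter
conventions and limitations.

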