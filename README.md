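# p38nfkb

Simulation and analysis of combinatorial p38 and NF-κB signaling dynamics
in single macrophages.

Macrophages respond to innate-immune stimuli (P3C4/TLR2, CpG/TLR9,
LPS/TLR4, TNF/TNFR) through two parallel signaling axes — the transcription
factor NF-κB and the stress kinase p38 — whose single-cell trajectory
*pairs* encode stimulus identity and dose. This package is for systems
biologists who want to simulate and dissect that combinatorial code. It
provides:

* **A branched pathway simulator** (`simulate_cell()`,
  `simulate_population()`): p38 activation through IKK/Tpl2→MKK3/6 (fast)
  and TAK1→MKK4 (slow) branches coupled to a reduced IκB–NF-κB
  negative-feedback module, with lognormal cell-to-cell parameter
  heterogeneity (σ = ln 2 / Φ⁻¹(0.995) ≈ 0.2691, putting 99% of each
  parameter within twofold of its median) and module-wise "denoising".
* **Trajectory processing** (`preprocess()`, `quality_filter()`,
  `call_responders()`, `extract_features()`): baseline/drift correction,
  the 3×SD / 3-frame / 1-h responder rule, and a catalog of dynamic
  features plus 30-min activity integrals.
* **Information and classification** (`knn_mi()`, `mi_extrapolated()`,
  `train_eval_tree_ensemble()`, `shuffled_pairing()`): the
  discrete–continuous k-nearest-neighbour mutual-information estimator
  ψ(N) − ⟨ψ(N_c)⟩ + ψ(k) − ⟨ψ(m_i)⟩ with jackknife subsample
  extrapolation (12 subsamples, 65–90%, MI regressed on 1/n), and bagged
  decision-tree classifiers (30 trees, ≤20 splits, stratified 5-fold CV)
  with shuffled-pairing controls.
* **Dose response** (`build_dose_response()`, `fit_hill()`,
  `half_max_fold_difference()`): responder-fraction curves and the
  four-parameter Hill fit
  A = maxA·cᴴ/(halfAᴴ + cᴴ) + intersect under the bounds
  HillC ∈ [0.1, 10], maxA ∈ [0, 1], intersect ∈ [0, 0.9].
* **Correlation structure** (`spearman_paired()`, `shuffle_control()`,
  `coefficient_of_variation()`): paired p38↔NF-κB Spearman correlations
  with the p < 0.05 ∧ |CC| > 0.15 significance mask.
* **AND-gate gene expression** (`simulate_mrna()`,
  `population_expression()`, `fano_factor()`, `bimodality_coefficient()`,
  `permutation_test_mean_diff()`): the kinetic mRNA model
  d[mRNA]/dt = k_syn·Hill(NF-κB) − k_deg·Hill⁻(p38)·[mRNA]
  in which NF-κB drives transcription and p38 stabilises the transcript,
  scored by Fano factor and bimodality coefficient.

Everything is tidyverse-native: functions take data frames, return
tibbles, chain with the pipe, and fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(p38nfkb)
library(dplyr)

# 1. Simulate a heterogeneous LPS-stimulated population (500 cells)
pop <- simulate_population(
  population_spec(n_cells = 500, seed = 1),
  default_stimulus_program("LPS")
)

# 2. Extract dynamic features and look at paired correlations
ft <- extract_features(pop)
cor(ft$p38_integral_000_030, ft$nfkb_integral_000_030, method = "spearman")
#> [1] 0.5189
cor(ft$p38_integral_210_240, ft$nfkb_integral_210_240, method = "spearman")
#> [1] 0.4329
```

The early (0–0.5 h) p38×NF-κB integral correlation (0.519) exceeds the
late (3.5–4 h) one (0.433): early activity reflects the receptor input the
two pathways share, while late activity is dominated by module-intrinsic
noise.

```r
# 3. How much stimulus information do p38 features carry?
pop_tnf <- simulate_population(population_spec(n_cells = 500, seed = 2),
                               default_stimulus_program("TNF"))
both <- bind_rows(pop, pop_tnf)
fb <- extract_features(both)
mi <- mi_extrapolated(fb$stimulus, select(fb, starts_with("p38_")), seed = 1)
mi
#> Dropped 1 feature column(s): p38_first_peak_width
#> Extrapolated mutual information: 1 bits
#>   12 subsamples of n = 650-900 (of 1000), k = 3
```

Two fully distinguishable stimuli carry 1 bit; the estimate extrapolates
to that ceiling, meaning LPS and TNF p38 trajectories are essentially
perfectly separable in feature space. (One feature column is dropped
before scaling because it contains missing values for non-responding
flat-ish cells.)

```r
# 4. The lognormal heterogeneity contract
tab <- sample_parameters(population_spec(n_cells = 1e5, seed = 1),
                         pathway_parameters())
mean(between(tab$p38_tot, 0.5 * 0.4, 2 * 0.4))
#> [1] 0.99006
```

About 99% of sampled totals lie within twofold of the representative
value, as the sampler's shape parameter guarantees.

## Documentation

The methods vignette (`vignettes/p38nfkb-methods.Rmd`) describes the
model structure and its assumptions, the heterogeneity and denoising
machinery, every estimator's conventions and tolerances, and known
limitations. Function-level documentation is in the roxygen comments in
`R/`.
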