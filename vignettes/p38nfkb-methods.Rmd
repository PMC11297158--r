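---
title: "Modeling combinatorial p38 and NF-kB signaling in single macrophages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling combinatorial p38 and NF-kB signaling in single macrophages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Macrophages sense pathogen- and host-derived signals (P3C4/TLR2, CpG/TLR9,
LPS/TLR4, TNF/TNFR) and respond through at least two parallel signaling
axes: the transcription factor NF-kB and the stress kinase p38. In single
cells both responses are dynamic and heterogeneous, and the *combination*
of their trajectories — not either pathway alone — carries information
about stimulus identity and dose. This package provides a simulator of
paired single-cell p38/NF-kB trajectories plus the downstream analytics
(feature extraction, mutual information, classification, dose-response
fits, correlation structure, and an AND-gate gene-expression model) needed
to study that combinatorial code quantitatively.

## The pathway model

p38 is activated through two branches that share upstream receptor input
but differ in kinetics:

* **IKK → Tpl2/p105 → MKK3/6 → p38.** IKK phosphorylates p105, whose
  degradation releases active Tpl2; Tpl2 drives MKK6 double
  phosphorylation. This branch is fast.
* **TAK1 → MKK4 → p38.** TAK1 drives MKK4 double phosphorylation; in the
  shipped LPS program TAK1 activity rises slowly, making this the late
  branch.

Both MKK6-pp and MKK4-pp doubly phosphorylate p38; pp-p38 is the reported
p38 activity. Each two-step phosphorylation is reduced to a Hill-type rate
in the *driving* kinase with a pseudo-first-order dependence on the
substrate form:

$$ \frac{d[S_p]}{dt} = v\,\frac{D^{n}}{K^{n}+D^{n}}\,([S_u]-[S_p]) - \dots $$

Two properties motivated this reduction: kinase-family mass
(\(S_u + S_p + S_{pp}\)) is conserved *exactly*, and the dynamics of the
phosphorylated *fractions* are independent of the family total, so doubling
total p38 doubles the pp-p38 trace while leaving its timing untouched —
the behaviour expected of an abundance parameter.

Receptor-proximal biochemistry is deliberately replaced by parametric
input curves: per-stimulus difference-of-exponentials pulses for IKK and
TAK1 (LPS adds a delayed second IKK phase standing in for TRIF-dependent
signaling), bounded to [0, 1]. Dose scales each curve through a saturating
occupancy term; the TAK1 branch carries a higher dose EC50 than the IKK
branch, which reproduces the experimental observation that p38 activation
requires substantially more ligand than NF-kB activation.

NF-kB is modeled with a reduced 4-state IkB feedback module: IkB mRNA,
free IkB, the cytoplasmic NF-kB:IkB complex, and nuclear NF-kB (free
cytoplasmic NF-kB is closed algebraically, so total NF-kB is conserved
exactly). IKK degrades IkB free and in complex; released NF-kB imports
into the nucleus and induces IkB resynthesis — the classical negative
feedback responsible for adaptation and damped oscillation. A full
receptor-resolved NF-kB parameterization exists in the literature, but
only its mechanistic skeleton matters for the questions this package
addresses (shared upstream input; IkB feedback nonlinearity), so the
reduced module is a deliberate design decision.

### The representative cell and its calibration

The shipped defaults of `pathway_parameters()` are the "representative
cell". Dataset-level rate constants for this architecture are not
available as printed values, so the defaults were calibrated against the
canonical stimulus phenotypes the experimental literature establishes,
using the same machinery exposed to users through `fit_representative()`:

* TNF: fastest time-to-half-max and lowest pp-p38 amplitude of the four
  stimuli; transient.
* LPS: biphasic pp-p38, with the MKK6-pp peak preceding the MKK4-pp peak
  by tens of minutes.
* P3C4: highest amplitude, moderate width. CpG: slow and broad.
* pp-p38 peaking near 0.08 uM at the highest doses, nuclear NF-kB in the
  0.05–0.3 uM range.

`fit_representative()` itself minimises the summed squared error of a
chosen parameter subset against stimulus-labeled target pp-p38 traces,
optimising on the log scale with derivative-free Nelder–Mead (integrator
tolerance makes finite-difference gradients unreliable at small residual
scales), and recovers kinase totals essentially exactly from
self-generated targets.

### Units

Experimental p38 activity is a baseline-deducted KTR cytoplasmic/nuclear
ratio (A.U.); NF-kB is baseline-deducted nuclear fluorescence (A.U.).
`rescale_units()` converts A.U. to model uM with per-channel factors. The
p38 factor is 0.08/0.73 = 0.1096 (maximal experimental C/N ratio mapped to
an assumed 0.08 uM maximal pp-p38). The conventional NF-kB factor 0.0383
maps a 7.62 A.U. 90th-percentile LPS response to 0.30 uM; note that
0.30/7.62 rounds to 0.0394, not 0.0383 — the published convention is kept
as the default and the discrepancy documented here.

## Heterogeneity and denoising

Cell-to-cell variability is generated by sampling ten parameters per cell
from lognormal distributions with median at the representative value:
three kinase totals (p38, MKK4, MKK6), the shared receptor-curve
amplitude, and six NF-kB-module parameters (total NF-kB, IkB mRNA
synthesis, translation, IKK-driven IkB degradation, nuclear import,
export). The shape parameter is
\(\sigma = \ln 2 / \Phi^{-1}(0.995) \approx 0.2691\), the unique value for
which exactly 99% of lognormal mass lies within twofold of the median.
All ten names use this default; which non-kinase parameters the original
experimental calibration distributed, and with what spreads, is not
public, so a single declared shape is used for all of them.

"Denoising" a module (`population_spec(denoise = ...)`) replaces its
sampled parameters by the representative value, localising heterogeneity
sources. Two population-level patterns are built into the shipped
calibration and asserted by the test suite at a fixed seed (500 LPS
cells, seed 1):

* The Spearman correlation between paired p38 and NF-kB 0–0.5 h activity
  integrals exceeds that of the 3.5–4 h integrals: early activity reflects
  the shared receptor input, while late activity is dominated by
  module-intrinsic parameters (the NF-kB feedback's adaptation largely
  discounts the input amplitude at late times).
* Denoising the NF-kB module *increases* the max-amplitude and
  total-activity correlations: with the independent NF-kB noise removed,
  the shared receptor amplitude dominates what variability remains.

Getting these right constrains the model's operating points: the Tpl2 and
TAK1 Hill drivers must not saturate (else the shared amplitude stops
propagating into p38), and NF-kB:IkB complex degradation must be slow
enough that the released fraction — hence nuclear NF-kB — remains
sensitive to IKK amplitude. The experimental observation of *negative*
late-time correlations is not reproduced and not attempted: it implicates
an unidentified cross-regulation mechanism outside this model's scope;
the simulator only reproduces the decay of the positive correlation.

## Trajectory processing and features

The long trajectory format is uniform 5-min frames, six baseline frames at
negative times, stimulation at t = 0, and 97 post-stimulus frames to 480
min (classification conventionally consumes the first 95). `preprocess()`
subtracts the per-cell baseline mean and, given at least eight mock
trajectories, a smoothed mock-derived drift curve. `quality_filter()`
applies configurable presence/completeness/extremity rules and reports
per-rule removals; exact production-pipeline thresholds are not public,
so defaults are permissive and all thresholds live in the rules object.

A cell is a **responder** when its activity exceeds 3x its own baseline SD
for 3 consecutive frames within 1 h of stimulation (`call_responders()`);
noise-free fixtures fall back to an absolute floor of 1e-3 A.U.

`extract_features()` computes, per pathway, 12 named dynamic features
(activation/deactivation speed, amplitude, derivatives, first-peak width
at half prominence, supra-threshold duration, total activity and its
half-time, dominant frequency, peak count, early/late ratio) plus sixteen
30-min interval integrals tiling 0–8 h. Declared conventions:
time-to-half-max is the first linearly interpolated crossing of half the
maximum; duration is total (not necessarily contiguous) time above the
responder threshold; the dominant frequency is the argmax of DFT power of
the linearly detrended 0–4 h segment excluding the zero bin; derivatives
are central differences over one frame; `total_activity` equals the sum of
the interval integrals to machine precision by construction. The full
published feature catalog (hundreds of features) is not reproduced; this
set covers every feature the analyses here need and is extensible.

## Information, classification, dose response, statistics

**Mutual information.** `knn_mi()` implements the discrete–continuous
k-nearest-neighbour estimator
\(I = \psi(N) - \langle\psi(N_c)\rangle + \psi(k) - \langle\psi(m_i)\rangle\)
(k = 3 by default, the standard choice for this estimator) on z-scored features
(`clean_and_scale()` drops missing-value and constant columns first).
`mi_extrapolated()` controls finite-sample bias by one subsample draw at
each of 12 sizes spanning 65–90% of the data, regressing MI on 1/n and
reporting the intercept; the within-range size schedule and single draw
per size are declared choices. Negative raw estimates are reported as
computed.

**Classification.** `train_eval_tree_ensemble()` uses bagged decision
trees (30 trees, `mtry` = all predictors, at most 20 splits via
`maxnodes = 21`), z-scoring across classes, class balancing by
downsampling, and stratified 5-fold cross-validation with per-class equal
fold counts (stratified fold construction is a declared package choice).
`shuffled_pairing()` permutes one pathway's rows across all classes to
destroy within-cell pairing, resampling an identity permutation. An LSTM
time-series classifier is a common alternative route for raw-trajectory
classification; this package ships only the tree ensemble, which is the
surface all quantitative checks use.

**Dose response.** `build_dose_response()` computes responder fractions
per dose (mock encoded 100x below the lowest dose, for the log axis);
`fit_hill()` fits
\(A = \mathrm{maxA}\,c^{H}/(\mathrm{halfA}^{H}+c^{H}) + \mathrm{intersect}\)
by bounded nonlinear least squares (HillC in [0.1, 10], halfA in
[min, max] dose, maxA in [0, 1], intersect in [0, 0.9]) from five
deterministic log-spaced halfA starts, best residual winning; doses are
weighted equally. Flat responses are
flagged unidentifiable rather than fit.

**Statistics.** Spearman correlations use average-rank ties; p-values use
the t approximation above n = 30 and a seeded 10,000-draw permutation
below; the significance mask requires
p < 0.05 *and* |CC| > 0.15. The Fano factor is sample variance over mean
(n − 1 denominator), zeros retained. The bimodality coefficient is
\((g_1^2+1)/(g_2 + 3(n-1)^2/((n-2)(n-3)))\) with bias-corrected sample
skewness/kurtosis, computed on non-zero values for expression data. The
permutation test for mean differences is two-sided with \(p = (1+\#\{|\Delta_{perm}|\ge|\Delta_{obs}|\})/(n_{perm}+1)\).

## AND-gate gene expression

The mRNA model couples the two pathways with opposite signs:

$$ \frac{d[mRNA]}{dt} = k_{syn,max}\frac{N^{n_N}}{K_{d,N}^{n_N}+N^{n_N}}
   - k_{deg,max}\frac{K_{d,P}^{n_P}}{K_{d,P}^{n_P}+P^{n_P}}\,[mRNA] $$

NF-kB (N) drives transcription; p38 (P) suppresses degradation,
stabilising the transcript. `NFkB_only` mode replaces the p38 Hill factor
by 1 (degradation at full rate), chosen so that the p38 → 0 limit of the
AND gate coincides with it bit-for-bit. Published parameter values for
this equation are not available; defaults (\(K_d\)s mid-range of the
simulated activities, Hill coefficients 2, \(k_{deg,max}=0.02\)/min,
\(k_{syn,max}=1\)/min) are package choices, exposed in
`gene_model_parameters()`. Inputs are clamped at 0 (baseline noise can
dip negative), linearly interpolated between frames, with mRNA starting
at 0; single-cell abundances are sampled at 0.25, 1, 3 and 8 h. On the
default heterogeneous LPS population the AND gate yields higher mean
expression than NF-kB-only from 1 h onward and an equal-or-larger Fano
factor at 8 h — the intrinsic-noise-free prediction that p38-dependent
stabilisation amplifies expression heterogeneity. Transcriptional
bursting is out of scope: the model is deterministic per cell.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable), rtol 1e-6, atol 1e-9 uM,
  output on the 5-min grid; the mRNA equation uses rtol 1e-8.
* Pre-stimulus equilibration solves the resting NF-kB module as a
  one-dimensional root problem (the kinase cascade rests at zero
  phosphorylation), verifies max |derivative| < 1e-9 uM/min, and falls
  back to relaxation over up to 5000 min; failure names the
  non-converged species.
* Hill fitting: `minpack.lm::nlsLM` under box bounds, 5 deterministic
  starts, ties by first index.
* All randomness flows through explicit integer seeds; pipeline stage i
  derives seed `seed + 1000 i`, so stages reproduce in isolation.
* Test problem sizes: the fixed-seed population checks use 500 LPS cells
  (seed 1); MI reference checks use 2000 cells per class; permutation
  calibration uses 200 replicates of 999 permutations. These sizes give
  the estimators comfortable margins relative to the asserted tolerances.

## What the simulator does and does not emulate

The generator reproduces: stimulus-specific paired trajectory shapes,
lognormal parameter heterogeneity with the 99%-within-twofold contract,
module-wise denoising, baseline frames and frame-rate conventions, and
toy pulse fixtures with analytic features. It does not emulate: imaging
noise and segmentation/tracking artefacts, receptor-level biochemistry,
negative late-time cross-pathway correlations, transcriptional bursting,
or scRNA-seq count statistics (measured counts enter only through
`read_counts()`). Tests passing on simulated populations therefore
validate the analytics and the model's qualitative structure, not the
quantitative behaviour of any particular experimental dataset.

## Known limitations

* The representative-cell rate constants are package calibrations, not
  published measurements; quantitative outputs (e.g. absolute correlation
  values) should be read as qualitative patterns.
* The Hill-reduced cascade omits explicit kinase-phosphatase enzymes;
  dephosphorylation is first-order.
* `fit_representative()` optimises a declared parameter subset; fitting
  all rates simultaneously is possible but not identifiable from four
  target traces.
* The dose → input-curve mapping is a single saturating occupancy term
  per branch; real dose responses may be steeper or shallower per
  stimulus.
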