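---
title: "Committor-based reaction coordinate optimization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Committor-based reaction coordinate optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rcoptim)
```

## The model

A two-state conformational transition (closed ↔ S1) is summarized by the
committor `p(S1|x)`: the probability that dynamics launched from
configuration `x` reaches the S1 state before the closed state. The package
fits the working model

  p(S1|x) ≈ σ(z),  z = Σ_k w_k · (f_k(x) − μ_k)/σ_k + b,  σ(z) = 1/(1+e^(−z)),

a logistic function of a *linear* combination of z-scored structural
features. Two assumptions are load-bearing: (i) the committor is well
approximated by a logistic along an adequate coordinate, and (ii) an
adequate coordinate is linear in the chosen features. When the feature set
lacks a relevant factor, the fit still yields the best linear combination
of what it was given — but not the true reaction coordinate; the
transition-state diagnostics (`ts_diagnostics`) are the check, not the fit
quality alone. The weights are estimated by *least squares on the
probabilities* (not cross-entropy), which treats a committor estimate of
0.48 vs 0.52 as the near-tie it is; `z = 0` is the transition state by
construction because `σ(0) = 0.5`.

Fitting proceeds in stages, each with its own guardrail:

1. committor-correlation filter (`|r| > 0.1`) removes features carrying no
   marginal signal;
2. Leiden/CPM clustering of the absolute-correlation graph at resolution
   0.6, followed by per-cluster PC1 reduction and a second-round merge of
   reduced features with `|r| > 0.7`, removes the multicollinearity that
   would otherwise make coefficients uninterpretable;
3. a Monte-Carlo add/remove search over feature subsets, scored by the
   mean adjusted R² of bootstrap fits on a validation split, with
   worst-first pruning of coefficients whose bootstrap sign test exceeds
   p = 0.05, repeated independently; features present in at least 17% of
   the final subsets are retained;
4. final coefficients are averages over stratified bootstrap refits, with
   R²/MAE/MSE reported on a held-out, committor-stratified test set.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| contact cutoff | 0.45 | nm | heavy-atom minimum-distance contact rule |
| persistence | 0.70 | fraction | of frames × symmetry-fold instances |
| symmetry fold | 5 | — | homopentamer contact pooling |
| coordination r0, n | 0.3, 6 | nm, — | rational switching function midpoint/steepness |
| template filter | 0.25 | absolute Pearson r | against the contact-PCA PC1 transition template |
| retained PCs | 2 / 5 | — | contacts / distances CV construction |
| shots per snapshot | 100 | — | binomial SE ≈ 0.05 at p = 0.5 |
| committor filter | 0.1 | absolute Pearson r | entry to the decorrelation stage |
| Leiden resolutions | 0.6 / 0.2 | — | feature clustering / CV splitting |
| merge threshold | 0.7 | absolute Pearson r | second-round reduction |
| bootstraps | 20 / 300 | — | subset scoring / coefficient finalization |
| retention | 0.17 | fraction of repeats | subset-frequency cutoff |
| TS stripe | [−0.25, 0.25] | CV units | σ(±0.25) ≈ 0.44–0.56 |
| umbrella window, bias | 0.5, 50 | CV units, kJ/mol | spacing and harmonic strength (≈ 18.8 kT at 320 K) |
| RT | 2.661 | kJ/mol | 320 K |

`selection_config()` defaults to the production-scale search budget
(1000 proposals × 100 repeats × 20 bootstraps, sized for feature sets in
the hundreds-to-thousands). `run_benchmark()` uses 150 × 12 × 20: the
planted benchmark offers 60 features of which a handful survive screening,
so the larger budget only re-walks the same small subset lattice.

## The synthetic benchmark

`benchmark_system()` defines the study system: a quartic double well along
the transition coordinate (wells at ±1, barrier 4 kT — low enough that
reactive paths and first-passage statistics are affordable on a desk) plus
one harmonic orthogonal mode (stiffness 4 kT), integrated by overdamped
Euler–Maruyama dynamics at kT = 1 with friction 1 and timestep 0.01 in
arbitrary simulation time units. Inertia is deliberately absent: the
overdamped engine admits an *exact* committor,

  q(x) = ∫_a^x e^{U/kT} dy / ∫_a^b e^{U/kT} dy,

(`analytic_committor_1d`), which serves as the oracle for every shooting
test; "fresh Maxwell–Boltzmann velocities" of an inertial engine map to
fresh, independent noise streams per shot.

`feature_embedding_spec()` dresses the latent coordinate up as a feature
table with the statistical structure the analysis has to cope with:

* 5 informative features: four saturating sigmoids whose midpoints are
  spread across the transition region plus one linear map, each with
  additive Gaussian noise (sd 0.3 against a ±1 link span). The spread
  midpoints make the informative features *complementary* reporters — each
  resolves a different stage of the transition, the way distinct contacts
  break at distinct points — so their pairwise correlations sit below the
  0.7 merge threshold over the committor records and the selection is
  forced to keep all of them rather than one representative.
* 55 decoys independent of the transition: 45 white singletons and two
  collinear blocks of 5 sharing a latent factor at pairwise correlation
  0.9. Blocks are labelled as distance-kind features (adjacent helical-turn
  distances co-vary in real data); this also keeps the contact family's
  PC1 template aligned with the transition rather than with a block
  factor. The `|r| > 0.25` template screen is what eliminates white decoys:
  over the pooled path frames their correlation with the template is
  O(n^−1/2) ≈ 0.015, far below threshold, whereas at the committor stage
  alone (a few hundred records) chance correlations above 0.1 would be
  routine.

What the generator does *not* emulate: time-correlated decoys (a real
contact series has memory; set `decoy_ar` to probe this), heavy-tailed
noise, feature nonstationarity across replicas, and any coupling of the
orthogonal mode into the features. A pipeline that passes here has been
shown to recover a planted truth under honest noise and multicollinearity —
not that it will recover the truth of any particular protein.

Benchmark problem sizes (the package's own choices): 12 reactive paths with
300 frames of committed dwell context per side, all reactive-zone frames
shot at 100 shots each, then stratified down to 300 committor records in 10
bins; a 30-record test split. The umbrella scan uses 4 replicate scans of
~24 windows (25 time units of production each, all windows propagated in
lock-step); kinetics uses one 6,000-time-unit equilibrium run.

## Numerical choices

* **Shooting.** Uncommitted shots (step budget exhausted) are excluded from
  the committor denominator and reported separately: the conditional
  estimate is unbiased, and the count is the user's warning flag. Per-shot
  streams derive from a documented hash (`derive_seed`), so any record is
  exactly reproducible.
* **Logistic least squares.** Levenberg–Marquardt with an analytic
  Jacobian; initialization at weights 0, intercept logit(mean p) clamped to
  [0.01, 0.99]. Non-convergence raises a classed condition; bootstrap
  drivers respond by drawing a fresh replicate, and coefficient
  finalization errors out if more than 10% of replicates fail.
* **Acceptance rule.** Subset moves are accepted on strict improvement of
  the mean adjusted R² (a Metropolis temperature is exposed but defaults
  to 0); subset scores are cached within a repeat.
* **Coefficient p-values.** Bootstrap sign test, p = 2·min(frac(w>0),
  frac(w<0)) — coarse at 20 replicates (the smallest nonzero p is 0.1), by
  design: a coefficient survives search-stage pruning only when its sign is
  unanimous across replicates.
* **Validation split.** How large the validation set should be, and whether
  it is redrawn, is genuinely open. Drawing it once proved actively harmful
  at benchmark scale: with ~270 non-test records a single unlucky 10% draw
  can hide a genuinely informative feature from *every* repeat, because all
  repeats then score subsets against the same 27 records. The default
  therefore redraws a stratified 15% validation split per repeat, which
  decouples the retention frequencies from any single draw;
  `redraw_validation = FALSE` restores the fixed-split behaviour.
* **States and ties.** State regions are axis-aligned, half-open boxes
  (`[lo, hi)` per axis), so every point has exactly one label and boundary
  ties resolve deterministically. The density-derived regions ignore speck
  components (< 5% of high-density bins) and, if the two main components'
  bounding boxes overlap diagonally, trim both along the axis of larger
  centre separation.
* **WHAM.** Self-consistent binned iteration (bin width 0.25 CV units,
  tolerance 1e−8, max 1e5 iterations), with an explicit adjacent-window
  overlap check. Replicate profiles are interpolated to a common grid,
  anchored at zero in the closed-side minimum, and averaged with SEM.
  Because the fitted CV saturates outside the wells (vanishing dz/dx bends
  the marginal down again), basin analysis runs on the window-covered core
  range; `analytic_profile_on_cv` provides the matching quadrature oracle.
  The biased integrator's timestep is set from the bias stiffness through
  the CV's maximum slope.
* **Basins.** The 1RT rule: each basin is the contiguous interval around
  its minimum where the profile stays within RT of it. A secondary interior
  maximum only makes the profile "multimodal" (an error) when the valley
  between it and the principal barrier is deeper than 0.5 RT — flat barrier
  plateaus and bin noise are tolerated.
* **Transition times.** A barrier crossing counts only if the path then
  reaches the S1 basin before re-entering the closed basin; raw first
  crossings would count recrossings and bias the mean time low. Paths
  without a committed crossing are censored with a reason. The attempt
  frequency ν_c counts upward crossings of the closed basin's 1RT level per
  residence time and is a lower bound at finite frame spacing.
* **Eyring–Polanyi.** k_TST = ν_c·exp(−F_TS/RT): the exponent is negative —
  the barrier suppresses the rate — which the worked numbers (10 kJ/mol,
  0.85 ns⁻¹, 320 K → ≈ 50 ns) confirm.
* **Split CV.** When dividing the optimized coordinate into two
  interpretable parts (Leiden at resolution 0.2), the intercept goes to the
  part with the larger weight norm; with the shared coefficients the parts
  sum exactly to the full coordinate.

## Limitations

* Structural-mode biased sampling is out of scope: the optimized CV is
  exported (`write_cv_json`, `rc_as_linear_cv`) for use in an external
  engine, but umbrella sampling in this package runs only on the synthetic
  engine, where bias forces flow through the embedding's smooth mean map.
* The committor model is linear-logistic by construction; systems whose
  committor is genuinely multivariate-nonlinear in any feature basis will
  show it in the stripe diagnostics, not in a fitting error.
* Turn annotations are user-supplied; the package does not detect
  secondary structure.
* Conductance is a gross event count at one salt concentration; the
  documented ×0.1 physiological scaling is a note, not a model.
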