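# rcoptim

Committor-based reaction coordinate optimization for two-state
conformational transitions.

## The problem

A protein that switches between two metastable conformations — here the
gating of a mechanosensitive channel from its closed state to a first
sub-conducting intermediate (S1) — is best described by a *reaction
coordinate*: a single scalar function of the configuration that tracks
progress through the transition. The ideal reaction coordinate is the
**committor** `p(S1|x)`, the probability that dynamics started at
configuration `x` reaches S1 before returning to the closed state; the
transition state is the `p = 0.5` surface. The committor itself is far too
expensive to evaluate everywhere, so the practical task is to find an
interpretable surrogate — a linear combination of structural features
(residue contacts, coordination numbers, inter-helix distances) — that
reproduces it.

`rcoptim` implements that workflow end to end:

1. **Featurization** — persistent residue contacts under rotational
   symmetry (4.5 Å heavy-atom rule, 70% persistence), smooth coordination
   numbers `s_ij = 1 / (1 + (r_ij/r0)^6)`, and distances between
   helical-turn centres of mass; a PC1 transition template filters features
   at `|r| > 0.25`.
2. **Collective variables** — PCA + linear SVM classifiers separating the
   end states give two preliminary CVs (contacts-based and
   distances-based); path density in their 2D space defines the state
   regions and the reactive zone between them.
3. **Committor estimation** — shooting: `n` short relaxations with fresh
   noise from each reactive-zone snapshot; `p = n_S1 / (n_S1 + n_closed)`.
4. **Reaction-coordinate optimization** — the core model. Assuming
   `p(S1|x) ≈ 1 / (1 + exp(-z))` with `z = Σ w_k f_k + b` over scaled
   features, the weights are found by least squares on the committor
   values. Features are first decorrelated (Leiden/CPM clustering of the
   `|r|` graph, per-cluster PC1), the optimal subset is found by a
   Monte-Carlo add/remove search scored by bootstrap-averaged adjusted R²
   on a validation split with p-value pruning, and the final coefficients
   are bootstrap-averaged. The result is an `rc_fit` object with `print`,
   `summary`, `coef`, `predict`, `plot`, `residuals` and `simulate`
   methods; `z = 0` is the transition state by construction.
5. **Free energy** — umbrella sampling along the optimized CV
   (harmonic bias, WHAM unbiasing, replicate-profile averaging), 1RT basin
   definition, barrier height, and `ΔF = -RT ln(P_S1 / P_closed)` by
   Boltzmann integration over the basins.
6. **Kinetics and transport** — committed transition times with an
   ECDF-exponential fit and a two-sample Kolmogorov–Smirnov check, the 1RT
   attempt frequency `ν_c`, the Eyring–Polanyi rate
   `k_TST = ν_c exp(-F_TS / RT)`, and ion permeation counting
   `G = N e / (|V| T)` for channel conductance.

Because the original molecular-dynamics trajectories are not required, the
package ships a **synthetic benchmark**: overdamped Langevin dynamics on a
double-well potential with an *exact* 1D committor oracle
(`analytic_committor_1d`), dressed up as a realistic feature table
(informative features monotone in the transition coordinate, decoys,
collinear blocks, noise). Every stage of the pipeline is validated against
that ground truth.

## Worked example

```r
library(rcoptim)
bench <- run_benchmark(seed = 1)   # full synthetic pipeline, ~20 s

bench$state_definition
#> <state_definition>
#>   closed   [-3.68, -2.58) x [-3.26, -1.66)
#>   S1       [2.43, 4.14) x [1.68, 3.51)
#>   reactive [-2.58, 2.43) x [-4.39, 4.77)

summary(bench$fit)
#> Optimized reaction coordinate - bootstrap summary
#>
#>             estimate boot_se p_value
#> (intercept)   0.2575  0.1145      NA
#> rf001        -0.3497  0.1165  0.0067
#> rf002        -2.3659  0.1478  0.0000
#> rf003         0.6909  0.1420  0.0000
#>
#> Test-set metrics (bootstrap means): R2 = 0.75  MAE = 0.117  MSE = 0.0235

bench$ts_diagnostics$mean_committor   # observed committor in the z in [-0.25, 0.25] stripe
#> [1] 0.56
```

The fitted model keeps three decorrelated feature clusters (`rf001`–
`rf003`, each a PC1 over planted informative features); every coefficient
differs from zero at the bootstrap sign test. The held-out test-set R² of
0.75 is limited by the 100-shot binomial noise on the committor estimates;
against the *exact* committor of the generating potential the predicted
committor reaches R² ≈ 0.93. Snapshots near the coordinate's zero have a
mean shooting committor of 0.56 — the stripe straddles the transition
state, as an adequate reaction coordinate must.

Free energy and kinetics on the same benchmark:

```r
fep <- benchmark_free_energy(bench)   # umbrella + WHAM along the fitted CV
fep$basins$barrier_height             # ~4.8 kT (matches the analytic marginal)
kin <- benchmark_kinetics(bench, fep)
kin$fit$tau                           # empirical mean transition time
kin$ratio                             # TST-vs-empirical rate ratio (~1.2)
```

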