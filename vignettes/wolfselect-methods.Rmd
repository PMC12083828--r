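---
title: "Methods: grey wolf wrapper feature selection with adaptive mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grey wolf wrapper feature selection with adaptive mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolfselect)
```

## The model

`wolfselect` performs wrapper feature selection: a candidate feature subset
is scored by the cross-validated error of a classifier trained on exactly
those features, and a population metaheuristic searches the `2^D` subset
space. The intended data regime is high-dimensional and small-sample
(tens to low hundreds of samples, hundreds to thousands of features), as in
microarray gene-expression classification.

Each of the `n` search agents ("wolves") carries a continuous position in
`[0, 1]^D`. The binary solution exists only through the stochastic sigmoid
transfer: coordinate `j` selects feature `j` with probability
`sigma(x_j) = 1 / (1 + exp(-10 (x_j - 0.5)))`. Keeping the dynamics
continuous and binarizing at evaluation time preserves the original GWO
update equations; the steepness 10 makes the transfer near-deterministic
once a coordinate commits to either half of the cube.

The fitness of a mask is the mean per-fold error rate of a K-nearest-
neighbour classifier (Euclidean distance on the selected columns) under
stratified k-fold cross-validation. There is no subset-size penalty in the
objective: pressure toward small subsets arises only insofar as noise
features raise the error. This matches the protocol the package implements
and explains why returned subsets on easy problems tend to stay near half
of `D` (the mass of the binomial initialization).

### Baseline dynamics

Per iteration, with convergence factor `a` decayed from 2 to 0, each wolf
moves toward a consensus of the three current best wolves: for each leader
`l` in (alpha, beta, delta), independent per-dimension coefficients
`A = 2 a r1 - a`, `C = 2 r2` are drawn, the distance
`D_l = |C_l * X_l - X|` is formed, the guide is `X_l - A_l * D_l`, and the
new position is the mean of the three guides, clipped to `[0, 1]^D`.
Leaders are the three best agents of the current population; the
best-so-far solution is tracked separately and never worsens, giving a
nonincreasing convergence trace.

### The three adaptive mechanisms

* **Nonlinear parameter control (APC).** `a = 2 - 2 sin((pi/2) (t/T)^3)`
  replaces the linear ramp. The schedule stays above the linear one for
  most of the search (the crossover sits past mid-search), sustaining
  exploration, then collapses rapidly. The loop counter `t` is 1-based;
  `t = 0` is accepted as the analytic endpoint where the factor equals 2.
* **Adaptive fitness-distance balance (AFDB).** Every odd iteration, each
  candidate is scored `S = normF + normDP`: min-max-normalized fitness
  (oriented so the lowest error maps to 1, since the objective is
  minimized) plus min-max-normalized Euclidean distance to the best-so-far
  position. The highest-scoring candidate replaces the wolf's own position
  in the distance terms, steering the pack through good-but-diverse
  regions. On even iterations the original own-position update is used.
* **Adaptive neighborhood mutation (ADV).** Each guide `X_k` is perturbed
  by `(X_best - X_k) * randn` with per-dimension standard-normal draws:
  mean-zero noise whose scale is the guide's offset from the best-so-far
  solution, so mutation intensity shrinks automatically as the pack
  converges. Guides are not re-clipped after mutation; the single
  projection onto `[0, 1]^D` happens when the guides are combined.

All mechanisms are toggles on one shared loop, so any subset can be
enabled: all three is AMGWO, single ones are the ablation variants, none
is the baseline GWO (bit-identical under the same seed — this is asserted
in the tests). None introduces an extra loop: every variant performs
exactly `n` evaluations per iteration, `O(n d T)` coordinate work overall.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n` | 30 | population size; at least 4 (three leaders + a follower) |
| `T` | 100 | iterations; with `n` this fixes the evaluation budget `n(T+1)` |
| `knn_k` | 5 | neighbours in the wrapper classifier |
| `folds` | 10 | stratified CV folds; reduced to `L` on tiny data (leave-one-out) |
| `scale_features` | off | per-fold z-scoring, fitted on training folds only |
| `scalar_mutation_noise` | off | one normal draw per guide instead of per dimension |

The defaults `n = 30`, `T = 100`, `K = 5`, 10-fold CV are the standard
comparison protocol for this family of feature-selection studies. Feature
scaling is off by default because the target benchmark matrices arrive
pre-processed; the flag exists for raw data with heterogeneous column
scales.

## Determinism and numerical choices

* **One master seed per run** derives separate sub-seeds (pure integer
  hash, all below `2^31`) for the fold shuffle and for the search stream;
  exported entry points restore the caller's RNG state. Identical
  `(dataset, config, seed)` gives identical results, and sweep runs are
  reproducible in any execution order because per-run seeds are a pure
  function of (master seed, dataset index, algorithm index, run index).
* **Fold partitions are fixed for a whole run**, so fitness is a
  deterministic function of the mask within a run and agents compete on
  identical partitions.
* **KNN ties** — both equal-distance neighbours and tied votes — resolve
  toward the lowest class code (then lowest sample index), making the
  wrapper fully deterministic. This is also why the package carries its
  own KNN rather than delegating to implementations with randomized tie
  breaking.
* **Empty masks** (all bits zero after binarization) are repaired to one
  uniformly random selected bit: the classifier needs at least one column
  and the candidate encoding requires a nonempty subset.
* **Degenerate FDB ranges**: when all fitnesses (or all distances) are
  equal, that normalized term is defined as 0 for every candidate, so a
  fully collapsed population scores uniformly 0.
* **Parity of the AFDB alternation** uses the 1-based counter, so the
  first iteration already uses the FDB reference.
* **`X_best` in the mutation is the best-so-far solution**, not the
  current alpha: with elitist bookkeeping the two can differ, and the
  mechanism's anchor is the global incumbent.
* The guide equations use independent coefficient draws per leader; the
  second and third guides follow beta and delta respectively (the
  symmetric completion of the update across the three leaders).
* Positions are clipped to `[0, 1]` once per update, after combining
  guides, keeping the sigmoid operating range centred.

## The synthetic generator

`make_microarray()` draws a Gaussian class-conditional model with equal
spherical covariance: all `D` features have noise SD `noise_sd`; the
planted informative features add a mean shift of `class_sep * noise_sd`
between adjacent classes; the rest are label-independent noise. Class
sizes are as equal as possible so stratified 10-fold CV remains valid at
small `L`. The ground-truth indices are returned beside the dataset, never
inside it, so recovery experiments stay blind.

What it emulates: the dimensions, sample sizes and sparse-signal structure
of the benchmark regime. What it does not emulate: gene-gene correlation,
batch effects, heavy-tailed intensities, class imbalance. Tests passing on
this generator therefore demonstrate the mechanics of the search and the
scoring, not performance on real transcriptomes.

Two regimes matter for interpretation, and the test suite uses both
deliberately:

* At the study shape `L = 60, D = 200` with 10 planted features at 3-SD
  separation, the problem is *easy*: nearly any mask containing a few
  planted features reaches zero CV error, so the fitness landscape is flat
  at its optimum and the optimizer has no gradient left to climb. Under an
  error-only objective, enrichment of planted features beyond a random
  mask of equal size is then marginal by construction — the
  planted-recovery study in the acceptance tests reports exactly this, and
  its enrichment assertion documents the limitation rather than the
  package's mechanics.
* Noise dilution — the phenomenon that motivates feature selection — only
  appears once noise dimensionality dominates the signal. The dilution
  property is therefore exercised at a Colon-like shape
  (`L = 40, D = 2000`, 5 planted features, 5-SD separation), where the
  all-features mask measurably underperforms the informative-only mask.

## Problem sizes in the tests

The suite favours many small instances over few large ones: oracle
comparisons run on instances with `L <= 30, D <= 10` (50 random cases for
the KNN wrapper, 100 populations for the FDB scores, full permutation
enumeration for the rank-sum test), the worked fixture is `20 x 6`, and
the recovery study uses `L = 60, D = 200` with `n = 30, T = 100` over 10
seeds per algorithm — ample to exercise every code path while keeping the
whole suite in minutes on one core.

## Known limitations

* The wrapper classifier is KNN only; the fitness slot is internal and not
  yet pluggable for other classifiers.
* The objective carries no subset-size term, so on problems where many
  masks tie at the optimal error the returned subset size is essentially
  the initialization mass (about `D/2`), and ties freeze the incumbent on
  the first optimal mask found.
* Wilcoxon p-values are reported per comparison without multiple-testing
  correction, matching the evaluation convention this battery mirrors.
* Dataset input is CSV (features plus a final `label` column); no binary
  interchange formats are read.
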