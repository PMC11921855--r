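---
title: "Cross-lagged panel network methodology in clpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel network methodology in clpnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpnet)
```

## The estimand

A cross-lagged panel network (CLPN) treats p symptoms measured on the same
subjects at two waves as a directed network: the weight of edge *i → j* is
the coefficient of symptom *i* at T1 predicting symptom *j* at T2 after
adjusting for every other T1 symptom. Diagonal entries are autoregressive
paths (a symptom predicting itself), off-diagonal entries cross-lagged
paths. The p regression equations are estimated independently, one LASSO
per T2 target, so the network is simply the p × p array of selected
coefficients.

Two assumptions matter. First, linearity on the observed score scale:
ordinal 0–3 items are treated as continuous outcomes and predictors. This
is the standard approximation in temporal symptom-network work; it costs
some attenuation (see the generator section) but keeps coefficients
comparable and estimation convex. Second, two waves only: the model says
nothing about dynamics between or beyond the waves, and edge weights are
specific to the panel's lag.

## Estimation choices

**Standardization.** Both predictors and outcomes are z-standardized
within the analyzed group before fitting. Standardizing the predictors is
required for the L1 penalty to treat coefficients symmetrically;
standardizing the outcome as well makes edge weights unit-free and
comparable across equations and across groups, which the between-group
comparisons rely on. Whether the outcome should also be standardized is
genuinely open in this literature; we standardize and state it, since
reported weights are uninterpretable without knowing the convention.

**Objective.** Each equation minimizes `(1/2n) Σ r² + λ Σ|β|`. The
normalization is part of the model definition: a λ value is meaningless
without it. Selected penalties are reported per target.

**Penalty path and selection.** The grid is 100 log-spaced values from
λ_max (the smallest penalty with an all-zero solution, `max_j |x_j'y|/n`)
down to `1e-4·λ_max`. Ten-fold cross-validation with a single seeded fold
shuffle per equation (seed = master seed + target index, recorded in the
fit) selects the λ minimizing mean squared prediction error; ties break
toward the larger λ, i.e. the sparser model. The 1-SE rule is available
(`rule = "1se"`) but the CV minimizer is the default, matching common CLPN
practice. Covariates are penalized together with symptom predictors —
the default of standard LASSO tooling — and are reported separately,
never as network edges.

**Solver.** Cyclic coordinate descent on precomputed Gram matrices
(`X'X/n`, `X'y/n`), warm-started down the path, with the sweep in compiled
code. Covariance updates make each sweep O(k²) regardless of n, so a full
10-fold CV fit of all nine equations takes well under a second. The
convergence tolerance is 1e-10 on the maximum coefficient change;
coefficients inside the soft-threshold dead band are exact zeros, so
"absent edge" means exactly zero, never a small number. With the penalty
disabled the solver reproduces least squares, and its objective values
agree with an independent proximal-gradient oracle to 1e-6 (both are
tested).

**Degenerate inputs.** Zero-variance predictor columns are flagged and
contribute zero coefficients; a zero-variance outcome yields an all-zero
incoming column with a warning. Groups below 20 subjects trigger an
instability warning; the pipeline skips groups below a configurable
minimum (default 50) entirely.

## Trajectory stratification

PHQ-9 totals (0–27) are dichotomized at a cutoff, default 7, with "7 or
more" counting as probable depression — the boundary subject with a total
of exactly 7 is depressed. The 2×2 pattern over the two waves maps
deterministically to chronic / delayed / recovery / resistance; there is
no latent-class machinery, by design. Percentages are reported rounded
half-up to one decimal, with raw proportions retained. Note that published
applications of this scheme are not always internally consistent about the
resulting group percentages (the same cohort is described with different
chronic/resistance shares in different sections of at least one report);
this package reproduces the arithmetic that follows from the stated group
counts and total.

## Centrality and comparison

Expected influence sums signed edge weights: out-EI(i) = Σⱼ B[i,j], in-EI(j)
= Σᵢ B[i,j]. The *cross-lagged* variant removes the node's own
autoregressive path from both sums; *cross-construct* additionally removes
edges within a community (with a single symptom community it is
identically zero and is computed only on request). Tables report raw and
z-standardized values; the z-transform is monotone, so ranks are shared.
The *overall* variant with z values is the headline report; which variant a
given published table used is not always stated, so both overall and
cross-lagged are written by the pipeline.

Between-group similarity is the Pearson correlation of vectorized edge
matrices. Whether the autoregressive diagonal belongs in that vector is a
convention, not a fact; both versions (81 and 72 elements) are computed,
with the diagonal included by default. The attached p-value uses the
`t = r √((m−2)/(1−r²))` transform as if the m edges were independent —
they are not, so the output labels it approximate.

## Resampling diagnostics

**Edge accuracy.** Nonparametric bootstrap (default 1000 replicates):
subjects are resampled with replacement and the full procedure — including
CV penalty re-selection — is re-run per replicate; 95% intervals are the
empirical 2.5/97.5 percentiles. Percentile rather than BCa intervals keep
replicate storage simple and match standard network-toolkit defaults. A
`refit = "fixed_lambda"` fast mode freezes the point fit's penalties; it
is used by the test suite and is appropriate whenever penalty-selection
variability is not itself under study. Replicates with degenerate columns
are retained (affected coefficients zero) and flagged.

**Difference tests.** Two edges, or two nodes' centralities, differ
significantly when the percentile interval of their per-replicate
difference excludes zero. The decision is symmetric and self-comparisons
are never significant.

**CS coefficient.** For each drop proportion q on a fixed grid (0.10 to
0.70 in steps of 0.05), `reps_per_level` subsamples of size `round(n(1−q))`
are drawn without replacement, the network refit, and the subsample
centrality correlated with the full-sample centrality. CS is the largest q
whose 5% correlation quantile still reaches 0.7. The fixed grid with fixed
replicates per level is a transparent variant of the usual sampled-
proportion procedure; threshold 0.7 and confidence 0.95 follow the
convention behind the usual "≥ 0.25 acceptable, ≥ 0.5 preferred" reading.
The number of replicates per level and the grid are package defaults, not
field-mandated constants. An undefined correlation (a constant centrality
vector, as happens on pure-noise refits) counts as 0 — instability, not
missingness. Note that a CS near the grid maximum requires centralities
that are *heterogeneous* across nodes as well as stable: if all true
centralities are equal, their sample rank order is exchangeable and the
correlation criterion cannot be met no matter how much data there is.

**Seeding.** Every resampling routine spawns independent per-replicate
substreams from the master seed, so results are bit-reproducible and
independent of execution order. Identical configuration + seed yields
byte-identical pipeline output files (tested).

## The synthetic generator

`generate_panel()` draws T1 latents from a multivariate normal (default
exchangeable correlation 0.4, a typical inter-item correlation for
depressive symptoms), propagates them through a sparse latent cross-lag
matrix B plus Gaussian innovations to give T2 latents, and discretizes
both waves at thresholds (0.5, 1.2, 2.0) into 0–3 scores. At zero mean
shift those thresholds give the right-skewed score distribution (≈ 70%
zeros) typical of community PHQ-9 data. Two deliberate design choices:

- The cross-lag feed uses the *centered* T1 latents, and the raw T2 latent
  is rescaled to unit variance (analytic mean/sd) before the wave-2 mean
  shift is added. Each wave's severity is therefore governed by its mean
  shift alone, which is what makes the four scenario presets (high/low
  shift at each wave: +1.3 / −0.3, chosen once from the threshold
  arithmetic so the expected total lands clearly above or below the
  cutoff) land their cohorts in the intended trajectory.
- Ground truth travels with the panel, so recovery checks never
  reconstruct it implicitly.

What the generator does *not* emulate: item-level measurement
non-invariance, missingness, three-wave dynamics, floor effects beyond
thresholding, and selection into the cohort. Passing recovery tests
therefore show that the estimator works under its own assumptions — a
linear latent process observed through ordinal cuts — not that real
panel data satisfy those assumptions.

**Attenuation.** Discretizing latents shrinks observed correlations, so
estimated standardized edges are biased toward zero relative to the
latent-scale B (and the unit-variance rescaling additionally scales each
target column). Recovery is accordingly judged by correlation and sign
agreement between true and estimated matrices, never by absolute equality;
at n = 2000 the vectorized correlation is typically ≈ 0.9 with complete
sign agreement on edges of magnitude ≥ 0.2 (computed in the test suite and
acceptance script).

## Problem sizes used in the checks

The test suite fits networks at n between 100 and 2000, runs bootstrap
checks at 200 replicates × 20 experiments (fast mode), CS checks on a
13-level grid × 100 replicates, and the full pipeline on a four-scenario
cohort of 800 subjects — sizes at which every property under test (support
recovery, coverage, CS saturation/collapse, determinism) is already
stable. The defaults users see (1000 bootstrap replicates, full-procedure
refits) are the analysis-grade settings.

## Limitations

Edge estimates are regularized, hence biased toward zero; CIs around them
describe sampling variability of the *procedure*, not debiased effects.
The elementwise-independence p-values for network correlations are
approximate. The deterministic cutoff rule inherits the measurement error
of a sum-score screen; boundary subjects move groups if the cutoff
convention changes (we use ≥ 7 at both waves, stated prominently, since
that choice changes group composition). Ordinal items are modeled
linearly; rank-based or ordinal-link variants are out of scope.
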