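---
title: "Power-law modeling of cell fates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-law modeling of cell fates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powerfate)
```

## The models

`powerfate` relates the activities $x_1,\dots,x_n$ of measured signaling
proteins (e.g. phosphorylation levels, arbitrary positive units) to the
probability $P$ of a cell fate, typically the apoptotic fraction of a cell
population. Two model kinds are fitted by partial least squares regression
(PLSR):

* **linear**: $P = \sum_i \alpha_i x_i + \text{intercept}$ — the classical
  data-driven signaling model;
* **power-law**: $P = e^{\beta_0}\prod_i x_i^{\beta_i} + \epsilon$, fitted in
  log space as $\ln(P-\epsilon) = \beta_0 + \sum_i \beta_i \ln x_i$.

The power-law form is the S-system ansatz of biochemical systems theory:
many biological dose–response relationships are straight lines in log–log
coordinates over wide ranges, and a product of powers composes gracefully
through a signaling cascade (the exponents add along paths). Its key
assumptions are that all signals are strictly positive, that the fate value
exceeds the offset $\epsilon$, and that fold changes — not increments — are
what propagate.

Both kinds reduce to one linear PLS regression, so their comparison is an
honest like-for-like: the same estimator, the same component count, applied
to raw versus log-transformed coordinates.

### Parameters that matter

* `epsilon` ($\epsilon \ge 0$, same units as the fate): keeps the power
  function off the origin and must be below the smallest training fate
  value; the default `1e-6` is effectively "no offset" for probability-scale
  fates. It is validated at fit time, stored in the model and applied at
  prediction.
* `n_components`: PLS components, default `min(10, min(p, n - 1))`. Fewer
  components regularize collinear predictor sets; the full count reproduces
  ordinary least squares on full-rank problems (a property the test suite
  pins against the normal equations at `1e-8`).
* Centering/scaling: predictors and responses are mean-centered and scaled
  to unit **sample** standard deviation ($n-1$ denominator) before PLS;
  coefficients are mapped back, so models predict on the original scale.
  The same sample-SD convention is used by `sigmoid_normalize()` and
  `reverse_dream8_normalization()`; fixing one convention everywhere is what
  makes serialized models and reports exactly reproducible.

## Evaluation metrics

`kl_divergence(p, p_hat)` is the base-2 loss
$L(p,\hat p)=\sum_{i=1}^m p_i\log_2(p_i/\hat p_i)$ over the $m$ pooled
predictions. Two conventions are deliberate: predictions are clipped to
$[10^{-12}, 1]$ before the logarithm (the fitted models can stray outside
$(0,1]$), and the pairs are *not* renormalized into a distribution — $m$ is
simply the number of predictions, so losses from different protocols add.
Over proper distributions the loss is the usual non-negative divergence;
over raw prediction lists individual terms can be negative, which is why the
non-negativity checks in the tests draw normalized vectors.

`aic(loss, k, m)` is $\log_2 L + 2k/m$. The base-2 logarithm matches the
base-2 loss it wraps; with the package's conventions the printed losses of
the combined breast-cancer comparison (450.5 and 1117.5 bits at $k=33$,
$m=32{,}800$) map to AIC 8.8 and 10.1 at one decimal, which a natural-log
reading does not reproduce. A `base` argument exposes the natural-log
variant.

RMSE appears in two flavors: curve-fitting reports divide the SSE by the
residual degrees of freedom (`goodness_of_fit(..., rmse_type = "dof")`,
matching standard curve-fitting tools), prediction pipelines divide by the
number of predictions (`rmse()`). Both are exported; each caller documents
which it uses.

## Curve-family comparison

`fit_family()` fits $y = ax^b$, $y = ax+b$, $y = ae^{bx}$ and
$y = a e^{-((x-b)/c)^2}$ by Levenberg–Marquardt least squares
(`minpack.lm`), with deterministic initialization: the log-linear closed
form for the power and exponential families, and (max $y$, argmax $x$,
half-range) for the Gaussian. If an initial fit fails, three multiplicative
jittered restarts under a fixed seed are tried, so results are reproducible
without being brittle. `compare_families()` ranks by dof-RMSE, breaking
ties by larger $R^2$ and then family name.

## Influence matrix and virtual knock-down

`fit_influence_matrix()` estimates
$x_i = e^{\lambda_{i0}}\prod_{j\neq i} x_j^{\lambda_{ij}} + \epsilon_i$ as
$n$ independent log-space PLS regressions with the diagonal pinned at zero.
Note an identifiability caveat that the tests make explicit: when several
proteins are deterministic functions of a common driver, only the fitted
relation — not the individual $\lambda_{ij}$ — is identified, and PLS
spreads weight across the collinear parents. Entrywise recovery is
therefore only asserted on v-structures with independent parents.

`virtual_knockdown(M, model, k)` zeroes column $k$ of the matrix (protein
$k$ influences nobody), zeroes $\beta_k$, and rewires every remaining
coefficient. Two rules are provided:

* `"replace"` (default): $\beta_j' = \sum_i \lambda_{ij}\beta_i$ — each
  protein's contribution to the fate is what it exerts *through* the others.
  This is the rule used for the drug-effect analyses on real data.
* `"additive"`: $\beta_j' = \beta_j + \sum_i \lambda_{ij}\beta_i$, which
  retains the direct effects.

The replacement rule has a structural quirk: it discards all direct
contributions, so on small sparse systems the $n$ knocked-down models become
nearly indistinguishable and the ranking loses power. The synthetic
recovery benchmark (a receptor → hub → effectors motif from `hub_lambda()`,
with the hub blocked in the drugged table) therefore uses the additive rule,
under which the blocked hub ranks first in every seeded replicate; the
benchmark's role is to verify the ranking machinery, not to adjudicate
between the rules. Knock-down is a pure function — inputs are never
mutated — and re-knocking the protein a model already has knocked down
returns the model unchanged (the model records its knocked index; the
rewiring map itself is not algebraically idempotent).

`rank_knockdowns()` sorts ascending RMSE in `"blocked"` mode (a good fit
after removal means the treatment already removed that signal flow) and
descending in `"enhanced"` mode (for stimulus analyses); ties break by
protein name.

## Evaluation protocols

Fold assignment draws one uniform permutation per repeat and cuts it into
contiguous blocks — no stratification — with the seed recorded in every
result, so 5-fold × 200 repeats yields exactly 1000 evaluated folds and the
same seed gives bit-identical reports. Folds with fewer than three test
rows or zero-variance predictions carry `NA` correlations, are flagged, and
never enter threshold counts.

The per-protein protocol for response-free data splits each cell line
2/3 : 1/3 at random, runs leave-one-out CV on the training part, averages
the back-transformed coefficient vectors (intercept included) across folds,
and scores the averaged model on the held-out third; 100 repeats by
default.

Time-staggered pairing maps the fate at output index $o>0$ to the signals
at input index $o-\text{degree}$, with the untreated baseline (index 0)
always pairing to itself and unmatched points dropped.

Cell-line discrimination projects observations onto the first two PLS
latent components (log-scale for the power-law kind) and assigns each
observation to the nearest cell-line centroid in that plane; the
misclassification count is the number of observations whose nearest
centroid belongs to another line. Nearest-centroid is the simplest rule
consistent with "clusters that are separated and concentrated"; it is a
design choice, and the score coordinates are exported so other rules can be
applied downstream.

## Synthetic data: what it emulates, and what it does not

### Ensemble Boolean simulator

`simulate_boolean()` emulates stochastic signal-transduction simulators on
the 7-node cell-death circuit of `cell_death_network()` (DNA damage →
initiator caspases → Casp3 → death, with an EGFR-driven oncogenic signature
inhibiting Casp3; all weights and input levels 0.8). Design rationale: a
single-run readout of cumulative activation frequency cannot produce the
curve shapes such simulators show — with absorbing states every node's
running frequency is $(t-t_0)/t$, and any two such curves are exactly
affine in one another, so a four-family comparison degenerates to the
linear family by construction. The package therefore simulates an
*ensemble* of cells, each with binary node states, and reports the fraction
of cells in which a node is active: a graded, saturating trajectory, which
is also what a fraction-of-dead-cells readout means experimentally. Time
scales are separated the way signaling separates them — interior cascade
steps fire at the full drive probability (phosphorylation is fast), while
receptor engagement (`input_rate = 0.015` per step × input level) and
terminal death commitment (`commitment_rate = 0.033` per step × drive) are
slow and absorbing per cell. The rates are set so that, over the default
100-step horizon, the input and death curves both traverse most of their
dynamic range rather than sitting on a plateau. Under these defaults the
death-versus-input relation is well described by a power function ($R^2
\approx 0.999$), with the Gaussian family a close second and the
exponential family clearly worse — the qualitative fingerprint the
single-variable analysis relies on. This is an emulation of a class of
simulators, not a clone of any one tool; a memoryless (`absorbing =
FALSE`) variant is included for sensitivity checks.

### Power-law and influence generators

`generate_powerlaw_dataset()` draws lognormal signals and computes the fate
exactly from the model with multiplicative lognormal noise — the parameter
recovery oracle: at zero noise the fitted exponents must match to $10^{-6}$,
and at $n=500,\ \sigma=0.05$ the exponent RMSE stays below 0.02.
`generate_influence_dataset()` propagates lognormal roots through an
acyclic influence matrix; the drugged twin of a table severs the signal
flow into the blocked protein (its value becomes independent basal noise,
its direct fate contribution is removed) while sharing the random stream
with the control, so control and drugged tables differ only where the
intervention reaches. With no blocked node the two tables are identical by
construction.

### ODE cascade

`simulate_cascade_ode()` integrates a five-species mass-action cascade
(receptor → initiator caspase → effector caspase → cumulative death, with a
survival input damping the initiator) with `deSolve`. It stands in for
large kinetic apoptosis models as a continuous-dynamics data source; it
does not attempt their mechanistic detail. The death accumulation rate
(`k3 = 0.03`) and default horizon (`t_max = 10`) keep the death readout in
its transient range across the default 3 × 3 dose design — on a saturated
readout every model looks alike and rank correlations collapse into noise.
`generate_ode_dataset()` thins the dense trajectories (the
every-200th-point convention is available through `subsample_trajectory()`)
and adds 5% multiplicative measurement noise.

What passing tests on these generators does **not** show: real
phosphoproteomics has batch structure, detection floors, antibody
cross-reactivity and missingness that is informative rather than random;
real fate fractions are compositional across several fates. The generators
model none of that, so synthetic performance bounds real performance from
above.

## Data conventions

* `filter_valid()` drops every observation with a missing, zero or negative
  signal or fate — the preprocessing rule used before any fit; it is
  idempotent and order-preserving, and parsing keeps bad cells as `NA`
  rather than failing, so the filter is auditable.
* HT-29-style feature tables (`build_ht29_features()`) treat the first grid
  point as the pre-stimulus baseline: raw and summary families use the
  measured points, derivatives span the full grid, so 19 proteins × 13
  measured points give 247 + 247 + 57 = 551 columns; the optional
  area-under-curve family brings the space to 570. Steady state is the mean
  of the last three time points — a robust stand-in for an unobserved
  equilibrium.
* The DREAM8 reversal is (i) multiply by the correction factor, (ii)
  $\log_2$, (iii) divide by the series' sample SD; a zero-variance series
  is an error, not a silent pass-through.

## Numerical choices and degenerate inputs

NIPALS iterates to a relative score tolerance of $10^{-12}$ (500 iteration
cap) and stops early when the residual of either block is numerically zero,
returning however many components were extracted; a constant response
yields zero coefficients and the mean as intercept rather than an error.
Zero-variance predictors are an error when scaling is on. Curve fits are
deterministic given the documented initialization; the three restarts use
seeds fixed in code. Sigmoid normalization maps zero-variance columns to
0.5. All generator randomness flows through `withr::with_seed()`, so no
call touches the global RNG state.

## Problem sizes in the shipped tests

The suite exercises the protocols at sizes chosen to make every property
sharp but cheap: recovery at $n \le 500$ with 4–5 proteins, 1000-fold CV on
a 450-row ODE table, 20-seed knock-down recovery at 150 observations, and
10-seed curve comparisons at 5000 ensemble cells — the full suite runs in
well under a minute. The published-data analyses run at their natural sizes
once the converted supplements are present (see the README).

## Known limitations

* Single-protein knock-downs only; simultaneous multi-protein intervention
  is not modeled.
* The replacement rewiring rule's collapse of direct effects (above) makes
  its rankings most informative on rich, collinear real datasets and least
  informative on small sparse systems.
* The power-law model requires strictly positive signals and fates above
  $\epsilon$; standardized (signed) data must be shifted or handled by the
  linear kind.
* No regularized (ridge/lasso) variants, no pathway-database lookup for
  mapping ranked proteins to upstream targets, and no raw flow-cytometry or
  RPPA format readers.
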