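---
title: "Modeling learning during the test: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling learning during the test: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opirt)
```

## The model family

When the items of a test share cognitive operations, examinees may learn
(or tire) as the test progresses, and the responses to later items then
depend on the earlier ones.  `opirt` implements a nested family of
explanatory item response models for binary scores `x_ij` of person
`i = 1..I` on item `j = 1..J`, administered in a fixed order, built around
an item-by-operation weight matrix `W` whose entry `w_jm` counts how often
operation `m` is needed to solve item `j`:

* **Rasch**: `logit P(x_ij = 1) = theta_i - beta_j`, one free difficulty
  per item.
* **LLTM**: `beta_j = sum_m w_jm alpha_m`; `alpha_m` is the difficulty of
  operation `m`.
* **OSLM** (non-contingent learning): the difficulty of operation `m`
  drops by `delta_m` for every previous use of the operation, counted over
  all earlier items regardless of the response:
  `logit = theta_i - sum_m w_jm (alpha_m - delta_m sum_{k<j} w_km)`.
* **OSCLM** (contingent learning): only practice on *correctly answered*
  earlier items counts: the inner sum becomes `sum_{k<j} x_ik w_km`.
  Because the predictor now involves the person's own earlier responses,
  the model induces local dependence among items.
* **OSDCLM** (differential contingent learning): correct and incorrect
  practice carry separate effects,
  `alpha_m - delta_m sum_{k<j} x_ik w_km - gamma_m sum_{k<j}(1-x_ik) w_km`.

Setting `gamma_m = delta_m` recovers the OSLM, `gamma_m = 0` the OSCLM,
and `delta_m = gamma_m = 0` the LLTM; an identity `W` turns the LLTM into
the Rasch model.  These identities hold exactly in the implementation and
are tested to machine precision.

Positive `delta_m`/`gamma_m` mean the operation gets easier with practice
(learning); negative values mean it gets harder (fatigue, loss of
attention).  Abilities `theta_i` are one-dimensional and the response
vectors are assumed complete and in administration order; missing or
polytomous data are rejected at the door.

## Priors and estimation

All structural parameters receive independent normal priors with mean 0
and variance 100 (SD 10) by default — weak on the logit scale — and the
abilities receive standard normal priors, which also fix the latent
scale.  Both choices are configurable (`prior_mean`, `prior_var` in
`fit_oplm()`); a sensitivity check across prior variances is part of the
test suite.

Conditional on the observed response histories, every model in the family
is a Bernoulli-logit regression with a *fixed* design: the contingent
practice counts are functions of the data, not of the parameters.
`fit_oplm()` exploits this three ways:

1. A blockwise Newton solver computes the posterior mode and curvature
   (Laplace approximation).  The ability block of the Hessian is diagonal,
   so each Newton step only solves a dense system of the size of the
   structural block.
2. Hamiltonian Monte Carlo samples the joint posterior of
   `(alpha, delta, gamma, theta)` using the full Laplace precision as a
   fixed mass matrix, factorized in its arrow form (dense structural
   block, diagonal ability block, dense cross block).  This removes the
   strong posterior correlations between an operation's difficulty and its
   practice effects, so short trajectories (4–12 leapfrog steps, jittered)
   mix well.  The step size is tuned by dual averaging to a 0.8 acceptance
   target during the burn-in half of each chain.
3. Divergent trajectories are counted and reported; momenta, kinetic
   energies and the acceptance test all use the same factorized metric.

Defaults mirror the reference analysis protocol: 4 chains of 2,000
iterations, first half discarded.  Convergence is monitored with the
split-half potential scale reduction statistic for every parameter
(threshold 1.1 by default; exceeding it attaches a warning, it does not
discard the fit).  An identification check runs before sampling and warns
rather than fails, since the prior renders the posterior proper either
way.

The sampler is validated in the test suite against an independent Gibbs
sampler (JAGS) on a small instance, by Rasch-difficulty recovery, by
interval coverage over replicated data sets, and by the nesting
identities.

## Identifiability

For the LLTM the structural block is identified when `rank(W) = M`; for
the OSLM when `rank(Q) = 2M` with `Q = (W; V)` and
`v_jm = w_jm sum_{k<j} w_km` the non-contingent practice counts.  Under
Bayesian estimation with a proper ability prior these conditions replace
the stricter classical (CML) ones, which would append a column of ones
and require `M <= J - 1` (LLTM) or `M <= (J-1)/2` (OSLM); the package
reports the Bayesian check and documents the classical one here.

For the contingent models the joint probability of a response pattern
`x_t` collapses, up to a pattern-specific normalizer, to
`lambda_t = s_t theta + r_t' xi`, where `s_t` is the number-right score
and `r_t` stacks per operation the pattern's total operation weight
(negated), its accumulated correct practice, and (OSDCLM) its accumulated
incorrect practice.  Identifiability of `xi` requires the matrix
`R+ = (R; 1)` over response patterns to have full column rank
(`2M + 1` or `3M + 1`); `check_identification()` verifies this through
the rank of the small square matrix `R+'R+`, over all `2^J` patterns or
over the patterns realized in a data set (empirical identifiability).
Rank is computed from singular values with the standard tolerance
`max(dim) * eps * sigma_max`.

`pattern_jacobian()` exposes the underlying machinery: at a fixed ability
the pattern probabilities are `p = softmax(s theta + R xi)`, the Jacobian
of `log p` is `(I - 1 p')R`, and the information matrix is `J' diag(p) J`;
a constant column in `R` produces the predicted rank deficiency.  One
subtlety is documented rather than hidden: for contingent models the
softmax (common-denominator) form is *not* identical to the product of
sequential conditionals, because the normalizer of the latter is
pattern-specific.  The package therefore uses the softmax form only for
identification analysis, while `pattern_probabilities()` — used to
validate the simulator — integrates the product-of-conditionals
likelihood over the standard normal ability distribution with 41-node
Gauss–Hermite quadrature (enumeration is guarded at `J <= 12`; 41 nodes
make quadrature error negligible at that size).

## Posterior predictive checking

`ppmc()` generates one replicated data set per retained draw.  For
contingent models replication is sequential within person: each simulated
response feeds the practice terms of the *replicated* history, never the
observed one.  Two discrepancy statistics are built in:

* **Odds ratio (OR)** per unordered item pair,
  `n11 n00 / (n10 n01)`, summed over pairs containing an item (item level)
  and over all pairs (test level) — a model-free measure of local
  dependence, the footprint of contingent learning.  Item-level sums
  count every pair twice, so they add to twice the test-level value; this
  identity is asserted for every matrix the tests touch.  A pair with an
  empty cell (common in replicated data) receives the Haldane–Anscombe
  correction — 0.5 added to all four cells of that table only — and is
  flagged; correcting rather than dropping keeps realized and replicated
  sums over the identical pair set.
* **Bayesian latent residual (BLR)**: each observation is augmented with
  a latent response `Z_ij` centred at the linear predictor and truncated
  by the response (`Z > 0` if correct, `Z <= 0` if not); squared residuals
  `(Z_ij - eta_ij)^2` are summed per item and over the test.  One latent
  draw is taken per posterior draw, by inverse-CDF sampling on the log
  scale so extreme predictors stay finite.  The latent scale is standard
  normal by default — the classical Albert–Chib augmentation, whose
  residual magnitudes match published applications of this statistic — with
  a standard logistic alternative (`latent = "logistic"`) that matches the
  link function exactly; posterior predictive p values are insensitive to
  the choice because realized and replicated residuals share it.  The
  sampler's conditional second moments are verified against numerical
  integration of the truncated distribution.

The PPP value is the proportion of draws whose replicated discrepancy is
greater than **or equal to** the realized one (ties count), and the
hypothesis of fit is rejected at the test level when PPP < .05 or > .95 —
so a degenerate PPP of exactly 1.0 rejects.  Realized OR values are
data-only constants; realized BLR values vary over draws and are reported
with their posterior SD.

## Model comparison

`waic()` and `loo_psis()` work on the pointwise log-likelihood matrix
(`pointwise_loglik()`); the prediction unit is a single response `x_ij`,
and contingent models condition on the observed history, consistent with
estimation.  WAIC uses the summed posterior variance of the log
predictive density as its complexity penalty; LOO uses Pareto-smoothed
importance sampling — generalized Pareto fitted to the largest 20% of the
importance ratios by the Zhang–Stephens empirical-Bayes method (with the
usual mild prior pulling the shape toward 0.5), tail weights replaced by
expected order statistics and truncated at the raw maximum, shapes above
0.7 flagged.  Both criteria are reported on the deviance scale
(`WAIC = -2 elpd`); `select_model()` takes the minimum, and exact ties go
to the model with fewer structural parameters.

## The simulation-study harness

`run_study()` reproduces the factorial generating-model × fitted-model
design at configurable scale.  The generator defaults *are* the reference
study conditions: abilities standard normal, `I = 536` persons, the
15 × 5 fraction-subtraction weight matrix (`fraction_weights()`), and the
reference OSDCLM structural estimates (`fraction_true_params()`) as true
values, with nested generating models dropping the blocks they do not
define.  Per cell it tabulates mean PPP and the empirical proportion of
rejections (EPR), mean WAIC/LOOIC and the empirical proportion of
selections (EPS), and the three recovery summaries (SE, absolute Bias,
RMSE — `recovery_metrics()` implements the exact averaging-over-operations
formulas and is tested against a literal loop transcription).

Every replicate's theta, data and fit seeds derive deterministically from
the master seed, so any cell can be recomputed independently and a rerun
with the same configuration replays bit for bit.  Failed fits are warned
about and excluded; non-converged fits are kept but flagged.

The package's own acceptance checks run the design at desk scale —
20 replicates per cell with 2 chains × 1,000 iterations, and PPMC on 400
draws — which reproduces the reference recovery and calibration values
within Monte-Carlo error while keeping a full run in minutes.  What the
synthetic data do *not* emulate: real response matrices have no guarantee
that a single latent dimension, the assumed weight matrix, or additive
operation effects are correct, so passing recovery and calibration tests
demonstrates the correctness of the machinery under the model, not the
adequacy of the model for any particular test.

## Numerical choices, degenerate inputs, limitations

* Bernoulli log-densities use the `x*eta - log1p(exp(eta))` form with the
  usual large-argument branches; likelihoods remain finite for
  `|alpha|, |delta|, |gamma|` up to 50 and `|theta|` up to 10 and beyond.
* Non-integer weights are accepted with a warning (the practice
  bookkeeping presumes counts); all-zero item rows or operation columns
  are rejected.
* The first item of every test has zero practice by construction; a
  one-item test yields an all-zero practice design.
* Weight-matrix CSVs are read item-major by default; the printed
  transposed dialect is handled by an explicit `transposed = TRUE` flag,
  never guessed.
* Person-specific learning parameters, nonlinear practice trajectories,
  multidimensional abilities, person covariates and polytomous responses
  are out of scope.  CML estimation is not provided; identification under
  CML is only documented above.
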