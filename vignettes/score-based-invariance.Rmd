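---
title: "Score-based measurement invariance tests: models, null distributions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based measurement invariance tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoremiv)
```

## The problem

A measurement model is *invariant* when its parameters describe every
individual equally well. In practice a factor loading, intercept, unique
variance, or factor covariance may drift with an auxiliary variable V —
age, cohort, income — and the classical approach (split into groups, fit a
multigroup model, run a likelihood ratio test) requires pre-specified
groups, one extra model fit per hypothesis, and is blind to the *ordering*
of groups: a violation rising steadily with age and an anomaly in one
middle group are treated identically. The score-based family tested here
uses one restricted fit and turns the ordering into power.

## Model and estimation

`cfa_fit()` estimates a multigroup CFA under the casewise
multivariate-normal log-likelihood with implied moments
$\mu_g(\theta) = \nu_g$ and
$\Sigma_g(\theta) = \Lambda_g \Phi_g \Lambda_g' + \Psi_g$, factor means
fixed to 0, and optional cross-group equality constraints (e.g.
`group_equal = "loadings"` for weak/metric invariance). Two
identification conventions are supported and matter for which parameters
exist to be tested:

* **marker** (default for data analysis): first loading per factor fixed
  to 1, factor variances free — the convention of the worked gratitude
  example, where the four free loadings occupy parameter positions 1–4;
* **variance** (used by the simulation engine): factor variances fixed to
  1, all loadings free — required when "all six loadings" are a tested
  set.

Numerical choices, all of which were open design decisions:

* Optimization runs on a transformed scale on which the implied
  covariance is positive definite by construction: log unique variances,
  log-Cholesky factor-covariance blocks when the whole block is free, and
  an atanh-transformed correlation when the factor variances are fixed.
  This removes the need for penalized objective values at infeasible
  iterates. Mixed free/fixed covariance patterns beyond these (and
  correlation blocks of three or more factors with fixed variances) are
  rejected with an error rather than supported half-heartedly.
* `nlminb` with analytic gradients is followed by Fisher-scoring polish
  with step halving; convergence requires the total-gradient infinity
  norm below $10^{-5}\sqrt{n}$ (so casewise score columns sum to zero an
  order of magnitude inside the $10^{-4}\sqrt{n}$ tolerance the
  fluctuation process assumes). Three jittered restarts are attempted;
  anything short of that tolerance is an error, never a silently returned
  partial result.
* Likert items are treated as continuous multivariate-normal data — the
  standard normal-theory ML practice this methodology targets; no
  polychoric machinery is involved.
* Missing data: complete-case filtering with a reported drop count. No
  direct ML for incomplete data.

Casewise scores are analytic throughout (matrix-calculus identities per
parameter role), with a central finite-difference fallback
(`scores(fit, method = "numeric")`) kept as a permanent cross-check; the
5000-replication-scale simulations are only feasible with the analytic
route. The information matrix defaults to **observed** (negative scaled
Hessian, computed by differencing the analytic gradient), with
outer-product and expected information available; under a correctly
specified model the three agree asymptotically, and the tests accept any
of them for decorrelation.

## The fluctuation process and the six statistics

`empirical_process()` builds
$B(t) = \hat I^{-1/2} n^{-1/2} \sum_{i \le \lfloor nt \rfloor}
s(\hat\theta; x_{(i)})$ after sorting observations by V. Decorrelation
always uses the **full** $k \times k$ information; testing a subset of
parameters is column selection afterwards. Decorrelating only the tested
sub-block would produce different (wrong) statistics, because the tested
parameters remain correlated with the untested ones in the joint fit.
Parameter subsets are addressed positionally (1-based, parameter-table
order) or by label; output always reports labels.

Continuous orderings use a stable sort, so tied observations keep input
order — supported, but with a warning, since the result then depends on
that arbitrary order. The ordinal statistics (`WDMo`, `maxLMo`) read the
process only at the level boundaries $i_\ell = \lfloor n t_\ell \rfloor$
and are exactly invariant to within-level reshuffling; `LMuo` uses the
squared between-level increments weighted by inverse block length, which
makes it $\chi^2_{k(m-1)}$ under the null and asymptotically equivalent
to the multigroup LRT (the package's tests verify both properties
empirically).

The `maxLM` trimming window defaults to (0.1, 0.9). The weight
$\{t(1-t)\}^{-1}$ diverges at the ends, so some trim is mandatory; the
10%/90% window is the common structural-change convention and is
user-overridable.

## Null distributions

* `DM`: analytic, $p = 1 - F(c)^k$ with $F$ the sup-of-|bridge| crossing
  series truncated at relative $10^{-12}$; independence across components
  is exactly what decorrelation buys.
* `WDMo`: the tie-point values of one component are jointly Gaussian with
  covariance $t_a(1 - t_b)$. The rectangle probability is computed by
  iterated one-dimensional integration along the bridge's Markov
  transitions on a 501-point grid per level — accurate to ~$10^{-6}$ and
  verified against raw simulation.
* `maxLMo`: simulated. Only the $m-1$ tie-point values are drawn per
  component (the finite-dimensional law is exact), not a path grid, which
  makes the default 50,000 replications cheap. Tables (`ord_l2bb()`)
  embed their seed, replication count and tie proportions, reproduce
  bit-identically, cover a requested range of process dimensions
  (default 1–20), and refuse to be applied to data with different level
  proportions.
* `LMuo`: $\chi^2_{k(m-1)}$ upper tail.
* `CvM`, `maxLM`: simulated Brownian-bridge paths on a 1000-point grid,
  20,000 replications by default (a grid-resolution test in the suite
  confirms 500- vs 2000-point grids move the 95% quantile by under 3%).

All simulated p-values carry their seed and replication count in the
result's provenance field.

## The simulation engine

`cfa_dgp()` is the two-factor, three-indicators-each design used for the
power studies. True values — loadings 1, intercepts 0, unique variances
1, factor variances 1, factor covariance 0.5, and (for misspecification
studies) an unmodeled cross-loading of 0.5 from the second factor to the
first indicator — are fixed, documented defaults chosen as a plain,
well-conditioned factor model; the package's power claims are
order-based (which test beats which) rather than tied to these values.

Violations are injected at the changepoint level $1 + m/2$: individuals
below it get the violating parameter shifted by $d$ times its asymptotic
standard error at the current $n$ (from the analytic expected information
at the true values), so $d$ is comparable across sample sizes and power
curves overlay across $n$. Levels are balanced by largest remainder.
Unique-variance violations are applied on the raw variance scale; the
generator refuses (with the offending cell named) any deviation that
breaks positive definiteness.

`run_power_study()` derives one seed per cell and per replication from a
master seed, drops and counts non-converged fits (flagging cells losing
more than 5%), reuses one critical-value table per tie structure, and can
retain per-replication rejections so that functionals can be compared on
paired replications.

Problem sizes in the shipped tests: the localization study runs 500
replications per cell at $n = 480$, $m = 8$ over $d \in \{0, 2, 3, 4\}$
and the misspecification study 500 replications at $d = 4$; parameter
recovery uses 200 replications at $n = 10{,}000$; the acceptance script
uses 1000 null replications. These sizes put Monte-Carlo standard errors
near 0.01 on rejection proportions, enough to resolve the qualitative
claims being checked, and were chosen as the package's own test scale
(full-scale studies at 5000 replications run through the same engine by
raising `nrep`).

## What the synthetic fixture does and does not show

`simulate_gratitude()` emulates the *shape* of a youth gratitude survey —
five 7-point items, one factor, six ordered near-equal age groups — by
discretizing a one-factor Gaussian model. It exercises the entire
tutorial pipeline (constrained multigroup fit, LRT, all six functionals,
instability plots) offline. It is synthetic and invariant by
construction: passing tests on it demonstrate plumbing and distributional
calibration, not recovery of any published data analysis. Real Likert
data differ in ways the fixture deliberately ignores (skew, floor/ceiling
effects, unbalanced groups); an optional integration test reproduces the
published worked-example numbers when a user supplies the real data as
CSV.

## Known limitations

* Normal-theory ML only; no GLS/WLS discrepancies, no polychoric models,
  no incomplete-data likelihood.
* Factor means are fixed at zero; latent-mean invariance is out of scope.
* The `maxLMo` p-value resolution is $1/\mathrm{nrep}$; at the default
  50,000 replications this is $2 \times 10^{-5}$.
* With the fixed all-ones DGP values, the misspecification artifact loads
  partly on the factor covariance (through the absorbed cross-covariance
  $\lambda_{11}\phi_{12}$), so its rejection rate sits mildly above the
  nominal level rather than at it; the qualitative localization pattern
  (loading and unique variance strongly affected, intercept not) is
  unchanged.
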