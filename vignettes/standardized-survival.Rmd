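---
title: "Standardized survival for multilevel models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized survival for multilevel models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsurvstd)
```

## The model

`mlsurvstd` works with three-level survival data — subjects
(i = 1..I_jk) nested in surgeons (j = 1..J_k) nested in centers
(k = 1..K) — under a parametric proportional-hazards model with a
Weibull baseline and Gaussian random intercepts at both cluster levels:

$$h_{ijk}(t) = p\,\lambda\,t^{p-1}
  \exp(X_{ijk}\beta + \alpha_{jk} + \gamma_k),\qquad
  \alpha_{jk}\sim N(0,\sigma^2_\alpha),\ \ \gamma_k\sim N(0,\sigma^2_\gamma).$$

The baseline cumulative hazard is $\lambda t^{p}$, so the fully
conditional survival is $S_0(t)^{\exp(X\beta+\alpha+\gamma)}$ with
$S_0(t)=\exp(-\lambda t^p)$. Nesting is structural: a surgeon belongs to
exactly one center, the two effects are independent, and crossed designs
are rejected at validation. Assumptions carried throughout:
proportional hazards, a correctly specified Weibull baseline,
non-informative censoring, Gaussian random effects, and no
subject–cluster interactions.

## Estimation

The marginal likelihood integrates the random effects out. Conditional
on the effects, a surgeon's subjects contribute
$A_j + D_j(\alpha+\gamma) - e^{\alpha+\gamma}H_j$, where $D_j$ is the
surgeon's event count, $H_j=\sum_i \lambda t_i^p e^{X_i\beta}$, and
$A_j$ collects terms free of the effects. The likelihood therefore
depends on the data only through per-surgeon scalars, and both
integrals stay one-dimensional:

* **inner (surgeon)**: adaptive Gauss–Hermite quadrature recentered at
  the conditional mode of $\alpha$ given $\gamma$ (found by a damped
  Newton iteration on a concave scalar equation) and rescaled by the
  mode curvature;
* **outer (center)**: the same construction on the profile integrand in
  $\gamma$, with log-sum-exp accumulation throughout.

Optimization (BFGS) runs on the transformed scale
$(\log p, \log\lambda, \beta, \log\sigma^2_\alpha, \log\sigma^2_\gamma)$;
the covariance matrix is the inverse of a central-finite-difference
Hessian (step $\max(10^{-4}, 10^{-4}|x_i|)$) on that scale, which is
also the scale used for Monte-Carlo parameter draws so positive
parameters stay positive. A zero variance (fixed via `fix_var`)
collapses the corresponding integral to a point mass rather than
dividing by zero. Starting values come from a single-level Weibull fit;
variances start at 0.05.

Numerical choices that matter:

* **Nodes.** 15 per dimension by default for fitting (the value is
  configurable; on test problems the log-likelihood is stable to at
  least 8 digits between 15 and 35 nodes), 25 for posterior summaries,
  30 for the non-adaptive prior integrals of marginal standardization —
  non-adaptive there because the integral is a prior (exactly Gaussian)
  expectation, not a posterior one.
* **Convergence reporting.** A failed optimizer or a singular /
  indefinite Hessian flags the fit as unconverged; posterior and CI
  machinery refuse to run on such fits. Variance estimates collapsing
  to the boundary ($\hat\sigma^2\to 0$) are the common cause with few
  clusters; the practical remedy is refitting with that variance fixed
  at 0.
* **Degenerate inputs.** Events at time 0 are rejected (the hazard is
  undefined at the origin for $p<1$); censored records at time 0 are
  dropped with a warning; missing covariates are rejected because
  standardization needs a complete case-mix matrix.

## Empirical-Bayes prediction

Cluster performance is summarized by the posterior of each random
intercept with the model parameters fixed at their estimates. The
default is the posterior **mean** (it minimizes posterior mean-squared
prediction error), with the posterior SD as its uncertainty; posterior
**modes** (with curvature-based SDs from the arrowhead precision matrix
of the joint mode) are available as a cheaper alternative and agree
with means on large clusters. For a center with $J_k$ surgeons the
joint posterior is $(J_k{+}1)$-dimensional, but surgeons are
conditionally independent given the center effect, so every moment
reduces to nested 1-D quadratures — no multidimensional grids.

Two structural facts worth knowing:

* predictions are *shrunken* toward 0, more strongly for clusters with
  less data; a cluster with no data has posterior equal to the prior;
* with a single surgeon per center only the *sum* $\alpha+\gamma$ is
  well identified; the individual posteriors then remain wide no matter
  how many subjects the cluster has, floored at the prior partition of
  the total. Rankings within a level are unaffected.

Ties in best/worst selection break lexicographically by cluster id.

## Standardization and contrasts

All comparisons standardize over one common case-mix (default: all n
subjects; any subset can be supplied, with the output recording the
fraction of the population drawn from other clusters as an
extrapolation guard — no automatic trimming). Three estimators:

* **fixed/fixed**: plug in the EB predictions of a surgeon and its
  center (or 0 for the theoretical average cluster) and average the
  conditional survivals row-wise;
* **marginal**: fix one level's EB prediction and integrate the other
  level over its *estimated prior* $N(0,\hat\sigma^2)$ — not over the
  empirical set of EB predictions, which is shrunken and would
  understate the spread; this is a deliberate reading of the estimators
  where either convention is defensible;
* **contrast**: pointwise difference of two curves; the time grids and
  population hashes must match exactly or the contrast refuses.

The default time grid is 100 equally spaced points from 0 to the 99th
percentile of observed follow-up. A useful sanity property: the
marginal exceeds the plug-in-at-zero curve when the per-subject
cumulative hazards exceed 1 (convex regime of
$u\mapsto\exp(-He^u)$) and drops below it when they are all under 1 —
so the two curves cross, and neither dominates globally.

Rankings categorize clusters against a reference (typically the
theoretical average): medium if the cluster's CI covers the reference,
low risk if entirely above, high risk if entirely below; without CIs,
clusters are uncategorized unless a tercile split is explicitly
requested. The policy is recorded in the output.

## Monte-Carlo uncertainty

For any estimand $\psi$ the machinery draws B parameter vectors from
the transformed-scale asymptotic normal, draws cluster effects
independently from $N(\text{EB mean}, \text{posterior SD}^2)$,
re-evaluates $\psi$ per draw, and reports the empirical SE (1/B
denominator) with percentile (default, B = 1000) or normal intervals.
The point estimate is always the plug-in value, never the draw mean.
Effects fixed at zero (theoretical-average estimands) take no draw —
the posterior-draw step is vacuous for them. Non-finite draws are
excluded with a warning; more than 5% is an error.

One caveat: when a variance component sits at the boundary, its
log-scale sampling SD is effectively unbounded and drawn variances can
be enormous, which inflates intervals of marginal estimands absurdly.
Treat boundary fits as two-level models (fix the collapsed variance at
0) before requesting intervals.

## The synthetic-data generator

`simulate_survdata()` draws effects and covariates per the model above
and inverts the conditional survival for event times,
$T^\ast = (-\log U/(\lambda e^{\eta}))^{1/p}$, with censoring
$C=\min(\tau, \text{Exp(rate)})$ — independent of the event process by
construction. Randomness is split into three phases (center effects,
surgeon effects, subject-level draws) with phase seeds derived from the
base seed by an injective affine map modulo $2^{31}-1$; this keeps the
drawn effects invariant to cluster-size changes and makes replicates
with consecutive base seeds independent.

`paperlike_config()` emulates the structure of the bladder-cancer
application the methodology was illustrated on: 21 centers, 3 surgeons
per center, 40 patients per surgeon (n = 2520 — cluster sizes of this
order are needed for variance components as small as the application's,
0.018 and 0.019, to be identified rather than collapse to the
boundary), covariates age ~ N(65, 10), sex ~ Bern(0.25),
chemo ~ Bern(0.5) with log-hazard ratios (0.02, 0.10, −0.30), Weibull
shape 1.1 with the scale calibrated so 10-year survival at the mean
profile is about 0.07, an administrative horizon of 15 time units and
exponential censoring at rate 0.02. It emulates the published
application's *structure*; it is not a replication of any real dataset,
and passing tests on it demonstrate internal consistency of the
machinery, not agreement with clinical data — real cohorts have
non-Weibull baselines, informative censoring, covariate–cluster
dependence and missingness that the generator deliberately omits.

## Problem sizes used in the checks

The package's simulation-based checks use: a 50-replicate parameter
recovery study at K = 40 centers × 4 surgeons × 25 patients
(β = (0.5, −0.3), p = 1.2, σ²_α = 0.05, σ²_γ = 0.10); and a
200-replicate interval-calibration study at K = 10 × 3 × 15 (n = 450)
with B = 500 percentile draws per replicate, targeting the 10-year
standardized survival of the theoretical average cluster, whose truth
is computable from the generator. The calibration cohort size was
chosen as the smallest at which the variance components are usually
(not always) identified, which also exercises the boundary-collapse
path above.

Simulation evidence from these checks: baseline and covariate
parameters are recovered without detectable bias, while the
center-level variance shows the well-known small-K maximum-likelihood
downward bias (about −0.01 on a true 0.10 at K = 40 centers); there is
no REML-style correction in this model class, so analysts comparing
variance components across studies should keep the cluster count in
mind.

## Known limitations

Left truncation, interval censoring, time-varying covariates and
effects, crossed random effects, competing risks, AFT metrics,
doubly-robust weighting, Bayesian estimation and the hierarchical
bootstrap are out of scope. The t-distributed posterior alternative for
effect draws is a documented hook, not implemented. Contrasts inherit
the proportional-hazards assumption; all causal readings require the
measured case-mix to close the relevant back-door paths.
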