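---
title: "Bayesian geographically weighted regression: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian geographically weighted regression: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Geographically weighted regression (GWR) addresses spatial non-stationarity:
the association between covariates and an outcome changes across space. With
observations $Y_{i,1:m_i}$ at sampling locations $i = 0, \dots, n$ with
coordinates $(u_i, v_i)$, a GLM
$\mathbb{E}(Y_i \mid X_i) = g^{-1}(X_i \varphi(u_i, v_i))$ is assumed, where
the coefficient surface $\varphi(u, v)$ is smooth in space. Some families
carry an additional nuisance parameter $\theta_i$ — the negative binomial
dispersion, or the Gaussian standard deviation — which we take to be locally
unique and *not* spatially smooth (think of per-site measurement equipment).

When a single location has too few observations for a stable fit, GWR
borrows data from neighbours through a distance kernel. The classical
locally-weighted likelihood raises each neighbouring location's likelihood
to a kernel weight $W(d_i, \eta) \in [0, 1]$; because a power of a density
is no longer a density, a standard Bayesian treatment does not directly
apply. `bgwr` implements the modularized-Bayesian resolution: the weighted
likelihood defines a *geographically-powered posterior*, a Gibbs-posterior-
style target in which each neighbouring module's feedback onto the shared
coefficients is tempered by its kernel weight, using an auxiliary copy
$\tilde\theta_i$ of each neighbour's nuisance parameter:

$$
p_{\mathrm{pow},\eta}(\theta_0, \tilde\theta_{1:n}, \varphi \mid Y)
\;\propto\;
\pi(\theta_0, \tilde\theta_{1:n}, \varphi)\;
p(Y_{0,1:m}\mid\theta_0,\varphi)
\prod_{i=1}^{n} p(Y_{i,1:m}\mid\tilde\theta_i,\varphi)^{W(d_i,\eta)} .
$$

The marginal in $(\theta_0, \varphi)$ of this single target is the object of
inference for the centre location; the unweighted per-location conditionals
of the original $\theta_i$ never need to be materialized, which is why the
sampler only ever works with the powered factor. Two limits anchor the
interpretation: as $\eta \to 0$ all non-centre weights vanish and the target
reduces to the *cut* distribution (the centre's own data only); as
$\eta \to \infty$ all weights tend to 1 and it becomes the standard pooled
posterior. The bandwidth interpolates between them, trading the variance
reduction of borrowed data against the bias of partial misspecification. In
the large-$m$ limit the posterior concentrates on the minimizer of a
kernel-weighted combination of Kullback–Leibler divergences; in the Gaussian
known-variance case that minimizer is the closed form
$\varphi^* = \sum_i W_i \mu_i / \sum_i W_i$, which the test suite uses as an
oracle.

## Families, kernels, priors

**Families.** Negative binomial with log link and additive offset
(log-exposure), parameterized so that $\mathrm{Var}(Y) = \mu + \theta\mu^2$
with $\mu = \exp(\mathrm{offset} + x\varphi)$ — note $\theta$ is the
*reciprocal* of the conventional "size" parameter, a classic source of
dispersion-convention bugs, and is documented as such on every function.
Gaussian with identity link and $\theta$ the standard deviation. The family
interface (log-density, moments, linear predictor) is the extension point
for further families with a nuisance parameter, such as beta regression.

**Kernels.** Gaussian $W(d,\eta) = \exp(-d^2/\eta^2)$ and its truncated
variant, which is exactly zero wherever $\exp(-d^2/\eta^2) \le W^*$ (strict
inequality keeps a weight). Truncation bounds the per-iteration likelihood
cost at $\mathcal{O}(m \times n(W^*))$, where $n(W^*)$ is the number of
locations with positive weight. The package reports a truncation diagnostic
— the percentage change of the *log* powered posterior between the full and
truncated kernels across supplied posterior draws. The percentage is taken
on the log-density: the quantity whose change the diagnostic is meant to
bound is the sampler's target, and the log scale is the one on which that
target is computed and compared. The diagnostic is exactly zero at
$W^* = 0$ and non-decreasing in $W^*$. Distances are Euclidean (planar
coordinates) or haversine great-circle (longitude/latitude in decimal
degrees, mean Earth radius 6371 km by default); distances and bandwidths
must share units and the package never converts units.

**Priors.** The sources leave prior forms unspecified, so the package
defaults are weakly informative and strictly proper — propriety is what
guarantees the powered posterior has a finite normalizer:
$\varphi_k \sim N(0, 10^2)$ iid and
$\theta, \tilde\theta_i \sim \mathrm{LogNormal}(0, 1)$. All hyperparameters
are configurable through `prior_spec()`.

## Sampling

Any standard MCMC scheme can target the powered posterior; `bgwr` uses
random-walk Metropolis with two block types, implemented in C++:

* a **joint multivariate normal proposal on $\varphi$**, whose covariance is
  adapted during burn-in to $2.38^2/p$ times the empirical chain covariance,
  with a Robbins–Monro-tuned global scale targeting 0.234 acceptance;
* **componentwise log-scale random walks** for $\theta_0$ and each
  $\tilde\theta_i$, each adapted toward 0.44 acceptance. The prior is placed
  directly on $\log\theta$ (normal), which is the lognormal prior on
  $\theta$ with the Jacobian absorbed, so proposals are unconstrained.

Adaptation happens only during burn-in; the kernel is frozen afterwards, so
retained draws come from a fixed Markov kernel. Because the
$\tilde\theta_i$ factors are conditionally independent given $\varphi$, all
scalar updates in one sweep touch only their own location's (cached)
likelihood terms; the negative binomial log-likelihood is decomposed so the
$\varphi$-block ratio skips all log-gamma terms (they cancel) and the
$\theta$-updates reuse cached linear predictors. These two cache layers are
what makes bandwidth cross-validation on a laptop-scale lattice feasible.

**Initialization.** Chains start at a kernel-weighted quasi-Poisson (NB) or
weighted least-squares (Gaussian) estimate of $\varphi$, with per-location
moment estimates of $\theta$. A fixed starting point such as $\varphi = 0$
is supported (`init = "zero"`) but not the default: the adapted random walk
moves through parameter space at a rate set by the posterior scale, and
with the chain lengths used in practice (thousands of iterations) a start
several posterior standard deviations away would dominate the burn-in
budget. The weighted-GLM start is deterministic given the data, so seed
reproducibility is unaffected.

**Reproducibility.** Each (location, chain) pair derives its own RNG
sub-seed from the master seed and a hash of the location id string —
a counter-based scheme, so results are bitwise reproducible and independent
of execution order or parallel scheduling, and permuting the location list
permutes but does not change per-location results.

## Bandwidth selection

For each location of interest the model's predictive quality is the
expected log pointwise predictive density (elpd) of new observations at
that location; the optimal shared bandwidth maximizes the mean elpd across
locations. The package estimates elpd by held-out cross-validation: at each
interest location a random half of the observations (configurable) is held
out; the model centred there is fitted on everything else (the held-out
rows are removed *only* at the interest location); and

$$
\widehat{\mathrm{elpd}} = \frac{1}{m - m'} \sum_{j = m'+1}^{m}
\log\Big( \tfrac{1}{S}\sum_{s=1}^{S} p(Y_{i,j} \mid \theta^{(s)},
\varphi^{(s)}) \Big),
$$

with the inner average computed by log-sum-exp (equal to the naive average
wherever that does not underflow, finite where it does). Held-out subsets
are drawn once per fold and shared across candidates, so candidates are
compared on identical splits. Fold means are averaged per candidate — the
aggregation the general $Q$-fold scheme leaves open — and the argmax is
selected, with ties broken toward the smallest candidate (the more local,
hence more conservative, model). Per-chain elpd estimates are recorded
alongside the pooled ones to expose the across-chain spread.

`eval_location_ids` restricts the mean to a subset of locations for
scaled-down studies. This deviates from the all-locations mean that defines
the selection rule, and the output flags whenever it is used.

## The synthetic study

`simulate_lattice()` generates the package's reference study: a regular
integer lattice (default $40 \times 40$, $m = 100$) with

$$
\varphi_0 = 3,\qquad
\varphi_1(u,v) = 0.1 + 0.01\sqrt{u^2 + v^2},\qquad
\varphi_2(u) = 0.05\big(\sin(\tfrac{\pi}{2} + \tfrac{\pi u}{20}) +
\cos(\tfrac{\pi}{2} + \tfrac{\pi u}{20}) + 4\big),
$$

$\theta(u,v) \sim N(0.5, 0.01^2)$ iid (non-positive draws redrawn),
covariates $x_1 = 1$, $x_2 \sim U(0,10)$, $x_3 \sim U(2,7)$ drawn
independently per observation, and negative binomial outcomes with
$\mu = \exp(\varphi_0 + \varphi_1 x_2 + \varphi_2 x_3)$. The radial form of
$\varphi_1$ is the only defensible reading of the surface definition: the
alternative reading $0.1 + 0.01u^2 + v^2$ reaches $\approx 1600$, which is
impossible inside $\exp(X\varphi)$. The generator emulates spatially smooth
coefficient surfaces with a non-smooth local dispersion; it does not
emulate features of real surveillance data such as temporal autocorrelation,
reporting artefacts, or covariate measurement error, so passing tests
demonstrate correct recovery under the stated generating process, not
robustness to those features.

At reduced scale — a $15 \times 15$ lattice with $m = 50$, candidates
$\{10^{-4}, 2, 4, 10, 1000\}$, 50% holdout, 2 chains of 2000 iterations
(500 burn-in), elpd averaged over a random subset of 40 interest locations,
repeated over three seeds — the cross-validation selects the interior
candidate $\eta = 4$, and the mean squared error of the posterior-mean
varying coefficients against the true surfaces is smaller at the selected
bandwidth than at either extreme candidate. These problem sizes are the
package's acceptance workload (`scripts/acceptance.R` and the acceptance
test file) and were chosen so the whole suite runs in minutes on one core
while leaving the selection signal clearly above Monte Carlo noise.

## Numerical and design notes

* The powered posterior is represented only through its unnormalized
  log-density; normalization is never computed. A plain-R reference
  evaluation and the C++ sampler target are cross-checked to $10^{-10}$ in
  the tests.
* The prior term covers every auxiliary copy the evaluated state carries,
  whether or not its location is active under the current kernel. Kernels
  then differ only through the weighted likelihood terms, which is what the
  truncation diagnostic should measure; zero-weight likelihood factors
  contribute nothing and their auxiliary copies are simply not sampled.
* Quantiles everywhere are empirical with linear interpolation between
  order statistics (R type 7), declared once so summaries are bit-stable.
* Split-$\widehat{R}$ follows the halved-chain formula; identical constant
  chains report $\widehat{R} = 1$ by convention. Effective sample size uses
  chain-averaged autocorrelations with Geyer's initial-positive-sequence
  truncation.
* Degenerate inputs: a location with a single observation is valid (m >= 1);
  an infeasible holdout errors naming the location; an elpd of $-\infty$
  (every draw assigns zero density to a test point) warns rather than
  aborts; a non-finite log-target at the chain start raises an
  initialization error.
* Known limitations: one global bandwidth (no spatially-varying or
  parameter-specific bandwidths); no temporal weighting; nuisance-parameter
  inference at the centre rests on that location's own observations only
  and is therefore weak at very small $m$; cross-validated selection
  refits every location for every candidate and fold, which is the
  dominant cost.

## A worked example

```{r, eval = FALSE}
library(bgwr)

sim <- simulate_lattice(grid_u = 10, grid_v = 10, m = 30, seed = 1)
cv <- cv_config(candidates = c(0.0001, 2, 4, 1000), holdout_fraction = 0.5,
                seed = 1,
                mcmc = mcmc_config(n_chains = 2, n_iterations = 1500,
                                   burn_in = 500, seed = 1))
spec <- kernel_spec("truncated_gaussian", bandwidth = 1, threshold = 0.01)
tab <- run_bandwidth_cv(sim$dataset, spec, cv = cv)
sel <- select_bandwidth(tab)

fits <- fit_all_locations(sim$dataset,
                          kernel_spec("truncated_gaussian",
                                      bandwidth = sel$selected,
                                      threshold = 0.01),
                          cfg = mcmc_config(n_chains = 2,
                                            n_iterations = 2000,
                                            burn_in = 500, seed = 1))
summarize_chains(fits[["L5_5"]])
```
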