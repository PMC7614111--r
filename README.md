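# bgwr — Bayesian geographically weighted regression

`bgwr` fits generalized geographically weighted regression (GWR) models in
a modularized (cutting-feedback) Bayesian framework. It is aimed at spatial
epidemiologists and biostatisticians who need per-location regression
coefficients that vary smoothly over space — e.g. the association between
influenza positivity and climate across countries — together with honest
posterior uncertainty, from count data with overdispersion and varying
exposure.

## The model

For observations $Y_{i,1:m}$ at locations $i = 0,\dots,n$, a GLM
$\mathbb{E}(Y_i \mid X_i) = g^{-1}(X_i\varphi(u_i, v_i))$ with a smooth
coefficient surface $\varphi$ and a locally unique (non-smooth) nuisance
parameter $\theta_i$. Supported families: negative binomial with log link,
offset and $\mathrm{Var} = \mu + \theta\mu^2$, and Gaussian with identity
link and $\theta$ the standard deviation. For a centre location, inference
targets the *geographically-powered posterior*

$$
p_{\mathrm{pow},\eta}(\theta_0, \tilde\theta_{1:n}, \varphi \mid Y)
\propto \pi(\theta_0, \tilde\theta_{1:n}, \varphi)\,
p(Y_{0,1:m}\mid\theta_0,\varphi)
\prod_{i=1}^{n} p(Y_{i,1:m}\mid\tilde\theta_i,\varphi)^{W(d_i,\eta)},
$$

with Gaussian kernel $W(d, \eta) = \exp(-d^2/\eta^2)$ (optionally truncated
below a threshold $W^*$ to bound computation) and an auxiliary copy
$\tilde\theta_i$ of each neighbour's nuisance parameter. Small bandwidths
cut all feedback from neighbours (fully local fit); large bandwidths
recover the pooled standard posterior. The bandwidth is selected by
maximizing the mean (across locations) expected log pointwise predictive
density (elpd), estimated by held-out cross-validation. Sampling is
adaptive random-walk Metropolis with a compiled (Rcpp) core; one
independent model per location, deterministic per-(location, chain)
sub-seeds.

See the methods vignette (`vignettes/bayesian-gwr-methods.Rmd`) for the
full account: priors, proposal adaptation, truncation diagnostic, the
synthetic study, and design decisions.

## A worked example

Simulate a small lattice with smooth coefficient surfaces, select the
bandwidth by cross-validated elpd, and fit one location:

```r
library(bgwr)

sim <- simulate_lattice(grid_u = 15, grid_v = 15, m = 50, seed = 1)
set.seed(500001)
cv <- cv_config(candidates = c(0.0001, 2, 4, 10, 1000),
                holdout_fraction = 0.5,
                eval_location_ids = sample(sim$dataset$locations$id, 40),
                seed = 1,
                mcmc = mcmc_config(n_chains = 2, n_iterations = 2000,
                                   burn_in = 500, seed = 1))
tab <- run_bandwidth_cv(sim$dataset,
                        kernel_spec("truncated_gaussian", bandwidth = 1,
                                    threshold = 0.01),
                        cv = cv)
tab$mean_curve
#>     eta      elpd
#>   1e-04 -5.943597
#>   2e+00 -5.881143
#>   4e+00 -5.876682
#>   1e+01 -5.888989
#>   1e+03 -5.904391
select_bandwidth(tab)$selected
#> [1] 4
```

The mean elpd curve is highest at the interior bandwidth 4 — enough
borrowing from neighbours to stabilize each local fit, not so much that
spatially distant (differently behaved) locations bias it. The extreme
candidates correspond to the cut (1e-04, local-only) and pooled (1000)
limits and both predict worse. Refit at the selected bandwidth and
summarize:

```r
fits <- fit_all_locations(sim$dataset,
                          kernel_spec("truncated_gaussian", bandwidth = 4,
                                      threshold = 0.01),
                          cfg = mcmc_config(n_chains = 2,
                                            n_iterations = 2000,
                                            burn_in = 500, seed = 1),
                          center_ids = "L8_8")
summarize_chains(fits[["L8_8"]])
#>  parameter      mean    median      q2.5     q97.5     rhat      ess
#>      theta 0.4827292 0.4737153 0.3351124 0.6831704 1.002433 577.3205
#>         x1 2.9857793 2.9832621 2.8832085 3.1014488 1.015487 163.8883
#>         x2 0.2216910 0.2220465 0.2112048 0.2310099 1.016722 229.2665
#>         x3 0.1741707 0.1742540 0.1545479 0.1938157 1.009075 187.0107
```

The true values at this location are $\varphi = (3, 0.213, 0.168)$ and
$\theta = 0.514$: each 95% credible interval covers its target, with
`x2`/`x3` slightly smoothed toward neighbouring surface values, as a
kernel-weighted fit is designed to do.

A thin command-line interface over the same functions is installed at
`inst/cli/bgwr` (subcommands `simulate`, `select-bandwidth`, `fit`, `run`,
`summarize`).

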