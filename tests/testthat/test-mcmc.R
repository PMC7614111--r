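test_that("known-theta Gaussian sampling matches the weighted-precision posterior", {
  ds <- make_gaussian_toy(means = c(0, 2, 4), sd = 1, m = 20, seed = 42)
  W <- c(g1 = 1, g2 = 0.5, g3 = 0.1)
  prob <- powered_posterior_problem(ds, "g1", weight_vector("g1", W))
  cfg <- mcmc_config(n_chains = 4, n_iterations = 2500, burn_in = 800, seed = 7)
  res <- sample_powered_posterior(prob, cfg, init = list(phi = 0, theta = 1),
                                  fix_theta = TRUE)
  x <- pooled_draws(res)[, "x1"]
  oracle <- conjugate_phi_posterior(ds, W, sigma = 1)
  ess <- res$diagnostics$ess[res$diagnostics$parameter == "x1"]
  mcse <- oracle$sd / sqrt(ess)
  expect_lt(abs(mean(x) - oracle$mean), 3 * mcse)
  expect_equal(sd(x), oracle$sd, tolerance = 0.1)
})

test_that("identical seeds give bitwise-identical chains", {
  ds <- make_gaussian_toy(m = 5)
  prob <- powered_posterior_problem(ds, "g2",
                                    weight_vector("g2", c(g1 = 0.3, g2 = 1, g3 = 0.3)))
  cfg <- mcmc_config(n_chains = 2, n_iterations = 400, burn_in = 100, seed = 12)
  r1 <- sample_powered_posterior(prob, cfg)
  r2 <- sample_powered_posterior(prob, cfg)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$lp, r2$lp)
})

test_that("cut-limit draws match an independent sampler of the single-location posterior", {
  # all non-centre weights zero; known theta, so the exact posterior is the
  # conjugate normal -- draw iid from it as the independent reference
  ds <- make_gaussian_toy(means = 2, sd = 1, m = 15, seed = 21)
  prob <- powered_posterior_problem(ds, "g1", weight_vector("g1", c(g1 = 1)))
  cfg <- mcmc_config(n_chains = 2, n_iterations = 3000, burn_in = 1000, seed = 31)
  res <- sample_powered_posterior(prob, cfg, init = list(phi = 0, theta = 1),
                                  fix_theta = TRUE)
  x <- pooled_draws(res)[, "x1"]
  oracle <- conjugate_phi_posterior(ds, c(g1 = 1), sigma = 1)
  set.seed(77)  # pre-registered
  ref <- rnorm(2000, oracle$mean, oracle$sd)
  # thin the correlated chain to roughly independent draws for the KS test
  idx <- seq(1, length(x), by = 10)
  expect_gt(suppressWarnings(ks.test(x[idx], ref))$p.value, 0.01)
})

test_that("the theta-positivity and lp trace invariants hold on an NB fit", {
  sim <- simulate_lattice(grid_u = 3, grid_v = 3, m = 10, seed = 3)
  ds <- sim$dataset
  spec <- kernel_spec("gaussian", bandwidth = 1.5)
  prob <- powered_posterior_problem(ds, "L2_2",
                                    compute_weight_vector(ds, "L2_2", spec))
  cfg <- mcmc_config(n_chains = 2, n_iterations = 600, burn_in = 200, seed = 5)
  res <- sample_powered_posterior(prob, cfg, keep_aux = TRUE)
  pooled <- pooled_draws(res)
  expect_equal(nrow(pooled), 2 * 400)
  expect_true(all(pooled[, "theta"] > 0))
  expect_true(all(unlist(res$aux) > 0))
  # the incrementally tracked log-target matches a fresh evaluation
  last <- res$draws[[1]][400, ]
  aux_last <- res$aux[[1]][400, ]
  st <- parameter_state(last[["theta"]], last[c("x1", "x2", "x3")],
                        setNames(aux_last, colnames(res$aux[[1]])))
  expect_equal(res$lp[[1]][400], log_powered_posterior(st, prob),
               tolerance = 1e-8)
})

test_that("adapted acceptance rates sit near their targets on a lattice fixture", {
  sim <- simulate_lattice(grid_u = 5, grid_v = 5, m = 20, seed = 4)
  ds <- sim$dataset
  spec <- kernel_spec("truncated_gaussian", bandwidth = 2, threshold = 0.01)
  prob <- powered_posterior_problem(ds, "L3_3",
                                    compute_weight_vector(ds, "L3_3", spec))
  cfg <- mcmc_config(n_chains = 2, n_iterations = 2000, burn_in = 800, seed = 9)
  res <- sample_powered_posterior(prob, cfg)
  expect_lt(max(abs(res$acceptance$phi - cfg$target_accept_block)), 0.15)
  expect_lt(max(abs(res$acceptance$theta - cfg$target_accept_scalar)), 0.15)
})

test_that("a non-finite initial state raises an initialization error", {
  ds <- make_gaussian_toy(m = 5)
  prob <- powered_posterior_problem(ds, "g1", weight_vector("g1", c(g1 = 1)))
  cfg <- mcmc_config(n_chains = 1, n_iterations = 100, burn_in = 10, seed = 1)
  expect_error(
    suppressWarnings(sample_powered_posterior(prob, cfg,
                                              init = list(phi = 1e308, theta = 1))),
    "initialization error")
})

test_that("summarize_chains: exact summaries, constant-chain Rhat convention", {
  res <- structure(list(
    center_id = "a",
    draws = list(matrix(c(1, 1, 1, 1, 2, 3), 3, 2,
                        dimnames = list(NULL, c("theta", "x1"))),
                 matrix(c(1, 1, 1, 1, 2, 3), 3, 2,
                        dimnames = list(NULL, c("theta", "x1"))))),
    class = "chain_result")
  res$diagnostics <- bgwr:::chain_diagnostics(res)
  s <- summarize_chains(res)
  expect_equal(s$mean[s$parameter == "x1"], 2)
  expect_equal(s$median[s$parameter == "x1"], 2)
  expect_equal(s$rhat[s$parameter == "theta"], 1)  # identical constant chains
})

test_that("split-Rhat matches the brute-force formula on listed draws", {
  c1 <- c(1.0, 1.2, 0.8, 1.1, 0.9, 1.3, 0.7, 1.0)
  c2 <- c(2.0, 2.2, 1.8, 2.1, 1.9, 2.3, 1.7, 2.0)
  halves <- list(c1[1:4], c1[5:8], c2[1:4], c2[5:8])
  n <- 4
  W <- mean(sapply(halves, var))
  B <- n * var(sapply(halves, mean))
  oracle <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(bgwr:::split_rhat(list(c1, c2)), oracle)
  expect_gt(oracle, 1.5)  # shifted chains are flagged
  expect_lt(bgwr:::split_rhat(list(c1, c1 + 0.01)), oracle)
})

test_that("a single chain warns and omits Rhat", {
  ds <- make_gaussian_toy(m = 5)
  prob <- powered_posterior_problem(ds, "g1", weight_vector("g1", c(g1 = 1)))
  cfg <- mcmc_config(n_chains = 1, n_iterations = 200, burn_in = 50, seed = 2)
  expect_warning(res <- sample_powered_posterior(prob, cfg), "2 chains")
  expect_true(all(is.na(res$diagnostics$rhat)))
})

test_that("per-location fits are independent of list order; one location equals empty weights", {
  ds <- make_gaussian_toy(means = c(0, 1, 2), m = 8, seed = 13)
  spec <- kernel_spec("gaussian", bandwidth = 2)
  cfg <- mcmc_config(n_chains = 2, n_iterations = 300, burn_in = 100, seed = 3)
  f1 <- fit_all_locations(ds, spec, cfg = cfg)
  f2 <- fit_all_locations(ds, spec, cfg = cfg,
                          center_ids = c("g3", "g1", "g2"))
  for (id in names(f1)) expect_identical(f1[[id]]$draws, f2[[id]]$draws)

  one <- simulate_gaussian_toy(means = 5, sd = 1, m = 10, seed = 14)
  fo <- fit_all_locations(one, spec, cfg = cfg)
  prob <- powered_posterior_problem(one, "g1", weight_vector("g1", c(g1 = 1)))
  direct <- sample_powered_posterior(prob, cfg)
  expect_identical(fo$g1$draws, direct$draws)
})

test_that("with all weights one every location recovers the pooled standard posterior", {
  means <- rep(1.5, 4)
  ds <- simulate_gaussian_toy(means = means, sd = 1, m = 12,
                              coords = cbind(c(1, 1, 2, 2), c(1, 2, 1, 2)),
                              seed = 15)
  spec <- kernel_spec("gaussian", bandwidth = 1e6)  # all weights ~ 1
  cfg <- mcmc_config(n_chains = 2, n_iterations = 2000, burn_in = 600, seed = 6)
  fits <- fit_all_locations(ds, spec, cfg = cfg,
                            init = list(phi = 0, theta = 1), fix_theta = TRUE)
  oracle <- conjugate_phi_posterior(ds, setNames(rep(1, 4), paste0("g", 1:4)),
                                    sigma = 1)
  for (id in names(fits)) {
    x <- pooled_draws(fits[[id]])[, "x1"]
    ess <- fits[[id]]$diagnostics$ess[fits[[id]]$diagnostics$parameter == "x1"]
    expect_lt(abs(mean(x) - oracle$mean), 3 * oracle$sd / sqrt(ess))
    expect_equal(sd(x), oracle$sd, tolerance = 0.15)
  }
})
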