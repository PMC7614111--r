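test_that("with all non-centre weights zero the powered posterior is the cut component", {
  ds <- make_gaussian_toy()
  wv <- weight_vector("g1", c(g1 = 1, g2 = 0, g3 = 0))
  prob <- powered_posterior_problem(ds, "g1", wv)
  set.seed(5)
  for (i in 1:10) {
    st <- random_state(character(0))
    expect_equal(log_powered_posterior(st, prob),
                 log_single_location_posterior(st$theta_center, st$phi, "g1", ds))
  }
})

test_that("hand-evaluated two-location Gaussian powered posterior", {
  df <- data.frame(location_id = c("c", "o"), u = c(0, 1), v = 0,
                   y = c(1, 3), x1 = 1)
  ds <- spatial_dataset(df, covariates = "x1", family = "gaussian")
  wv <- weight_vector("c", c(c = 1, o = 0.5))
  pr <- prior_spec(phi_sd = 10)
  prob <- powered_posterior_problem(ds, "c", wv, glm_family("gaussian"), pr)
  st <- parameter_state(1, phi = 0, theta_aux = c(o = 1))
  # prior(phi = 0) + N(1; 0, 1) + 0.5 * N(3; 0, 1), minus the theta priors
  lp_theta <- 2 * dlnorm(1, 0, 1, log = TRUE)
  expect_equal(log_powered_posterior(st, prob) - lp_theta,
               -3.2215236 + -1.4189385 + 0.5 * -5.4189385, tolerance = 1e-6)
  # pure function: bitwise identical on repeated evaluation
  expect_identical(log_powered_posterior(st, prob),
                   log_powered_posterior(st, prob))
})

test_that("with all weights one the powered posterior is the standard joint posterior", {
  ds <- make_gaussian_toy()
  wv <- weight_vector("g1", c(g1 = 1, g2 = 1, g3 = 1))
  prob <- powered_posterior_problem(ds, "g1", wv)
  set.seed(6)
  for (i in 1:5) {
    st <- random_state(c("g2", "g3"))
    # standard posterior: prior x product of every location's full likelihood
    direct <- log_prior(st, prob$prior) +
      sum(gaussian_log_density(ds$data$y[1:20], 1, st$phi, st$theta_center)) +
      sum(gaussian_log_density(ds$data$y[21:40], 1, st$phi, st$theta_aux["g2"])) +
      sum(gaussian_log_density(ds$data$y[41:60], 1, st$phi, st$theta_aux["g3"]))
    expect_equal(log_powered_posterior(st, prob), direct)
  }
})

test_that("compiled log-target agrees with the reference evaluation for both families", {
  set.seed(8)
  # gaussian
  ds <- make_gaussian_toy()
  wv <- weight_vector("g1", c(g1 = 1, g2 = 0.7, g3 = 0.2))
  prob <- powered_posterior_problem(ds, "g1", wv)
  pk <- bgwr:::pack_problem(prob)
  for (i in 1:5) {
    st <- random_state(c("g2", "g3"))
    lt <- log(c(st$theta_center, st$theta_aux[setdiff(pk$active, "g1")]))
    expect_equal(
      bgwr:::cpp_log_target(pk$family, pk$y, pk$X, pk$offset, pk$loc_start,
                            pk$loc_len, pk$w, prob$prior$phi_sd,
                            prob$prior$log_theta_mean, prob$prior$log_theta_sd,
                            st$phi, lt),
      log_powered_posterior(st, prob), tolerance = 1e-10)
  }
  # negative binomial with offsets
  sim <- simulate_lattice(grid_u = 3, grid_v = 3, m = 5, seed = 2)
  nb <- sim$dataset
  nb$data$offset <- rep_len(c(0, log(2)), nrow(nb$data))
  spec <- kernel_spec("gaussian", bandwidth = 2)
  wv <- compute_weight_vector(nb, "L2_2", spec)
  prob <- powered_posterior_problem(nb, "L2_2", wv)
  pk <- bgwr:::pack_problem(prob)
  for (i in 1:5) {
    st <- random_state(setdiff(pk$active, "L2_2"), p = 3)
    lt <- log(c(st$theta_center, st$theta_aux[setdiff(pk$active, "L2_2")]))
    expect_equal(
      bgwr:::cpp_log_target(pk$family, pk$y, pk$X, pk$offset, pk$loc_start,
                            pk$loc_len, pk$w, prob$prior$phi_sd,
                            prob$prior$log_theta_mean, prob$prior$log_theta_sd,
                            st$phi, lt),
      log_powered_posterior(st, prob), tolerance = 1e-10)
  }
})

test_that("single-location posterior matches the conjugate normal posterior on a grid", {
  ds <- make_gaussian_toy(means = 1.5, sd = 1, m = 30, seed = 3)
  pr <- prior_spec(phi_sd = 5)
  y <- ds$data$y
  prec <- 1 / 25 + length(y)       # known sigma = 1
  post_mean <- sum(y) / prec
  post_sd <- 1 / sqrt(prec)
  grid <- seq(post_mean - 5 * post_sd, post_mean + 5 * post_sd, length.out = 401)
  lp <- vapply(grid, function(phi)
    log_single_location_posterior(1, phi, "g1", ds, prior = pr), numeric(1))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  expect_equal(sum(w * grid), post_mean, tolerance = 1e-4)
  expect_equal(sqrt(sum(w * (grid - sum(w * grid))^2)), post_sd,
               tolerance = 1e-3)
})

test_that("increasing a location's weight pulls the posterior mean toward its data", {
  # 1-parameter Gaussian toy, known theta; grid-normalized posterior oracle
  ds <- make_gaussian_toy(means = c(0, 5), sd = 1, m = 10, seed = 9)
  grid <- seq(-2, 7, length.out = 1201)
  post_mean_at_w <- function(w2) {
    wv <- weight_vector("g1", c(g1 = 1, g2 = w2))
    prob <- powered_posterior_problem(ds, "g1", wv)
    lp <- vapply(grid, function(phi) {
      st <- parameter_state(1, phi,
                            if (w2 > 0) c(g2 = 1) else numeric(0))
      log_powered_posterior(st, prob)
    }, numeric(1))
    p <- exp(lp - max(lp)); p <- p / sum(p)
    sum(p * grid)
  }
  means <- vapply(c(0, 0.25, 0.5, 1), post_mean_at_w, numeric(1))
  expect_true(all(diff(means) > 0))  # monotone toward g2's sample mean (~5)
  ybar2 <- mean(ds$data$y[ds$data$location_id == "g2"])
  expect_lt(means[4], ybar2)
})

test_that("the large-m maximizer is the kernel-weighted mean (Gaussian closed form)", {
  means <- c(1, 3, 6); W <- c(1, 0.5, 0.2)
  ds <- make_gaussian_toy(means = means, sd = 1, m = 4000, seed = 10)
  wv <- weight_vector("g1", setNames(W, c("g1", "g2", "g3")))
  prob <- powered_posterior_problem(ds, "g1", wv,
                                    prior = prior_spec(phi_sd = 100))
  opt <- optimize(function(phi)
    log_powered_posterior(parameter_state(1, phi, c(g2 = 1, g3 = 1)), prob),
    interval = c(0, 7), maximum = TRUE)
  ybars <- tapply(ds$data$y, ds$data$location_id, mean)[c("g1", "g2", "g3")]
  expect_equal(opt$maximum, sum(W * ybars) / sum(W), tolerance = 1e-3)
  # and the empirical weighted mean is itself near the population one
  expect_equal(opt$maximum, sum(W * means) / sum(W), tolerance = 0.05)
})

test_that("truncation diagnostic is zero without truncation and monotone in the threshold", {
  sim <- simulate_lattice(grid_u = 4, grid_v = 4, m = 4, seed = 5)
  ds <- sim$dataset
  others <- setdiff(ds$locations$id, "L2_2")
  set.seed(11)
  draws <- replicate(3, random_state(others, p = 3), simplify = FALSE)
  rep0 <- truncation_relative_change(draws, ds, "L2_2", eta = 2, w_star = 0)
  expect_identical(rep0$per_draw_changes, rep(0, 3))
  expect_identical(rep0$max_abs_pct_change, 0)
  grid <- c(0.001, 0.01, 0.1, 0.5)
  maxes <- vapply(grid, function(ws)
    truncation_relative_change(draws[1], ds, "L2_2", 2, ws)$max_abs_pct_change,
    numeric(1))
  expect_true(all(diff(maxes) >= 0))
})

test_that("two-location truncation change equals the dropped weighted term", {
  df <- data.frame(location_id = c("c", "o"), u = c(0, 3), v = 0,
                   y = c(1, 3), x1 = 1)
  ds <- spatial_dataset(df, covariates = "x1", family = "gaussian")
  eta <- 1  # weight of 'o' is exp(-9), below any modest threshold
  st <- parameter_state(1, 0.4, theta_aux = c(o = 1.2))
  rep <- truncation_relative_change(list(st), ds, "c", eta, w_star = 1e-2)
  w1 <- exp(-9)
  l1 <- sum(gaussian_log_density(3, 1, 0.4, 1.2))
  full <- log_powered_posterior(
    st, powered_posterior_problem(ds, "c",
      compute_weight_vector(ds, "c", kernel_spec("gaussian", eta))))
  expect_equal(rep$per_draw_changes, 100 * abs(w1 * l1) / abs(full))
})
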