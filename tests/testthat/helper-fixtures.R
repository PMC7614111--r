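# Small programmatic fixtures shared across test files.

# a valid 2-location NB dataset with explicit intercept and one covariate
make_nb_toy <- function(m = 3) {
  df <- data.frame(
    location_id = rep(c("a", "b"), each = m),
    u = rep(c(0, 3), each = m), v = rep(c(0, 4), each = m),
    y = c(1, 0, 2, 5, 3, 4)[seq_len(2 * m) %% 6 + 1],
    x1 = 1, x2 = seq_len(2 * m) / 10)
  spatial_dataset(df, covariates = c("x1", "x2"),
                  family = "negative_binomial")
}

# Gaussian dataset with stated per-location means, intercept-only
make_gaussian_toy <- function(means = c(0, 2, 4), sd = 1, m = 20, seed = 42) {
  simulate_gaussian_toy(means = means, sd = sd, m = m, seed = seed)
}

# random parameter state covering the given aux ids
random_state <- function(aux_ids, p = 1) {
  parameter_state(theta_center = exp(rnorm(1, 0, 0.3)),
                  phi = rnorm(p, 0, 0.5),
                  theta_aux = setNames(exp(rnorm(length(aux_ids), 0, 0.3)),
                                       aux_ids))
}

# closed-form posterior of the intercept in a weighted Gaussian known-theta
# model: precision = 1/phi_sd^2 + sum_i W_i m_i / sigma^2,
# mean = (sum_i W_i sum_j y_ij / sigma^2) / precision
conjugate_phi_posterior <- function(ds, weights, sigma, phi_sd = 10) {
  ids <- names(weights)
  ssum <- tapply(ds$data$y, ds$data$location_id, sum)[ids]
  m <- table(factor(ds$data$location_id, levels = ids))
  prec <- 1 / phi_sd^2 + sum(weights * as.numeric(m)) / sigma^2
  list(mean = sum(weights * ssum) / sigma^2 / prec, sd = 1 / sqrt(prec))
}
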