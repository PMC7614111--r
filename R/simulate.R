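#' True coefficient surfaces of the lattice simulation
#'
#' The geographically varying coefficients used by [simulate_lattice()]:
#' \deqn{\phi_0 = 3,\quad
#'       \phi_1(u, v) = 0.1 + 0.01\sqrt{u^2 + v^2},\quad
#'       \phi_2(u) = 0.05(\sin(\pi/2 + \pi u/20) + \cos(\pi/2 + \pi u/20) + 4).}
#' \eqn{\phi_1} is a smooth radial gradient and \eqn{\phi_2} a smooth wave in
#' `u`; both vary slowly between lattice neighbours, which is what a
#' geographically weighted fit exploits.
#'
#' @param u,v Lattice coordinates (vectors recycle).
#' @return Data frame with columns `phi0`, `phi1`, `phi2`.
#' @export
coefficient_surfaces <- function(u, v) {
  data.frame(phi0 = rep(3, length(u)),
             phi1 = 0.1 + 0.01 * sqrt(u^2 + v^2),
             phi2 = 0.05 * (sin(pi / 2 + pi * u / 20) +
                              cos(pi / 2 + pi * u / 20) + 4))
}

#' Simulate the negative-binomial lattice study
#'
#' Generates data on a `grid_u` x `grid_v` integer lattice (coordinates
#' `1..grid_u` x `1..grid_v`, Euclidean distance in lattice units). At every
#' location, the local dispersion `theta(u, v)` is drawn independently from
#' `N(theta_mean, theta_sd^2)` (non-positive draws are redrawn): similar
#' across space but *not* spatially smooth. Each of the `m` observations per
#' location draws covariates `x1 = 1`, `x2 ~ U(x2_range)`, `x3 ~ U(x3_range)`
#' independently, and an outcome from the negative binomial with mean
#' `exp(phi0 + phi1 x2 + phi2 x3)` (coefficients from
#' [coefficient_surfaces()]) and variance `mu + theta mu^2`.
#'
#' Defaults reproduce the full-scale study conditions: a 40 x 40 lattice
#' with m = 100, `theta ~ N(0.5, 0.01^2)`, `x2 ~ U(0, 10)`, `x3 ~ U(2, 7)`.
#'
#' @param grid_u,grid_v Lattice dimensions.
#' @param m Observations per location.
#' @param theta_mean,theta_sd Local dispersion distribution.
#' @param x2_range,x3_range Uniform covariate ranges.
#' @param seed Seed; identical seeds give identical datasets.
#' @return List with `dataset` (a [spatial_dataset()], covariates
#'   `x1, x2, x3`) and `truth` (data frame `location_id, u, v, phi0, phi1,
#'   phi2, theta`).
#' @export
simulate_lattice <- function(grid_u = 40, grid_v = 40, m = 100,
                             theta_mean = 0.5, theta_sd = 0.01,
                             x2_range = c(0, 10), x3_range = c(2, 7),
                             seed = 1) {
  stopifnot(grid_u >= 1, grid_v >= 1, m >= 1, theta_mean > 0)
  set.seed(seed)
  grid <- expand.grid(u = seq_len(grid_u), v = seq_len(grid_v))
  coef <- coefficient_surfaces(grid$u, grid$v)
  n_loc <- nrow(grid)
  theta <- rnorm(n_loc, theta_mean, theta_sd)
  while (any(theta <= 0)) {
    theta[theta <= 0] <- rnorm(sum(theta <= 0), theta_mean, theta_sd)
  }
  ids <- sprintf("L%d_%d", grid$u, grid$v)
  x2 <- runif(n_loc * m, x2_range[1], x2_range[2])
  x3 <- runif(n_loc * m, x3_range[1], x3_range[2])
  loc_idx <- rep(seq_len(n_loc), each = m)
  mu <- exp(coef$phi0[loc_idx] + coef$phi1[loc_idx] * x2 +
              coef$phi2[loc_idx] * x3)
  y <- rnbinom(n_loc * m, size = 1 / theta[loc_idx], mu = mu)
  df <- data.frame(location_id = rep(ids, each = m),
                   u = grid$u[loc_idx], v = grid$v[loc_idx],
                   y = y, x1 = 1, x2 = x2, x3 = x3,
                   stringsAsFactors = FALSE)
  ds <- spatial_dataset(df, covariates = c("x1", "x2", "x3"),
                        metric = "euclidean", family = "negative_binomial")
  truth <- data.frame(location_id = ids, u = grid$u, v = grid$v,
                      phi0 = coef$phi0, phi1 = coef$phi1, phi2 = coef$phi2,
                      theta = theta, stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth)
}

#' Simulate a Gaussian toy dataset
#'
#' Independent normal draws per location with stated means and a shared
#' standard deviation; the fixture for conjugate-posterior oracles and
#' weighted-mean consistency checks. The single covariate is an intercept
#' column `x1`.
#'
#' @param means Per-location true means.
#' @param sd Shared standard deviation (> 0).
#' @param m Observations per location.
#' @param coords Optional 2-column matrix of coordinates (default: locations
#'   placed at `(1, 1), (2, 1), ...` one unit apart).
#' @param seed Seed.
#' @return A Gaussian [spatial_dataset()] with locations `g1, g2, ...`.
#' @export
simulate_gaussian_toy <- function(means, sd, m, coords = NULL, seed = 1) {
  stopifnot(sd > 0, m >= 1)
  n_loc <- length(means)
  if (is.null(coords)) coords <- cbind(seq_len(n_loc), 1)
  coords <- rbind(coords)
  stopifnot(nrow(coords) == n_loc)
  set.seed(seed)
  ids <- paste0("g", seq_len(n_loc))
  loc_idx <- rep(seq_len(n_loc), each = m)
  df <- data.frame(location_id = ids[loc_idx],
                   u = coords[loc_idx, 1], v = coords[loc_idx, 2],
                   y = rnorm(n_loc * m, means[loc_idx], sd), x1 = 1,
                   stringsAsFactors = FALSE)
  spatial_dataset(df, covariates = "x1", metric = "euclidean",
                  family = "gaussian")
}
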