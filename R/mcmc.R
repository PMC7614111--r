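#' MCMC configuration
#'
#' Settings for the adaptive random-walk Metropolis sampler. `n_iterations`
#' is the total number of iterations per chain; the first `burn_in` are
#' discarded and are the only iterations during which proposal adaptation
#' takes place (the kernel is frozen afterwards, so retained draws come from
#' a fixed kernel). Defaults mirror the reference simulation design: 10
#' chains of 4000 iterations with 1000 burn-in.
#'
#' The coefficient block uses a joint multivariate normal proposal whose
#' covariance is adapted to the empirical chain covariance (scaled
#' \eqn{2.38^2/p}) with a Robbins-Monro-tuned global scale targeting
#' `target_accept_block`. Each nuisance parameter gets a componentwise
#' log-scale random walk targeting `target_accept_scalar`.
#'
#' @param n_chains Number of independent chains (>= 2 for split-Rhat).
#' @param n_iterations Total iterations per chain.
#' @param burn_in Discarded (and adapted) initial iterations; must be less
#'   than `n_iterations`.
#' @param seed Master seed. Per-(location, chain) sub-seeds are derived
#'   deterministically from it and from a hash of the location id, so
#'   results do not depend on execution order or parallel scheduling.
#' @param target_accept_block Target acceptance rate of the coefficient
#'   block (default 0.234).
#' @param target_accept_scalar Target acceptance rate of each nuisance
#'   update (default 0.44).
#' @param adapt Adapt proposals during burn-in (default `TRUE`).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 10, n_iterations = 4000, burn_in = 1000,
                        seed = 1, target_accept_block = 0.234,
                        target_accept_scalar = 0.44, adapt = TRUE) {
  stopifnot(n_chains >= 1, n_iterations >= 1, burn_in >= 0,
            burn_in < n_iterations,
            target_accept_block > 0, target_accept_block < 1,
            target_accept_scalar > 0, target_accept_scalar < 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 target_accept_block = target_accept_block,
                 target_accept_scalar = target_accept_scalar,
                 adapt = isTRUE(adapt)),
            class = "mcmc_config")
}

# deterministic 31-bit hash of a location id string
id_hash <- function(id) {
  h <- 0
  for (b in utf8ToInt(as.character(id))) h <- (h * 31 + b) %% 1000000007
  h
}

# counter-based sub-seed: depends on master seed, location id, chain index
sub_seed <- function(seed, id, chain) {
  (((seed %% 2147483587) * 48271) %% 2147483587 +
     (id_hash(id) * 97) %% 2147483587 +
     chain * 1000003) %% 2147483587 + 1
}

# pack a powered_posterior_problem into flat arrays for the C++ core;
# active locations only, centre first, rows grouped by location
pack_problem <- function(prob) {
  ds <- prob$ds
  active <- c(prob$center_id, setdiff(prob$weights$active_ids, prob$center_id))
  rows <- lapply(active, function(id) location_rows(ds, id))
  len <- lengths(rows)
  idx <- unlist(rows, use.names = FALSE)
  X <- as.matrix(ds$data[prob$ds$covariates])[idx, , drop = FALSE]
  list(family = if (prob$family$name == "negative_binomial") 0L else 1L,
       y = ds$data$y[idx], X = X, offset = ds$data$offset[idx],
       loc_start = as.integer(cumsum(c(0L, len[-length(len)]))),
       loc_len = as.integer(len),
       w = unname(prob$weights$weights[active]),
       active = active)
}

# kernel-weighted quasi-likelihood starting values; falls back to zeros
default_init <- function(prob, packed) {
  X <- packed$X
  wrow <- rep(packed$w, packed$loc_len)
  phi <- rep(0, ncol(X))
  if (packed$family == 0L) {
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, packed$y, weights = wrow,
                               offset = packed$offset,
                               family = quasipoisson())),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$coefficients))) {
      phi <- unname(fit$coefficients)
    }
    mu <- exp(as.numeric(X %*% phi) + packed$offset)
    theta <- vapply(seq_along(packed$w), function(k) {
      i <- (packed$loc_start[k] + 1):(packed$loc_start[k] + packed$loc_len[k])
      est <- sum((packed$y[i] - mu[i])^2 - mu[i]) / sum(mu[i]^2)
      min(max(est, 0.02), 50)
    }, numeric(1))
  } else {
    fit <- tryCatch(
      lm.wfit(X, packed$y - packed$offset, w = pmax(wrow, 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$coefficients))) {
      phi <- unname(fit$coefficients)
    }
    mu <- as.numeric(X %*% phi) + packed$offset
    theta <- vapply(seq_along(packed$w), function(k) {
      i <- (packed$loc_start[k] + 1):(packed$loc_start[k] + packed$loc_len[k])
      max(sqrt(mean((packed$y[i] - mu[i])^2)), 1e-4)
    }, numeric(1))
  }
  list(phi = phi, theta = theta)
}

#' Sample the geographically-powered posterior
#'
#' Runs `cfg$n_chains` independent adaptive Metropolis chains targeting the
#' unnormalized log powered posterior of `prob`. Auxiliary nuisance copies
#' are sampled internally but only the centre's `(theta, phi)` draws are
#' retained (they are the marginal of interest), unless `keep_aux = TRUE`.
#' Identical seeds give bitwise-identical output.
#'
#' @param prob A [powered_posterior_problem()].
#' @param cfg An [mcmc_config()].
#' @param init Optional list with `phi` (length p) and `theta` (scalar, or
#'   named vector over active locations) starting values. Default: a
#'   kernel-weighted quasi-Poisson (NB) or weighted least squares (Gaussian)
#'   estimate for `phi` and per-location moment estimates for `theta`.
#'   `init = "zero"` starts at `phi = 0`, `log theta = 0`.
#' @param fix_theta If `TRUE`, all nuisance parameters are held fixed at
#'   their initial values (known-theta sampling of `phi` only).
#' @param keep_aux Also retain the auxiliary nuisance draws (needed e.g. for
#'   the truncation diagnostic, which requires full-support states).
#' @return An object of class `chain_result`: list with `center_id`,
#'   `draws` (list of kept-draws matrices, one per chain, columns `theta`
#'   then the covariate names), `aux` (optional list of matrices, columns =
#'   active non-centre ids), `lp` (log-target traces), `acceptance` (per
#'   chain: coefficient-block rate and mean nuisance rate), `diagnostics`
#'   (per-parameter split-Rhat and effective sample size) and `config`.
#' @export
sample_powered_posterior <- function(prob, cfg, init = NULL,
                                     fix_theta = FALSE, keep_aux = FALSE) {
  packed <- pack_problem(prob)
  K <- length(packed$w)
  if (identical(init, "zero")) init <- list(phi = rep(0, ncol(packed$X)), theta = 1)
  if (is.null(init)) init <- default_init(prob, packed)
  phi0 <- init$phi
  if (length(phi0) != ncol(packed$X)) stop("init$phi has wrong length", call. = FALSE)
  th0 <- init$theta
  th0 <- if (length(th0) == 1L) rep(th0, K) else {
    if (is.null(names(th0))) {
      if (length(th0) != K) stop("init$theta has wrong length", call. = FALSE)
      th0
    } else unname(th0[packed$active])
  }
  if (any(!is.finite(th0)) || any(th0 <= 0)) stop("init$theta must be > 0", call. = FALSE)

  chains <- vector("list", cfg$n_chains)
  aux <- if (keep_aux) vector("list", cfg$n_chains) else NULL
  lp <- vector("list", cfg$n_chains)
  acc <- data.frame(chain = seq_len(cfg$n_chains), phi = NA_real_, theta = NA_real_)
  par_names <- c("theta", prob$ds$covariates)
  for (c in seq_len(cfg$n_chains)) {
    set.seed(sub_seed(cfg$seed, prob$center_id, c))
    out <- cpp_run_chain(packed$family, packed$y, packed$X, packed$offset,
                         packed$loc_start, packed$loc_len, packed$w,
                         prob$prior$phi_sd, prob$prior$log_theta_mean,
                         prob$prior$log_theta_sd,
                         phi0, log(th0),
                         cfg$n_iterations, cfg$burn_in, fix_theta,
                         cfg$target_accept_block, cfg$target_accept_scalar,
                         cfg$adapt, keep_aux)
    colnames(out$draws) <- par_names
    chains[[c]] <- out$draws
    if (keep_aux) {
      colnames(out$aux) <- setdiff(packed$active, prob$center_id)
      aux[[c]] <- out$aux
    }
    lp[[c]] <- out$lp
    acc$phi[c] <- out$accept_phi
    acc$theta[c] <- mean(out$accept_theta)
  }
  res <- structure(list(center_id = prob$center_id, draws = chains, aux = aux,
                        lp = lp, acceptance = acc, config = cfg,
                        fix_theta = fix_theta),
                   class = "chain_result")
  res$diagnostics <- chain_diagnostics(res)
  res
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("<chain_result> centre '%s': %d chains x %d kept draws; accept(phi) = %.2f, accept(theta) = %.2f\n",
              x$center_id, length(x$draws), nrow(x$draws[[1]]),
              mean(x$acceptance$phi), mean(x$acceptance$theta)))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Pool kept draws across chains
#'
#' @param res A `chain_result`.
#' @return Matrix of pooled draws (rows = chains stacked), columns `theta`
#'   then coefficients.
#' @export
pooled_draws <- function(res) do.call(rbind, res$draws)

# split-Rhat (chains halved) on a list of equal-length draw vectors
split_rhat <- function(chains) {
  if (length(unique(unlist(chains))) == 1L) return(1)  # constant chains
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)  # identical constant chains, by convention
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via initial-positive-sequence autocorrelations
ess_draws <- function(chains) {
  n <- length(chains[[1]])
  C <- length(chains)
  if (n < 4L) return(NA_real_)
  W <- mean(vapply(chains, var, numeric(1)))
  if (W == 0) return(NA_real_)
  lag_max <- min(n - 2L, 500L)
  rho <- rowMeans(vapply(chains, function(x) {
    a <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)
    as.numeric(a$acf)[-1]
  }, numeric(lag_max)))
  # Geyer: sum successive pairs while their sum stays positive
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  max(C * n / (1 + 2 * s), 1)
}

chain_diagnostics <- function(res) {
  pars <- colnames(res$draws[[1]])
  one_chain <- length(res$draws) < 2L
  out <- do.call(rbind, lapply(pars, function(pn) {
    cols <- lapply(res$draws, function(m) m[, pn])
    data.frame(parameter = pn,
               rhat = if (one_chain) NA_real_ else split_rhat(cols),
               ess = ess_draws(cols), stringsAsFactors = FALSE)
  }))
  if (one_chain) warning("split-Rhat requires at least 2 chains; omitted")
  out
}

#' Summarize chains
#'
#' Per-parameter posterior mean, median, 2.5% and 97.5% quantiles (type 7,
#' i.e. linear interpolation between order statistics), split-Rhat and
#' effective sample size, from pooled kept draws.
#'
#' @param res A `chain_result`.
#' @return Data frame with columns `parameter`, `mean`, `median`, `q2.5`,
#'   `q97.5`, `rhat`, `ess`.
#' @export
summarize_chains <- function(res) {
  pooled <- pooled_draws(res)
  out <- do.call(rbind, lapply(colnames(pooled), function(pn) {
    x <- pooled[, pn]
    data.frame(parameter = pn, mean = mean(x), median = median(x),
               q2.5 = unname(quantile(x, 0.025, type = 7)),
               q97.5 = unname(quantile(x, 0.975, type = 7)),
               stringsAsFactors = FALSE)
  }))
  merge(out, res$diagnostics, by = "parameter", sort = FALSE)
}

#' Fit one Bayesian GWR model per location
#'
#' Runs [sample_powered_posterior()] independently for every requested
#' location, each with the kernel centred at that location. Per-location
#' results depend only on the master seed and the location id (not on the
#' order of locations), so permuting the location list permutes but does not
#' change results. A failing location is reported and skipped; the others
#' complete.
#'
#' @param ds A [spatial_dataset()].
#' @param spec A [kernel_spec()].
#' @param family A [glm_family()]; defaults to the dataset's family.
#' @param prior A [prior_spec()].
#' @param cfg An [mcmc_config()].
#' @param center_ids Locations to fit (default: all).
#' @param ... Passed to [sample_powered_posterior()].
#' @return Named list (by location id) of `chain_result` objects; failures
#'   are recorded as condition messages and summarized in a warning.
#' @export
fit_all_locations <- function(ds, spec, family = glm_family(ds$family),
                              prior = prior_spec(), cfg = mcmc_config(),
                              center_ids = NULL, ...) {
  if (is.null(center_ids)) center_ids <- ds$locations$id
  out <- vector("list", length(center_ids))
  names(out) <- center_ids
  failed <- character(0)
  for (id in center_ids) {
    out[[id]] <- tryCatch({
      wv <- compute_weight_vector(ds, id, spec)
      prob <- powered_posterior_problem(ds, id, wv, family, prior)
      sample_powered_posterior(prob, cfg, ...)
    }, error = function(e) {
      failed <<- c(failed, id)
      structure(list(center_id = id, message = conditionMessage(e)),
                class = "fit_error")
    })
  }
  if (length(failed) > 0L) {
    warning("fit failed for ", length(failed), " location(s): ",
            paste(failed, collapse = ", "))
  }
  out
}
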