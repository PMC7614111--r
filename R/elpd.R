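#' Cross-validation configuration for bandwidth selection
#'
#' @param candidates Candidate bandwidths (strictly positive, nonempty).
#' @param holdout_fraction Share of each interest location's observations
#'   held out as test set (default 0.5, matching the reference design); must
#'   leave at least one training and one test observation.
#' @param folds Number of cross-validation folds Q (default 1). Each fold
#'   redraws the held-out subsets; fold means are averaged per candidate.
#' @param eval_location_ids Optional subset of locations over which the mean
#'   elpd is taken (default: all locations). Using a subset deviates from the
#'   all-locations mean and is flagged in the returned table.
#' @param seed Seed for the held-out draws. Held-out subsets are identical
#'   across candidates within a fold, so candidates are compared on the same
#'   splits.
#' @param mcmc An [mcmc_config()] used for every cross-validation fit.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(candidates, holdout_fraction = 0.5, folds = 1,
                      eval_location_ids = NULL, seed = 1,
                      mcmc = mcmc_config()) {
  if (length(candidates) == 0L || any(candidates <= 0)) {
    stop("candidates must be a nonempty set of positive bandwidths", call. = FALSE)
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(candidates = sort(unique(candidates)),
                 holdout_fraction = holdout_fraction,
                 folds = as.integer(folds),
                 eval_location_ids = eval_location_ids,
                 seed = as.integer(seed), mcmc = mcmc),
            class = "cv_config")
}

#' Estimate elpd from posterior draws on a test set
#'
#' The cross-validation elpd estimator: for each test observation, the log
#' of the posterior-predictive density is approximated by the log of the
#' average (over draws) of the observation's density, computed with
#' log-sum-exp; the estimate is the mean over test observations.
#'
#' @param test_obs Data frame of held-out rows with columns `y`, the
#'   covariates, and optionally `offset`.
#' @param draws Matrix of posterior draws with a `theta` column and one
#'   column per covariate (as returned in a `chain_result`, e.g. pooled with
#'   [pooled_draws()]), or a `chain_result` itself.
#' @param family A [glm_family()].
#' @param covariates Character vector naming the covariate columns of
#'   `test_obs` (and of `draws`).
#' @return Scalar elpd estimate; `-Inf` (with a warning) if every draw
#'   assigns zero density to some test point.
#' @export
estimate_elpd <- function(test_obs, draws, family, covariates) {
  if (inherits(draws, "chain_result")) draws <- pooled_draws(draws)
  if (nrow(test_obs) == 0L) stop("test set must be nonempty", call. = FALSE)
  if (is.null(dim(draws)) || nrow(draws) == 0L) {
    stop("draws must be a nonempty matrix", call. = FALSE)
  }
  X <- as.matrix(test_obs[covariates])
  off <- if ("offset" %in% names(test_obs)) test_obs$offset else 0
  phi <- draws[, covariates, drop = FALSE]
  theta <- draws[, "theta"]
  S <- nrow(draws)
  # log-density matrix: rows = test observations, cols = draws
  eta <- X %*% t(phi) + off
  ll <- if (family$name == "negative_binomial") {
    matrix(dnbinom(rep(test_obs$y, S), size = rep(1 / theta, each = nrow(X)),
                   mu = exp(as.numeric(eta)), log = TRUE), nrow = nrow(X))
  } else {
    matrix(dnorm(rep(test_obs$y, S), mean = as.numeric(eta),
                 sd = rep(theta, each = nrow(X)), log = TRUE), nrow = nrow(X))
  }
  lpd <- apply(ll, 1, log_mean_exp)
  if (any(lpd == -Inf)) {
    warning("every draw assigns zero density to some test point; elpd is -Inf")
  }
  mean(lpd)
}

# log(mean(exp(x))) via log-sum-exp; stays finite where the naive average
# underflows
log_mean_exp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(mean(exp(x - m)))
}

#' Cross-validated elpd over candidate bandwidths
#'
#' For each fold, a random `holdout_fraction` subset of observations is held
#' out at every evaluation location (the same subsets for every candidate).
#' For each candidate bandwidth and evaluation location, the powered
#' posterior centred there is fitted on the full dataset minus that
#' location's held-out rows only, and the elpd is estimated on the held-out
#' rows from the pooled post-burn-in draws (per-chain estimates are recorded
#' alongside). The mean curve averages pooled estimates over evaluation
#' locations, then over folds.
#'
#' @param ds A [spatial_dataset()].
#' @param spec_template A [kernel_spec()] whose bandwidth is overridden by
#'   each candidate (kernel family, threshold and metric are taken from it).
#' @param family A [glm_family()]; defaults to the dataset's family.
#' @param prior A [prior_spec()].
#' @param cv A [cv_config()].
#' @param progress Print one line per (candidate, location) fit.
#' @return An object of class `elpd_table`: list with `entries` (data frame
#'   `location_id, eta, fold, chain, elpd`, where `chain` is `"pooled"` or a
#'   chain index), `mean_curve` (data frame `eta, elpd`),
#'   `phi_posterior_means` (data frame `location_id, eta, fold, parameter,
#'   mean` of coefficient posterior means, a byproduct for error analysis),
#'   and `eval_subset` (`TRUE` if a location subset was used).
#' @export
run_bandwidth_cv <- function(ds, spec_template, family = glm_family(ds$family),
                             prior = prior_spec(), cv, progress = FALSE) {
  eval_ids <- cv$eval_location_ids
  if (is.null(eval_ids)) eval_ids <- ds$locations$id
  if (!all(eval_ids %in% ds$locations$id)) {
    stop("eval_location_ids contains unknown location id(s)", call. = FALSE)
  }
  m_all <- table(factor(ds$data$location_id, levels = ds$locations$id))
  for (id in eval_ids) {
    m <- m_all[[id]]
    n_test <- round(cv$holdout_fraction * m)
    if (n_test < 1L || m - n_test < 1L) {
      stop("holdout infeasible at location '", id,
           "': m = ", m, ", holdout_fraction = ", cv$holdout_fraction,
           call. = FALSE)
    }
  }
  entries <- list()
  phi_means <- list()
  for (q in seq_len(cv$folds)) {
    # held-out rows per location, drawn once per fold, shared by candidates
    set.seed((cv$seed * 7907 + q * 65537) %% 2147483587)
    heldout <- lapply(eval_ids, function(id) {
      rows <- location_rows(ds, id)
      sample(rows, round(cv$holdout_fraction * length(rows)))
    })
    names(heldout) <- eval_ids
    for (eta in cv$candidates) {
      spec <- kernel_spec(spec_template$family, bandwidth = eta,
                          threshold = spec_template$threshold,
                          metric = spec_template$metric,
                          earth_radius = spec_template$earth_radius)
      for (id in eval_ids) {
        train <- drop_rows(ds, heldout[[id]])
        test_obs <- ds$data[heldout[[id]], , drop = FALSE]
        wv <- compute_weight_vector(train, id, spec)
        prob <- powered_posterior_problem(train, id, wv, family, prior)
        cfg <- cv$mcmc
        cfg$seed <- (cfg$seed + q * 104729) %% 2147483587
        res <- sample_powered_posterior(prob, cfg)
        pooled <- estimate_elpd(test_obs, res, family, ds$covariates)
        per_chain <- vapply(res$draws, function(m)
          estimate_elpd(test_obs, m, family, ds$covariates), numeric(1))
        entries[[length(entries) + 1L]] <- data.frame(
          location_id = id, eta = eta, fold = q,
          chain = c("pooled", as.character(seq_along(per_chain))),
          elpd = c(pooled, per_chain), stringsAsFactors = FALSE)
        pm <- colMeans(pooled_draws(res))
        phi_means[[length(phi_means) + 1L]] <- data.frame(
          location_id = id, eta = eta, fold = q,
          parameter = names(pm), mean = unname(pm), stringsAsFactors = FALSE)
        if (progress) {
          message(sprintf("fold %d eta %-8g location %-6s elpd %.4f", q, eta,
                          id, pooled))
        }
      }
    }
  }
  entries <- do.call(rbind, entries)
  pooled <- entries[entries$chain == "pooled", ]
  per_eta_fold <- aggregate(elpd ~ eta + fold, data = pooled, FUN = mean)
  mean_curve <- aggregate(elpd ~ eta, data = per_eta_fold, FUN = mean)
  structure(list(entries = entries,
                 mean_curve = mean_curve[order(mean_curve$eta), ],
                 phi_posterior_means = do.call(rbind, phi_means),
                 eval_subset = !setequal(eval_ids, ds$locations$id),
                 cv = cv),
            class = "elpd_table")
}

#' @export
print.elpd_table <- function(x, ...) {
  cat("<elpd_table> mean elpd by bandwidth",
      if (x$eval_subset) "(mean over a location subset)" else "", "\n")
  print(x$mean_curve, row.names = FALSE)
  invisible(x)
}

#' Select the bandwidth maximizing mean cross-validated elpd
#'
#' The optimal bandwidth maximizes the mean (across locations, then folds)
#' elpd; ties are broken toward the smallest candidate.
#'
#' @param table An `elpd_table` from [run_bandwidth_cv()].
#' @return An object of class `bandwidth_result`: list with `selected`,
#'   `curve` and `tie_broken`.
#' @export
select_bandwidth <- function(table) {
  curve <- table$mean_curve
  if (is.null(curve) || nrow(curve) == 0L) stop("empty elpd table", call. = FALSE)
  best <- max(curve$elpd)
  winners <- curve$eta[curve$elpd == best]
  structure(list(selected = min(winners), curve = curve,
                 tie_broken = length(winners) > 1L),
            class = "bandwidth_result")
}

#' @export
print.bandwidth_result <- function(x, ...) {
  cat(sprintf("<bandwidth_result> selected eta = %g%s\n", x$selected,
              if (x$tie_broken) " (tie broken toward smallest)" else ""))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @importFrom stats aggregate
NULL
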