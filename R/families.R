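#' GLM family descriptor
#'
#' The two supported outcome families. The link is fixed by the family: log
#' for the negative binomial, identity for the Gaussian. The family interface
#' (log-density + moments + linear predictor) is what a new family (e.g. beta
#' regression) would have to provide.
#'
#' @param name `"negative_binomial"` or `"gaussian"`.
#' @return An object of class `glm_family` with elements `name` and `link`.
#' @export
glm_family <- function(name = c("negative_binomial", "gaussian")) {
  name <- match.arg(name)
  structure(list(name = name,
                 link = if (name == "negative_binomial") "log" else "identity"),
            class = "glm_family")
}

#' Negative binomial log-density (quadratic-variance parameterization)
#'
#' Log pmf of the negative binomial with mean
#' \eqn{\mu = \exp(\mathrm{offset} + x\phi)} and variance
#' \eqn{\mu + \theta\mu^2}. Note \eqn{\theta} here is the *reciprocal* of the
#' conventional "size": `dnbinom(size = 1/theta, mu = mu)`. Computed entirely
#' in log space.
#'
#' @param y Non-negative integer count(s).
#' @param x Covariate row (length p) or matrix (rows matching `y`).
#' @param phi Coefficient vector, length p.
#' @param theta Dispersion \eqn{\theta > 0}.
#' @param offset Log exposure, scalar or per-row (default 0).
#' @return Log-density, same length as `y`.
#' @export
nb_log_density <- function(y, x, phi, theta, offset = 0) {
  if (any(theta <= 0)) stop("theta must be > 0", call. = FALSE)
  if (any(y < 0) || any(y != floor(y))) {
    stop("y must be a non-negative integer", call. = FALSE)
  }
  mu <- exp(linear_predictor(x, phi) + offset)
  dnbinom(y, size = 1 / theta, mu = mu, log = TRUE)
}

#' Negative binomial mean and variance
#'
#' Mean \eqn{\mu = \exp(\mathrm{offset} + x\phi)}; variance
#' \eqn{\mu + \theta\mu^2} (equal in the \eqn{\theta \to 0} Poisson limit).
#'
#' @inheritParams nb_log_density
#' @return List with elements `mean` and `variance`.
#' @export
nb_moments <- function(x, phi, theta, offset = 0) {
  if (any(theta < 0)) stop("theta must be >= 0", call. = FALSE)
  mu <- exp(linear_predictor(x, phi) + offset)
  list(mean = mu, variance = mu + theta * mu^2)
}

#' Gaussian log-density with identity link
#'
#' Normal log-density with mean `offset + x phi` and standard deviation
#' `theta`.
#'
#' @inheritParams nb_log_density
#' @param y Real outcome(s).
#' @param theta Standard deviation \eqn{\theta > 0}.
#' @return Log-density, same length as `y`.
#' @export
gaussian_log_density <- function(y, x, phi, theta, offset = 0) {
  if (any(theta <= 0)) stop("theta must be > 0", call. = FALSE)
  dnorm(y, mean = linear_predictor(x, phi) + offset, sd = theta, log = TRUE)
}

linear_predictor <- function(x, phi) {
  if (is.matrix(x)) as.numeric(x %*% phi) else sum(x * phi)
}

# family-generic observation log-density for rows of a long data frame
family_log_density <- function(family, y, x, phi, theta, offset = 0) {
  if (family$name == "negative_binomial") {
    nb_log_density(y, x, phi, theta, offset)
  } else {
    gaussian_log_density(y, x, phi, theta, offset)
  }
}

#' Prior specification
#'
#' Independent, proper priors: each coefficient \eqn{\phi_k \sim N(0,
#' \mathrm{phi\_sd}^2)}; the nuisance parameter at the centre and every
#' auxiliary copy \eqn{\tilde\theta_i \sim
#' \mathrm{LogNormal}(\mathrm{log\_theta\_mean}, \mathrm{log\_theta\_sd}^2)}.
#' Propriety matters: the powered posterior is only defined when the prior
#' integrates the weighted likelihood to a finite normalizer.
#'
#' @param phi_sd Normal prior scale per coefficient (> 0); default 10
#'   (weakly informative).
#' @param log_theta_mean,log_theta_sd Lognormal prior parameters for the
#'   nuisance parameters; defaults 0 and 1.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(phi_sd = 10, log_theta_mean = 0, log_theta_sd = 1) {
  if (phi_sd <= 0 || log_theta_sd <= 0) stop("prior scales must be > 0", call. = FALSE)
  structure(list(phi_sd = phi_sd, log_theta_mean = log_theta_mean,
                 log_theta_sd = log_theta_sd),
            class = "prior_spec")
}

#' Parameter state of the powered posterior
#'
#' The augmented parameter: the nuisance parameter at the centre, one
#' auxiliary copy per active non-centre location, and the shared coefficient
#' vector.
#'
#' @param theta_center Positive scalar (NB dispersion / Gaussian sd at the
#'   centre).
#' @param phi Coefficient vector.
#' @param theta_aux Named positive vector of auxiliary nuisance values (by
#'   location id); may be empty.
#' @return An object of class `parameter_state`.
#' @export
parameter_state <- function(theta_center, phi, theta_aux = numeric(0)) {
  if (theta_center <= 0 || any(theta_aux <= 0)) {
    stop("theta values must be > 0", call. = FALSE)
  }
  if (any(!is.finite(phi))) stop("phi must be finite", call. = FALSE)
  if (length(theta_aux) > 0L && is.null(names(theta_aux))) {
    stop("theta_aux must be named by location id", call. = FALSE)
  }
  structure(list(theta_center = theta_center, phi = phi, theta_aux = theta_aux),
            class = "parameter_state")
}

#' Log prior density of a parameter state
#'
#' Sum of the independent prior terms of [prior_spec()] over `phi`, the
#' centre nuisance parameter and every auxiliary copy in the state.
#'
#' @param state A [parameter_state()].
#' @param prior A [prior_spec()].
#' @return Scalar log-density.
#' @export
log_prior <- function(state, prior) {
  if (state$theta_center <= 0 || any(state$theta_aux <= 0)) {
    stop("theta values must be > 0", call. = FALSE)
  }
  sum(dnorm(state$phi, 0, prior$phi_sd, log = TRUE)) +
    sum(dlnorm(c(state$theta_center, state$theta_aux),
               prior$log_theta_mean, prior$log_theta_sd, log = TRUE))
}
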