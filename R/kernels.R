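#' Kernel specification
#'
#' Describes the geographically weighted kernel: Gaussian
#' \eqn{W(d, \eta) = \exp(-d^2/\eta^2)} or its truncated variant, which is
#' zero wherever \eqn{\exp(-d^2/\eta^2) \le W^*} (strict inequality keeps a
#' weight). Distances and the bandwidth must share units; the package never
#' converts units.
#'
#' @param family `"gaussian"` or `"truncated_gaussian"`.
#' @param bandwidth Bandwidth \eqn{\eta > 0}, in distance units.
#' @param threshold Truncation threshold \eqn{W^* \in [0, 1)} (truncated
#'   family only; `threshold = 0` reproduces the untruncated kernel).
#' @param metric `"euclidean"` or `"haversine"`.
#' @param earth_radius Sphere radius for the haversine metric; default 6371
#'   (mean Earth radius, km).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "truncated_gaussian"),
                        bandwidth, threshold = 0,
                        metric = c("euclidean", "haversine"),
                        earth_radius = 6371) {
  family <- match.arg(family)
  metric <- match.arg(metric)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0) {
    stop("bandwidth must be a single positive number", call. = FALSE)
  }
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  structure(list(family = family, bandwidth = bandwidth,
                 threshold = if (family == "truncated_gaussian") threshold else 0,
                 metric = metric, earth_radius = earth_radius),
            class = "kernel_spec")
}

#' Euclidean distance between planar coordinates
#'
#' @param a,b Numeric length-2 vectors `c(u, v)`, or two-column matrices
#'   (rowwise).
#' @return Non-negative distance(s) in coordinate units.
#' @export
euclidean_distance <- function(a, b) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(unname(x), ncol = 2)
}

#' Great-circle (haversine) distance
#'
#' Coordinates are (longitude, latitude) in decimal degrees, in that order.
#' Computed with [geosphere::distHaversine()] on a sphere of radius
#' `earth_radius`.
#'
#' @param a,b Numeric length-2 vectors `c(lon, lat)` in degrees, or
#'   two-column matrices.
#' @param earth_radius Sphere radius; the result is in the same units.
#' @return Non-negative distance(s), at most `pi * earth_radius`.
#' @export
haversine_distance <- function(a, b, earth_radius = 6371) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  if (any(abs(a[, 2]) > 90) || any(abs(b[, 2]) > 90)) {
    stop("latitude must lie in [-90, 90] degrees", call. = FALSE)
  }
  if (any(abs(a[, 1]) > 180) || any(abs(b[, 1]) > 180)) {
    stop("longitude must lie in [-180, 180] degrees", call. = FALSE)
  }
  geosphere::distHaversine(a, b, r = earth_radius)
}

#' Gaussian kernel weight
#'
#' \eqn{W(d, \eta) = \exp(-d^2 / \eta^2)}: equal to 1 at distance zero,
#' strictly decreasing in distance, strictly increasing in the bandwidth for
#' positive distance.
#'
#' @param d Non-negative distance(s).
#' @param eta Bandwidth \eqn{\eta > 0}, in the same units as `d`.
#' @return Weight(s) in (0, 1].
#' @export
gaussian_weight <- function(d, eta) {
  if (!is.numeric(eta) || any(eta <= 0)) stop("eta must be > 0", call. = FALSE)
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  exp(-(d / eta)^2)
}

#' Truncated Gaussian kernel weight
#'
#' Equals [gaussian_weight()] where that exceeds the threshold `w_star`, and
#' exactly 0 otherwise. Used to bound the number of likelihood evaluations:
#' only locations with nonzero weight enter the powered posterior.
#'
#' @inheritParams gaussian_weight
#' @param w_star Threshold \eqn{W^* \in [0, 1)}.
#' @return Weight(s) in `{0}` or `(w_star, 1]`.
#' @export
truncated_gaussian_weight <- function(d, eta, w_star) {
  if (w_star < 0 || w_star >= 1) stop("w_star must lie in [0, 1)", call. = FALSE)
  w <- gaussian_weight(d, eta)
  ifelse(w > w_star, w, 0)
}

#' Distances from one location to all locations of a dataset
#'
#' @param ds A [spatial_dataset()].
#' @param center_id Location id of the centre.
#' @param spec A [kernel_spec()] (supplies metric and earth radius).
#' @return Named numeric vector of distances, in `ds` location order.
#' @export
location_distances <- function(ds, center_id, spec) {
  k <- match(center_id, ds$locations$id)
  if (is.na(k)) stop("unknown location id: ", center_id, call. = FALSE)
  pts <- cbind(ds$locations$u, ds$locations$v)
  ctr <- pts[k, , drop = FALSE]
  d <- if (spec$metric == "haversine") {
    as.numeric(geosphere::distHaversine(pts, ctr, r = spec$earth_radius))
  } else {
    sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  }
  d[k] <- 0  # centre distance exact, regardless of metric round-off
  setNames(d, ds$locations$id)
}

#' Kernel weights of all locations relative to a centre
#'
#' The centre's weight is exactly 1 (distance zero). `active_ids` lists the
#' locations with strictly positive weight; under the truncated kernel these
#' are the only locations whose likelihood is evaluated.
#'
#' @inheritParams location_distances
#' @return An object of class `weight_vector`: list with `center_id`,
#'   `weights` (named, in location order) and `active_ids`.
#' @export
compute_weight_vector <- function(ds, center_id, spec) {
  d <- location_distances(ds, center_id, spec)
  w <- if (spec$family == "truncated_gaussian") {
    truncated_gaussian_weight(d, spec$bandwidth, spec$threshold)
  } else {
    gaussian_weight(d, spec$bandwidth)
  }
  w[center_id] <- 1
  structure(list(center_id = center_id, weights = w,
                 active_ids = names(w)[w > 0]),
            class = "weight_vector")
}

#' Construct a weight vector directly from weights
#'
#' Mainly for toys and tests where weights are stated rather than derived
#' from a kernel.
#'
#' @param center_id Centre location id (must carry weight 1).
#' @param weights Named numeric vector of weights in `[0, 1]` over all
#'   location ids of the dataset.
#' @return A `weight_vector`.
#' @export
weight_vector <- function(center_id, weights) {
  if (is.null(names(weights))) stop("weights must be named by location id", call. = FALSE)
  if (!center_id %in% names(weights)) stop("center_id missing from weights", call. = FALSE)
  if (weights[[center_id]] != 1) stop("weight at the centre must equal 1", call. = FALSE)
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  structure(list(center_id = center_id, weights = weights,
                 active_ids = names(weights)[weights > 0]),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> centre '%s', %d active of %d locations\n",
              x$center_id, length(x$active_ids), length(x$weights)))
  invisible(x)
}
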