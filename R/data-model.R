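#' Construct a spatial dataset
#'
#' Bundles long-format spatial observations into the container used by every
#' fitting function: an ordered table of locations (unique id plus planar or
#' lon/lat coordinates) and, per location, an outcome vector, a covariate
#' matrix and an optional offset (log exposure) vector.
#'
#' Observations within a location are treated as exchangeable (iid given the
#' location's parameters). Locations are ordered by first appearance in
#' `data`. Unequal numbers of observations across locations are permitted.
#'
#' @param data Data frame in long format: one row per observation, with an id
#'   column, coordinate columns, an outcome column, covariate columns and
#'   optionally an offset column.
#' @param covariates Character vector naming the covariate columns (include
#'   an explicit all-ones column for an intercept if one is wanted; see
#'   [add_intercept()]).
#' @param metric Distance metric: `"euclidean"` (planar coordinates) or
#'   `"haversine"` (`u` = longitude, `v` = latitude, decimal degrees).
#' @param family Outcome family: `"negative_binomial"` (non-negative integer
#'   outcomes, log link) or `"gaussian"` (identity link).
#' @param id,u,v,y,offset Names of the id, coordinate, outcome and offset
#'   columns. `offset = NULL` (default) sets all offsets to zero, so the NB
#'   mean reduces to `exp(X phi)`.
#' @return An object of class `spatial_dataset`: a list with elements
#'   `locations` (data frame `id`, `u`, `v`), `data` (long data frame with
#'   columns `location_id`, `y`, `offset` and the covariates), `covariates`,
#'   `metric`, `family`.
#' @export
spatial_dataset <- function(data, covariates,
                            metric = c("euclidean", "haversine"),
                            family = c("negative_binomial", "gaussian"),
                            id = "location_id", u = "u", v = "v", y = "y",
                            offset = NULL) {
  metric <- match.arg(metric)
  family <- match.arg(family)
  needed <- c(id, u, v, y, covariates, offset)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("schema error: column(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- as.character(data[[id]])
  first <- !duplicated(ids)
  locations <- data.frame(id = ids[first],
                          u = as.numeric(data[[u]][first]),
                          v = as.numeric(data[[v]][first]),
                          stringsAsFactors = FALSE)
  # a single id must not carry two different coordinate pairs
  for (k in seq_len(nrow(locations))) {
    sel <- ids == locations$id[k]
    if (any(data[[u]][sel] != locations$u[k]) ||
        any(data[[v]][sel] != locations$v[k])) {
      stop("validation error: inconsistent coordinates for location id '",
           locations$id[k], "'", call. = FALSE)
    }
  }
  long <- data.frame(location_id = ids,
                     y = as.numeric(data[[y]]),
                     offset = if (is.null(offset)) 0 else as.numeric(data[[offset]]),
                     stringsAsFactors = FALSE)
  for (cv in covariates) long[[cv]] <- as.numeric(data[[cv]])
  ds <- new_spatial_dataset(locations, long, covariates, metric, family)
  problems <- validate_spatial_dataset(ds)
  if (length(problems) > 0L) {
    stop("validation error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  ds
}

new_spatial_dataset <- function(locations, data, covariates, metric, family) {
  structure(list(locations = locations, data = data, covariates = covariates,
                 metric = metric, family = family),
            class = "spatial_dataset")
}

#' Validate a spatial dataset
#'
#' Checks every container invariant and returns the violations found rather
#' than raising: unique ids, finite coordinates, at least one observation per
#' location, identical covariate dimension everywhere, finite offsets, and
#' (for the negative binomial family) non-negative integer outcomes.
#'
#' @param ds A `spatial_dataset` (possibly hand-corrupted).
#' @return Character vector of violation descriptions; empty iff `ds` is
#'   valid. Each entry names the offending location id and field.
#' @export
validate_spatial_dataset <- function(ds) {
  out <- character(0)
  loc <- ds$locations
  dup <- unique(loc$id[duplicated(loc$id)])
  for (d in dup) out <- c(out, sprintf("location '%s': duplicate id", d))
  bad <- !is.finite(loc$u) | !is.finite(loc$v)
  for (d in loc$id[bad]) {
    out <- c(out, sprintf("location '%s': non-finite coordinates (u, v)", d))
  }
  counts <- table(factor(ds$data$location_id, levels = unique(loc$id)))
  for (d in names(counts)[counts == 0L]) {
    out <- c(out, sprintf("location '%s': no observations (m >= 1 required)", d))
  }
  orphan <- setdiff(unique(ds$data$location_id), loc$id)
  for (d in orphan) {
    out <- c(out, sprintf("location '%s': observations without a location entry", d))
  }
  if (!all(ds$covariates %in% names(ds$data))) {
    out <- c(out, sprintf(
      "covariates: declared p = %d but data carries %d of the declared columns",
      length(ds$covariates), sum(ds$covariates %in% names(ds$data))))
  }
  if (any(!is.finite(ds$data$offset))) {
    d <- unique(ds$data$location_id[!is.finite(ds$data$offset)])
    out <- c(out, sprintf("location '%s': non-finite offset", d))
  }
  if (identical(ds$family, "negative_binomial")) {
    y <- ds$data$y
    bad <- !is.finite(y) | y < 0 | y != floor(y)
    for (d in unique(ds$data$location_id[bad])) {
      out <- c(out, sprintf(
        "location '%s': y must be a non-negative integer under negative_binomial", d))
    }
  } else {
    bad <- !is.finite(ds$data$y)
    for (d in unique(ds$data$location_id[bad])) {
      out <- c(out, sprintf("location '%s': non-finite y", d))
    }
  }
  out
}

#' Read a spatial dataset from delimited text
#'
#' Reads a comma-separated file with a header row (columns
#' `location_id,u,v,y,x1..xp[,offset]` by default, renameable through
#' `schema`) and returns a validated [spatial_dataset()]. Row order within a
#' location is preserved; locations are ordered by first appearance.
#'
#' @param path Path to a CSV file.
#' @param covariates Character vector of covariate column names.
#' @param schema Optional named list remapping the `id`, `u`, `v`, `y` and
#'   `offset` roles to column names, e.g. `list(y = "cases")`.
#' @inheritParams spatial_dataset
#' @return A `spatial_dataset`.
#' @export
read_spatial_dataset <- function(path, covariates,
                                 metric = c("euclidean", "haversine"),
                                 family = c("negative_binomial", "gaussian"),
                                 schema = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  defaults <- list(id = "location_id", u = "u", v = "v", y = "y", offset = NULL)
  defaults[names(schema)] <- schema
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  spatial_dataset(df, covariates = covariates, metric = metric,
                  family = family, id = defaults$id, u = defaults$u,
                  v = defaults$v, y = defaults$y, offset = defaults$offset)
}

#' Write a spatial dataset to delimited text
#'
#' Inverse of [read_spatial_dataset()]: writes the long-format table
#' (`location_id,u,v,y,<covariates>,offset`) as CSV.
#'
#' @param ds A `spatial_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spatial_dataset <- function(ds, path) {
  idx <- match(ds$data$location_id, ds$locations$id)
  out <- data.frame(location_id = ds$data$location_id,
                    u = ds$locations$u[idx], v = ds$locations$v[idx],
                    y = ds$data$y, stringsAsFactors = FALSE)
  for (cv in ds$covariates) out[[cv]] <- ds$data[[cv]]
  out$offset <- ds$data$offset
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Append an all-ones intercept column
#'
#' @param data Data frame.
#' @param name Column name for the intercept (default `"x1"`).
#' @return `data` with the constant column added.
#' @export
add_intercept <- function(data, name = "x1") {
  data[[name]] <- 1
  data
}

#' Write per-location posterior summaries to CSV
#'
#' Writes columns `location_id,parameter,median,ci_lower,ci_upper` (95%
#' equal-tailed credible intervals). Quantiles throughout the package are
#' empirical quantiles with linear interpolation between order statistics
#' (R's default type 7 rule).
#'
#' @param results Either a data frame with those five columns, or a named
#'   list (by location id) of [summarize_chains()] outputs.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(results, path) {
  if (is.data.frame(results)) {
    tab <- results
  } else {
    tab <- do.call(rbind, lapply(names(results), function(id) {
      s <- results[[id]]
      data.frame(location_id = id, parameter = s$parameter,
                 median = s$median, ci_lower = s$q2.5, ci_upper = s$q97.5,
                 stringsAsFactors = FALSE)
    }))
  }
  needed <- c("location_id", "parameter", "median", "ci_lower", "ci_upper")
  if (!all(needed %in% names(tab))) {
    stop("summaries must provide columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(tab$ci_lower <= tab$median & tab$median <= tab$ci_upper))
  write.csv(tab[needed], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write raw posterior draws to CSV
#'
#' Exports kept draws as delimited text with columns
#' `location_id,chain,iteration,theta,<covariate names>`, one row per kept
#' iteration per chain per location.
#'
#' @param fits A `chain_result`, or a named list of them (as returned by
#'   [fit_all_locations()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(fits, path) {
  if (inherits(fits, "chain_result")) fits <- setNames(list(fits), fits$center_id)
  tab <- do.call(rbind, lapply(fits, function(res) {
    do.call(rbind, lapply(seq_along(res$draws), function(c) {
      m <- res$draws[[c]]
      cbind(data.frame(location_id = res$center_id, chain = c,
                       iteration = seq_len(nrow(m)), stringsAsFactors = FALSE),
            as.data.frame(m))
    }))
  }))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  m <- table(factor(x$data$location_id, levels = x$locations$id))
  cat(sprintf("<spatial_dataset> %d locations, %d observations (m: %s), p = %d, family = %s, metric = %s\n",
              nrow(x$locations), nrow(x$data),
              if (length(unique(m)) == 1L) as.character(m[1]) else
                sprintf("%d-%d", min(m), max(m)),
              length(x$covariates), x$family, x$metric))
  invisible(x)
}

# rows of ds$data belonging to one location, in stored order
location_rows <- function(ds, id) which(ds$data$location_id == id)

# drop selected observation rows (by row index into ds$data)
drop_rows <- function(ds, rows) {
  if (length(rows) == 0L) return(ds)
  new_spatial_dataset(ds$locations, ds$data[-rows, , drop = FALSE],
                      ds$covariates, ds$metric, ds$family)
}
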