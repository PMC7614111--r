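#' Pipeline run configuration
#'
#' One structured object describing an end-to-end run: where the data come
#' from (a CSV path or a lattice simulation), the model, the kernel
#' (bandwidth possibly `"auto"`, requiring a CV config), and the MCMC
#' settings.
#'
#' @param data Either a CSV path (read with [read_spatial_dataset()]) or a
#'   list of [simulate_lattice()] arguments with `simulate = TRUE`.
#' @param covariates Covariate column names (ignored when simulating).
#' @param family `"negative_binomial"` or `"gaussian"`.
#' @param prior A [prior_spec()].
#' @param kernel A [kernel_spec()], or a list of [kernel_spec()] arguments
#'   with `bandwidth = "auto"`.
#' @param cv A [cv_config()]; required when `bandwidth = "auto"`.
#' @param mcmc An [mcmc_config()] for the final fit.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; overrides the seeds inside `mcmc` and `cv`.
#' @param center_ids Locations to fit in the final stage (default: all).
#' @return An object of class `run_config`.
#' @export
run_config <- function(data, covariates = NULL,
                       family = c("negative_binomial", "gaussian"),
                       prior = prior_spec(), kernel, cv = NULL,
                       mcmc = mcmc_config(), out_dir, seed = 1,
                       center_ids = NULL) {
  family <- match.arg(family)
  auto <- is.list(kernel) && !inherits(kernel, "kernel_spec") &&
    identical(kernel$bandwidth, "auto")
  if (auto && is.null(cv)) {
    stop("bandwidth = \"auto\" requires a cv_config", call. = FALSE)
  }
  structure(list(data = data, covariates = covariates, family = family,
                 prior = prior, kernel = kernel, auto_bandwidth = auto,
                 cv = cv, mcmc = mcmc, out_dir = out_dir,
                 seed = as.integer(seed), center_ids = center_ids),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: (1) load or simulate the dataset; (2) if the bandwidth is
#' `"auto"`, run [run_bandwidth_cv()] and [select_bandwidth()]; (3) refit
#' every location on the complete dataset at the chosen bandwidth; (4) write
#' posterior summaries. All artifacts are CSV files under `cfg$out_dir`,
#' recorded in a JSON manifest together with the exact seeds used, so a
#' rerun with the same config reproduces them.
#'
#' @param cfg A [run_config()].
#' @param progress Print stage progress.
#' @return The manifest (also written to `manifest.json`): list of artifact
#'   paths, the selected bandwidth, seeds and timings.
#' @export
run_pipeline <- function(cfg, progress = FALSE) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, artifacts = list(), timings = list())
  t0 <- Sys.time()

  # stage: data
  if (is.character(cfg$data)) {
    ds <- read_spatial_dataset(cfg$data, covariates = cfg$covariates,
                               family = cfg$family)
    truth <- NULL
  } else {
    sim_args <- cfg$data
    sim_args$simulate <- NULL
    sim_args$seed <- cfg$seed
    sim <- do.call(simulate_lattice, sim_args)
    ds <- sim$dataset
    truth <- sim$truth
    data_path <- file.path(cfg$out_dir, "simulated_data.csv")
    write_spatial_dataset(ds, data_path)
    truth_path <- file.path(cfg$out_dir, "truth.csv")
    write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
    manifest$artifacts$data <- data_path
    manifest$artifacts$truth <- truth_path
  }
  manifest$n_locations <- nrow(ds$locations)
  manifest$timings$data <- as.numeric(Sys.time() - t0, units = "secs")

  # stage: bandwidth selection
  if (cfg$auto_bandwidth) {
    ka <- cfg$kernel
    ka$bandwidth <- cfg$cv$candidates[1]
    spec_template <- do.call(kernel_spec, ka)
    cv <- cfg$cv
    cv$seed <- cfg$seed
    cv$mcmc$seed <- cfg$seed
    t1 <- Sys.time()
    tab <- run_bandwidth_cv(ds, spec_template, glm_family(cfg$family),
                            cfg$prior, cv, progress = progress)
    sel <- select_bandwidth(tab)
    elpd_path <- file.path(cfg$out_dir, "elpd_table.csv")
    write.csv(tab$entries, elpd_path, row.names = FALSE, quote = FALSE)
    curve_path <- file.path(cfg$out_dir, "elpd_curve.csv")
    write.csv(tab$mean_curve, curve_path, row.names = FALSE, quote = FALSE)
    manifest$artifacts$elpd_table <- elpd_path
    manifest$artifacts$elpd_curve <- curve_path
    manifest$selected_bandwidth <- sel$selected
    manifest$tie_broken <- sel$tie_broken
    manifest$eval_subset <- tab$eval_subset
    if (isTRUE(tab$eval_subset)) {
      warning("elpd mean taken over a subset of locations, not all locations")
    }
    manifest$timings$bandwidth_cv <- as.numeric(Sys.time() - t1, units = "secs")
    eta <- sel$selected
    spec <- do.call(kernel_spec, c(list(bandwidth = eta),
                                   ka[setdiff(names(ka), "bandwidth")]))
  } else {
    spec <- if (inherits(cfg$kernel, "kernel_spec")) cfg$kernel else
      do.call(kernel_spec, cfg$kernel)
    manifest$selected_bandwidth <- spec$bandwidth
  }

  # stage: final fit on the complete dataset
  t2 <- Sys.time()
  mcmc <- cfg$mcmc
  mcmc$seed <- cfg$seed
  fits <- fit_all_locations(ds, spec, glm_family(cfg$family), cfg$prior,
                            mcmc, center_ids = cfg$center_ids)
  ok <- vapply(fits, inherits, logical(1), "chain_result")
  manifest$failed_locations <- names(fits)[!ok]
  summaries <- lapply(fits[ok], summarize_chains)
  sum_path <- file.path(cfg$out_dir, "posterior_summary.csv")
  write_posterior_summary(summaries, sum_path)
  manifest$artifacts$posterior_summary <- sum_path
  diag_path <- file.path(cfg$out_dir, "diagnostics.csv")
  diags <- do.call(rbind, lapply(names(summaries), function(id) {
    cbind(location_id = id, summaries[[id]][c("parameter", "rhat", "ess")],
          accept_phi = mean(fits[[id]]$acceptance$phi),
          accept_theta = mean(fits[[id]]$acceptance$theta))
  }))
  write.csv(diags, diag_path, row.names = FALSE, quote = FALSE)
  manifest$artifacts$diagnostics <- diag_path
  manifest$timings$fit <- as.numeric(Sys.time() - t2, units = "secs")

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Reads the artifacts recorded in a manifest and produces a compact report:
#' per-location coefficient medians and credible intervals, the elpd curve
#' and selected bandwidth if cross-validation ran, and convergence flags for
#' any location-parameter with split-Rhat above 1.05.
#'
#' @param manifest A manifest as returned by [run_pipeline()], or the path
#'   of a `manifest.json`.
#' @return List with `summary` (data frame), `elpd_curve` (or `NULL`),
#'   `selected_bandwidth`, and `flagged` (data frame of high-Rhat rows).
#' @export
summarize_run <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  if (is.null(manifest$artifacts) ||
      is.null(manifest$artifacts$posterior_summary)) {
    stop("manifest records no posterior summary artifact", call. = FALSE)
  }
  p <- manifest$artifacts$posterior_summary
  if (!file.exists(p)) stop("missing artifact: ", p, call. = FALSE)
  summary <- read.csv(p, stringsAsFactors = FALSE)
  curve <- NULL
  if (!is.null(manifest$artifacts$elpd_curve)) {
    if (!file.exists(manifest$artifacts$elpd_curve)) {
      stop("missing artifact: ", manifest$artifacts$elpd_curve, call. = FALSE)
    }
    curve <- read.csv(manifest$artifacts$elpd_curve, stringsAsFactors = FALSE)
  }
  flagged <- data.frame()
  if (!is.null(manifest$artifacts$diagnostics) &&
      file.exists(manifest$artifacts$diagnostics)) {
    diags <- read.csv(manifest$artifacts$diagnostics, stringsAsFactors = FALSE)
    flagged <- diags[!is.na(diags$rhat) & diags$rhat > 1.05, ]
  }
  list(summary = summary, elpd_curve = curve,
       selected_bandwidth = manifest$selected_bandwidth, flagged = flagged)
}
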