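#' Configuration for an end-to-end analysis run
#'
#' Exactly one of `preset` (synthetic run) or `spectra_paths` (files on disk,
#' read with [read_spectrum_xy()]) must be given.
#'
#' @param preset Synthetic preset name for [llps_sim_params()], or `NULL`.
#' @param spectra_paths Character vector of spectrum file paths (each with an
#'   accompanying `.meta` sidecar), or `NULL`.
#' @param calibration A [calibration_model()].
#' @param V_O Observed volume (microlitres).
#' @param Y_mM Additive concentration (mM).
#' @param snr Synthetic signal-to-noise ratio.
#' @param seed Integer seed controlling all randomness of the run.
#' @param n_points Synthetic axis size.
#' @param probe_center_ppm,probe_halfwidth_ppm Probe fitting window.
#' @param out_dir Output directory for CSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @param ... Overrides forwarded to [llps_sim_params()] for preset runs.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = NULL, spectra_paths = NULL,
                       calibration = calibration_model(),
                       V_O = 236.8, Y_mM = 20, snr = 100, seed = 1,
                       n_points = 32768,
                       probe_center_ppm = -77, probe_halfwidth_ppm = 1.5,
                       out_dir = NULL, ...) {
  if (is.null(preset) == is.null(spectra_paths)) {
    stop("exactly one of `preset` or `spectra_paths` must be set", call. = FALSE)
  }
  structure(
    list(preset = preset, spectra_paths = spectra_paths,
         calibration = calibration, V_O = V_O, Y_mM = Y_mM,
         snr = snr, seed = seed, n_points = n_points,
         probe_center_ppm = probe_center_ppm,
         probe_halfwidth_ppm = probe_halfwidth_ppm,
         out_dir = out_dir, sim_overrides = list(...)),
    class = "run_config"
  )
}

# deconvolve a time series of spectra: model selection, fitting with warm
# starts from the previous time point, phase labelling
deconvolve_series <- function(spectra, config, dT_C) {
  cal <- config$calibration
  prev <- NULL
  purrr::map(seq_along(spectra), function(i) {
    win <- spectrum_window(spectra[[i]], config$probe_center_ppm,
                          config$probe_halfwidth_ppm)
    nc <- select_n_components(win)
    seeds <- if (!is.null(prev) && prev$n_components == nc) {
      list(centers = prev$peaks$center_ppm, fwhm_Hz = prev$peaks$fwhm_Hz,
           areas = prev$peaks$area, baseline = prev$baseline)
    }
    seeds_ok <- !is.null(seeds) &&
      all(seeds$centers >= min(win$ppm)) && all(seeds$centers <= max(win$ppm))
    fit <- fit_lorentzians(win, nc, seeds = if (seeds_ok) seeds)
    if (nc == 2) {
      fit <- assign_phases(fit, cal, dT_C = dT_C[i], Y_mM = config$Y_mM)
    }
    prev <<- fit
    fit
  })
}

#' Run the bulk-detection kinetics pipeline
#'
#' Deconvolve each spectrum of a kinetic series, quantify phase
#' concentrations, volumes and masses, audit mass conservation, and extract
#' kinetic features (crossover, lag, growth exponent).
#'
#' @param config A [run_config()].
#' @return A list of class `bulk_run`: `trajectory` (tibble), `kinetics`
#'   (one-row tibble), `audit` (conservation report), `truth` (simulated
#'   ground-truth trajectory, preset runs only), `config`.
#' @export
run_bulk_kinetics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(config$preset)) {
    params <- do.call(llps_sim_params, c(list(preset = config$preset,
                                              V_O = config$V_O),
                                         config$sim_overrides))
    truth <- simulate_phase_trajectory(params)
    spectra <- render_spectrum_series(
      truth, config$calibration,
      noise = noise_model(snr = config$snr, seed = config$seed),
      Y_mM = config$Y_mM, n_points = config$n_points
    )
    dT_C <- rep(params$temperature_C - 25, length(spectra))
    expected_total <- params$M_total_mg
  } else {
    spectra <- purrr::map(config$spectra_paths, function(p) {
      read_spectrum_xy(p, sidecar = paste0(p, ".meta"))
    })
    dT_C <- vapply(spectra, function(s) {
      tc <- spectrum_meta(s)$temperature_C
      if (is.na(tc)) 0 else tc - 25
    }, numeric(1))
    expected_total <- NA_real_
  }
  times <- vapply(spectra, function(s) spectrum_meta(s)$time_min, numeric(1))
  if (anyNA(times)) times <- seq_along(spectra)
  fits <- deconvolve_series(spectra, config, dT_C)
  trajectory <- build_phase_trajectories(fits, times, config$calibration,
                                         V_O = config$V_O, dT_C = dT_C,
                                         Y_mM = config$Y_mM)
  audit <- if (!is.na(expected_total)) {
    check_mass_conservation(trajectory, expected_total)
  }
  cross <- try(find_crossover(trajectory), silent = TRUE)
  if (inherits(cross, "try-error")) {
    cross <- tibble::tibble(crossover_min = NA_real_,
                            crossover_volume_min = NA_real_,
                            discordant = FALSE, found = FALSE)
  }
  lag <- estimate_lag(trajectory)
  dense <- trajectory[trajectory$phase == "dense", ]
  expo <- try(fit_growth_exponent(
    dense$time_min, dense$V_uL,
    window_min = c(5, if (nrow(cross) && cross$found) cross$crossover_min else Inf)
  ), silent = TRUE)
  kinetics <- tibble::tibble(
    crossover_min = cross$crossover_min,
    lag_min = lag$lag_min,
    growth_exponent = if (inherits(expo, "try-error")) NA_real_ else expo$exponent,
    exponent_ci_lo = if (inherits(expo, "try-error")) NA_real_ else expo$ci_lo,
    exponent_ci_hi = if (inherits(expo, "try-error")) NA_real_ else expo$ci_hi
  )
  out <- list(trajectory = trajectory, kinetics = kinetics, audit = audit,
              truth = truth, config = config)
  class(out) <- "bulk_run"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trajectory, file.path(config$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(kinetics),
                         file.path(config$out_dir, "kinetics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the spatially-selective settling pipeline
#'
#' Simulates (or consumes) a slice-resolved series, corrects gradient
#' nonlinearity against per-slice reference integrals, derives per-slice
#' phase fractions, locates the dense/lean boundary at each time, and fits
#' the two settling regimes.
#'
#' @param config A [run_config()] (preset runs only; the `"40C"` preset with
#'   an extended time base is the physically meaningful choice).
#' @param settling A [settling_sim_params()].
#' @param times_min Slice sampling times.
#' @param geometry A [compute_slice_geometry()].
#' @param sensitivity Optional per-slice sensitivity profile applied during
#'   simulation (the correction step must undo it).
#' @return A list of class `spatial_run`: `profile` (per-slice fractions over
#'   time), `boundary` (tibble time/boundary/censoring), `settling_fit`,
#'   `truth`, `config`.
#' @export
run_spatial <- function(config, settling = settling_sim_params(),
                        times_min = seq(150, 2000, by = 100),
                        geometry = compute_slice_geometry(),
                        sensitivity = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$preset)) {
    stop("run_spatial currently requires a preset (synthetic) configuration",
         call. = FALSE)
  }
  params <- do.call(llps_sim_params,
                    c(list(preset = config$preset, V_O = config$V_O,
                           t_max_min = max(times_min)),
                      config$sim_overrides))
  truth_traj <- simulate_phase_trajectory(params)
  sim <- simulate_slice_series(
    truth_traj, settling, geometry, config$calibration,
    times_min = times_min,
    noise = noise_model(snr = config$snr, seed = config$seed),
    sensitivity = sensitivity,
    n_points = config$n_points
  )
  dT <- params$temperature_C - 25
  profiles <- purrr::map(seq_along(times_min), function(ti) {
    slices <- sim$spectra[[ti]]
    ref_int <- vapply(slices, function(s) {
      spectrum_integral(spectrum_window(s, -61, 1))
    }, numeric(1))
    corr <- correct_gradient_nonlinearity(slices, ref_int)
    per_slice_phase_fractions(
      corr$spectra, config$calibration, geometry,
      dT_C = dT, Y_mM = config$Y_mM,
      probe_center_ppm = config$probe_center_ppm,
      probe_halfwidth_ppm = config$probe_halfwidth_ppm,
      time_min = times_min[ti]
    )
  })
  profile <- dplyr::bind_rows(profiles)
  class(profile) <- c("slice_profile", class(profile))
  boundary <- purrr::map(profiles, function(p) {
    b <- locate_boundary(p)
    b$time_min <- p$time_min[1]
    b
  }) |> dplyr::bind_rows()
  ok <- boundary$censored == "none"
  sfit <- if (sum(ok) >= 2) {
    fit_settling_regimes(boundary$time_min[ok], boundary$boundary_mm[ok])
  }
  out <- list(profile = profile, boundary = boundary, settling_fit = sfit,
              truth = sim$truth, config = config)
  class(out) <- "spatial_run"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(profile, file.path(config$out_dir, "slice_fractions.csv"),
                     row.names = FALSE)
    utils::write.csv(boundary, file.path(config$out_dir, "boundary.csv"),
                     row.names = FALSE)
  }
  out
}

#' Render a human-readable run summary
#'
#' @param run A `bulk_run` or `spatial_run`.
#' @return A character vector of report lines (invisibly printed with `cat`).
#' @export
write_report <- function(run) {
  lines <- character()
  push <- function(...) lines <<- c(lines, sprintf(...))
  if (inherits(run, "bulk_run")) {
    push("Bulk kinetics run (seed %d)", run$config$seed)
    ends <- run$trajectory |>
      dplyr::filter(.data$time_min == max(.data$time_min))
    for (i in seq_len(nrow(ends))) {
      push("  %s phase end point: %.1f mg/mL, %.1f uL, %.2f mg",
           ends$phase[i], ends$C_mgml[i], ends$V_uL[i], ends$M_mg[i])
    }
    k <- run$kinetics
    push("  crossover: %s", if (is.na(k$crossover_min)) {
      "not reached within window"
    } else sprintf("%.1f min", k$crossover_min))
    push("  lag: %s", if (is.na(k$lag_min)) "undefined" else
      sprintf("%.1f min", k$lag_min))
    push("  growth exponent: %s", if (is.na(k$growth_exponent)) "n/a" else
      sprintf("%.3f [%.3f, %.3f]", k$growth_exponent,
              k$exponent_ci_lo, k$exponent_ci_hi))
    if (!is.null(run$audit)) {
      push("  mass conservation: max deviation %.2f%% (%d flagged)",
           100 * run$audit$max_deviation, run$audit$n_flagged)
    }
  } else if (inherits(run, "spatial_run")) {
    push("Spatially-selective run (seed %d)", run$config$seed)
    if (!is.null(run$settling_fit)) {
      s <- run$settling_fit
      push("  settling: %.4g mm/hr then %.4g mm/hr, breakpoint %s min",
           s$rate_fast_mm_per_hr, s$rate_slow_mm_per_hr,
           format(s$breakpoint_min))
    } else {
      push("  settling: boundary never inside the observed window")
    }
  } else {
    stop("unknown run type", call. = FALSE)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
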