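#' Parameters for a synthetic phase-separation trajectory
#'
#' The generator implements the staged phenomenology of a
#' temperature-jump-triggered liquid-liquid phase separation: a highly
#' concentrated dense species emerges (after an optional lag), its
#' concentration falls while its volume grows, a crossover is reached where
#' dense concentration is minimal and volume maximal, and the dense phase
#' then compacts (concentration rises, volume shrinks). In the arrested mode
#' the dense network cannot coalesce: volume freezes at its maximum and no
#' settling ever occurs.
#'
#' Dense concentration follows a two-exponential relaxation
#' `C_d(s) = C_min + (C_init - C_min) e^(-s/tau1) + (C_final - C_min)(1 - e^(-s/tau2))`
#' with `s = max(t - lag, 0)` and `tau1 < tau2`, whose analytic minimum
#' defines the crossover. Dense volume rises as a saturating exponential to
#' its peak at the crossover, then relaxes toward the volume implied by the
#' target final concentrations. Lean concentration is derived from exact
#' mass conservation, `C_l = (M_total - C_d V_d) / (V_O - V_d)`.
#'
#' Presets `"40C"`, `"45C"` and `"50C-arrested"` differ only in kinetic
#' parameters and final dense concentration; they qualitatively reproduce
#' the experimental orderings (dense final concentration increases, dense
#' final volume decreases, with jump temperature; the 40 degree transition
#' has a pronounced lag and a crossover near the end of a 120 min window;
#' the 50 degree transition arrests).
#'
#' @param preset One of `"40C"`, `"45C"`, `"50C-arrested"`, or `NULL` to use
#'   the explicit arguments.
#' @param total_concentration Total protein concentration (mg/mL).
#' @param V_O Observed volume (microlitres).
#' @param temperature_C Jump target temperature.
#' @param lag_min Lag before dense-phase growth (min).
#' @param tau1_min,tau2_min Fast and slow concentration time constants (min),
#'   `tau1 < tau2`.
#' @param growth_tau_min Volume growth time constant (min).
#' @param shrink_tau_min Post-crossover volume compaction time constant (min).
#' @param C_dense_initial,C_dense_min,C_dense_final Dense-phase concentration
#'   scale: initial value, two-exponential floor, and final target (mg/mL).
#' @param C_lean_final Target final lean concentration (mg/mL); sets the
#'   asymptotic dense volume through mass conservation.
#' @param peak_volume_ratio Peak dense volume as a multiple of the asymptotic
#'   dense volume.
#' @param arrested Freeze the dense volume at its maximum (no settling).
#' @param t_max_min,dt_min Time grid (min).
#' @return An `llps_sim_params` list, with the analytic `crossover_min` and
#'   derived volumes attached.
#' @export
llps_sim_params <- function(preset = NULL,
                            total_concentration = 200, V_O = 236.8,
                            temperature_C = 45,
                            lag_min = 2, tau1_min = 11, tau2_min = 45,
                            growth_tau_min = 18, shrink_tau_min = 45,
                            C_dense_initial = 480, C_dense_min = 300,
                            C_dense_final = 360, C_lean_final = 80,
                            peak_volume_ratio = 1.15,
                            arrested = FALSE,
                            t_max_min = 120, dt_min = 0.5) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("40C", "45C", "50C-arrested"))
    ov <- switch(preset,
      "40C" = list(temperature_C = 40, lag_min = 15, tau1_min = 30,
                   tau2_min = 150, growth_tau_min = 40, shrink_tau_min = 150,
                   C_dense_final = 340),
      "45C" = list(temperature_C = 45),
      "50C-arrested" = list(temperature_C = 50, lag_min = 0, tau1_min = 5,
                            tau2_min = 25, growth_tau_min = 8,
                            shrink_tau_min = 25, C_dense_initial = 500,
                            C_dense_min = 310, C_dense_final = 420,
                            peak_volume_ratio = 1.1, arrested = TRUE)
    )
    for (nm in names(ov)) assign(nm, ov[[nm]])
  }
  stopifnot(tau1_min < tau2_min, dt_min > 0,
            C_dense_initial > 0, C_dense_min > 0, C_dense_final > 0,
            C_dense_final > C_lean_final, C_dense_min >= C_lean_final)
  # analytic crossover: minimum of the two-exponential concentration
  a <- C_dense_initial - C_dense_min
  b <- C_dense_final - C_dense_min
  s_star <- log((a / tau1_min) * (tau2_min / b)) / (1 / tau1_min - 1 / tau2_min)
  M_total <- total_concentration * V_O / 1000   # mg
  V_final <- V_O * (total_concentration - C_lean_final) /
    (C_dense_final - C_lean_final)
  V_peak <- peak_volume_ratio * V_final
  p <- list(
    preset = preset, total_concentration = total_concentration, V_O = V_O,
    temperature_C = temperature_C, lag_min = lag_min,
    tau1_min = tau1_min, tau2_min = tau2_min,
    growth_tau_min = growth_tau_min, shrink_tau_min = shrink_tau_min,
    C_dense_initial = C_dense_initial, C_dense_min = C_dense_min,
    C_dense_final = C_dense_final, C_lean_final = C_lean_final,
    arrested = arrested, t_max_min = t_max_min, dt_min = dt_min,
    crossover_min = lag_min + s_star, M_total_mg = M_total,
    V_final_uL = V_final, V_peak_uL = V_peak
  )
  # reject parameter sets that would drive the lean concentration negative
  C_at <- function(s) C_dense_min + a * exp(-s / tau1_min) + b * (1 - exp(-s / tau2_min))
  if (C_at(s_star) * V_peak / 1000 > M_total) {
    stop("invalid parameters: dense phase would hold more than the total mass ",
         "(lean concentration would go negative)", call. = FALSE)
  }
  class(p) <- "llps_sim_params"
  p
}

#' Generate a ground-truth phase trajectory
#'
#' Evaluates the staged model of [llps_sim_params()] on its time grid. Mass
#' is conserved exactly at every time point by construction.
#'
#' @param params An [llps_sim_params()].
#' @return A `phase_trajectory` tibble (`time_min`, `phase`, `C_mgml`,
#'   `V_uL`, `M_mg`) with the parameters and analytic crossover attached as
#'   attributes.
#' @export
simulate_phase_trajectory <- function(params) {
  stopifnot(inherits(params, "llps_sim_params"))
  t <- seq(0, params$t_max_min, by = params$dt_min)
  s <- pmax(t - params$lag_min, 0)
  a <- params$C_dense_initial - params$C_dense_min
  b <- params$C_dense_final - params$C_dense_min
  C_d <- params$C_dense_min + a * exp(-s / params$tau1_min) +
    b * (1 - exp(-s / params$tau2_min))
  s_star <- params$crossover_min - params$lag_min
  rise <- (1 - exp(-s / params$growth_tau_min)) /
    (1 - exp(-s_star / params$growth_tau_min))
  V_d <- ifelse(
    s <= s_star,
    params$V_peak_uL * rise,
    if (params$arrested) params$V_peak_uL else NA_real_
  )
  post <- s > s_star
  if (!params$arrested && any(post)) {
    V_d[post] <- params$V_final_uL +
      (params$V_peak_uL - params$V_final_uL) *
        exp(-(s[post] - s_star) / params$shrink_tau_min)
  }
  V_d[t <= params$lag_min] <- 0
  C_l <- (params$M_total_mg - C_d * V_d / 1000) / ((params$V_O - V_d) / 1000)
  out <- dplyr::bind_rows(
    tibble::tibble(time_min = t, phase = "lean", C_mgml = C_l,
                   V_uL = params$V_O - V_d),
    tibble::tibble(time_min = t, phase = "dense", C_mgml = C_d, V_uL = V_d)
  ) |>
    dplyr::mutate(M_mg = .data$C_mgml * .data$V_uL / 1000) |>
    dplyr::arrange(.data$time_min, .data$phase)
  attr(out, "params") <- params
  class(out) <- c("phase_trajectory", class(out))
  out
}

#' Frequency-domain noise and inhomogeneity model
#'
#' @param snr Tallest-peak amplitude over noise standard deviation; `Inf`
#'   for noiseless spectra.
#' @param seed Integer RNG seed.
#' @param onset_min Layer-separation onset (NA = never): after this time the
#'   reference and probe lines are broadened by the inhomogeneity term.
#' @param broadening_amp_Hz Asymptotic extra width after onset (Hz).
#' @param broadening_tau_min Time constant of the broadening ramp (min).
#' @return A `noise_model` list with an `extra_width_Hz(t)` function.
#' @export
noise_model <- function(snr = 100, seed = 1, onset_min = NA,
                        broadening_amp_Hz = 6, broadening_tau_min = 60) {
  stopifnot(snr > 0)
  structure(
    list(
      snr = snr, seed = seed, onset_min = onset_min,
      extra_width_Hz = function(t) {
        if (is.na(onset_min) || t < onset_min) 0
        else broadening_amp_Hz * (1 - exp(-(t - onset_min) / broadening_tau_min))
      }
    ),
    class = "noise_model"
  )
}

interp_schedule <- function(width, t, t_range) {
  if (length(width) == 1) return(rep(width, length(t)))
  width[1] + (width[2] - width[1]) * (t - t_range[1]) / diff(t_range)
}

#' Render a spectral time series from a phase trajectory
#'
#' Per time point the probe region holds a lean Lorentzian (centre from the
#' calibration at the lean concentration, area proportional to lean volume)
#' and a broader dense Lorentzian, plus a concentration-insensitive
#' reference line. After the layer-separation onset of the noise model, all
#' lines acquire the inhomogeneity broadening. Gaussian noise is added at
#' the stated SNR under the model's seed.
#'
#' @param trajectory A `phase_trajectory` from [simulate_phase_trajectory()].
#' @param calibration A [calibration_model()].
#' @param noise A [noise_model()].
#' @param lean_fwhm_Hz,dense_fwhm_Hz Probe linewidths; length 1 (constant) or
#'   2 (linear schedule over the time span).
#' @param dT_C Temperature offset from the calibration reference, scalar or
#'   per-time.
#' @param Y_mM Additive concentration (mM).
#' @param tft_center_ppm,tft_fwhm_Hz,tft_area Reference line parameters.
#' @param ppm_range,n_points Spectral axis.
#' @param freq_MHz Spectrometer frequency.
#' @return A list of [nmr_spectrum()] (one per time point, `time_min` in the
#'   metadata), with the per-time ground truth tibble attached as attribute
#'   `truth`.
#' @export
render_spectrum_series <- function(trajectory, calibration, noise = noise_model(),
                                   lean_fwhm_Hz = 15, dense_fwhm_Hz = 80,
                                   dT_C = NULL, Y_mM = 20,
                                   tft_center_ppm = -61, tft_fwhm_Hz = 3,
                                   tft_area = 0.5,
                                   ppm_range = c(-85, -55), n_points = 32768,
                                   freq_MHz = 470) {
  params <- attr(trajectory, "params")
  if (is.null(dT_C)) {
    dT_C <- if (!is.null(params)) params$temperature_C - 25 else 0
  }
  times <- sort(unique(trajectory$time_min))
  dT_C <- rep_len(dT_C, length(times))
  lean_w <- interp_schedule(lean_fwhm_Hz, times, range(times))
  dense_w <- interp_schedule(dense_fwhm_Hz, times, range(times))
  x <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  V_O <- if (!is.null(params)) params$V_O else {
    sum(trajectory$V_uL[trajectory$time_min == times[1]])
  }
  set.seed(noise$seed)
  truth <- list()
  spectra <- purrr::map(seq_along(times), function(i) {
    rows <- trajectory[trajectory$time_min == times[i], ]
    lean <- rows[rows$phase == "lean", ]
    dense <- rows[rows$phase == "dense", ]
    extra <- noise$extra_width_Hz(times[i])
    d_lean <- predict_shift(calibration, lean$C_mgml, dT_C[i], Y_mM)
    d_dense <- if (nrow(dense)) {
      predict_shift(calibration, dense$C_mgml, dT_C[i], Y_mM)
    } else NA_real_
    y_probe <- lorentzian_profile(x, d_lean, lean_w[i] + extra,
                                  lean$V_uL / V_O, freq_MHz)
    if (nrow(dense) && dense$V_uL > 0) {
      y_probe <- y_probe + lorentzian_profile(x, d_dense, dense_w[i] + extra,
                                              dense$V_uL / V_O, freq_MHz)
    }
    y <- y_probe + lorentzian_profile(x, tft_center_ppm, tft_fwhm_Hz + extra,
                                      tft_area, freq_MHz)
    if (is.finite(noise$snr)) {
      # SNR is defined on the tallest probe peak -- the signal that is
      # deconvoluted -- not on the (much taller, narrow) reference line
      y <- y + stats::rnorm(n_points, 0, max(y_probe) / noise$snr)
    }
    truth[[i]] <<- tibble::tibble(
      time_min = times[i],
      lean_center_ppm = d_lean, dense_center_ppm = d_dense,
      lean_area = lean$V_uL / V_O,
      dense_area = if (nrow(dense)) dense$V_uL / V_O else 0,
      extra_width_Hz = extra
    )
    nmr_spectrum(x, y, acquisition_meta(
      spectrometer_freq_19F = freq_MHz, time_min = times[i],
      temperature_C = if (!is.null(params)) params$temperature_C else NA
    ))
  })
  attr(spectra, "truth") <- dplyr::bind_rows(truth)
  spectra
}

#' Parameters for the layer-settling simulation
#'
#' @param onset_min Layer-separation onset (min).
#' @param rate_fast_mm_per_hr,rate_slow_mm_per_hr Boundary sinking rates in
#'   the fast and slow regimes.
#' @param breakpoint_min Time of the regime change.
#' @param start_mm Boundary height at onset (mm, gradient-coil frame;
#'   positive is up).
#' @param trapped_lean_frac_initial Lean volume fraction initially trapped in
#'   the dense layer.
#' @param trapped_decay_tau_min Decay time of the trapped lean fraction.
#' @return A `settling_sim_params` list with a `boundary_mm(t)` function.
#' @export
settling_sim_params <- function(onset_min = 140,
                                rate_fast_mm_per_hr = 0.154,
                                rate_slow_mm_per_hr = 0.004,
                                breakpoint_min = 1100,
                                start_mm = 6.0,
                                trapped_lean_frac_initial = 0.2,
                                trapped_decay_tau_min = 500) {
  stopifnot(rate_fast_mm_per_hr >= 0, rate_slow_mm_per_hr >= 0,
            breakpoint_min > onset_min)
  z_break <- start_mm - rate_fast_mm_per_hr * (breakpoint_min - onset_min) / 60
  p <- list(
    onset_min = onset_min,
    rate_fast_mm_per_hr = rate_fast_mm_per_hr,
    rate_slow_mm_per_hr = rate_slow_mm_per_hr,
    breakpoint_min = breakpoint_min, start_mm = start_mm,
    trapped_lean_frac_initial = trapped_lean_frac_initial,
    trapped_decay_tau_min = trapped_decay_tau_min,
    boundary_mm = function(t) {
      ifelse(t < onset_min, NA_real_,
        ifelse(t <= breakpoint_min,
          start_mm - rate_fast_mm_per_hr * (t - onset_min) / 60,
          z_break - rate_slow_mm_per_hr * (t - breakpoint_min) / 60))
    }
  )
  class(p) <- "settling_sim_params"
  p
}

#' Simulate a spatially-selective slice series
#'
#' Before the settling onset every slice carries the bulk phase mixture of
#' the trajectory. After onset a lean/dense boundary sinks through the
#' observed window at the two configured regime rates; slices above the
#' boundary are lean, slices below are dense with a trapped lean fraction
#' that decays exponentially; the slice containing the boundary is split by
#' geometric overlap. Per-slice spectra are rendered as in
#' [render_spectrum_series()], optionally modulated by a synthetic per-slice
#' sensitivity profile (emulating gradient nonlinearity).
#'
#' @param trajectory A `phase_trajectory` spanning the requested times.
#' @param settling A [settling_sim_params()].
#' @param geometry A [compute_slice_geometry()].
#' @param calibration A [calibration_model()].
#' @param times_min Times at which slice sets are generated.
#' @param noise A [noise_model()].
#' @param sensitivity Per-slice sensitivity factors (default uniform).
#' @param ... Further rendering arguments passed to the per-slice renderer
#'   (`lean_fwhm_Hz`, `dense_fwhm_Hz`, `ppm_range`, `n_points`, ...).
#' @return A list with `spectra` (list over times of lists over slices),
#'   `truth` (tibble: `time_min`, `slice`, `lean_frac`, `dense_frac`,
#'   `boundary_mm`), and `geometry`.
#' @export
simulate_slice_series <- function(trajectory, settling, geometry, calibration,
                                  times_min, noise = noise_model(),
                                  sensitivity = NULL, ...) {
  params <- attr(trajectory, "params")
  if (max(times_min) > max(trajectory$time_min)) {
    stop("trajectory does not span the requested slice times", call. = FALSE)
  }
  if (is.null(sensitivity)) sensitivity <- rep(1, nrow(geometry))
  stopifnot(length(sensitivity) == nrow(geometry))
  dots <- list(...)
  truth <- list()
  all_spectra <- purrr::map(seq_along(times_min), function(ti) {
    t_i <- times_min[ti]
    idx <- which.min(abs(sort(unique(trajectory$time_min)) - t_i))
    t_snap <- sort(unique(trajectory$time_min))[idx]
    rows <- trajectory[trajectory$time_min == t_snap, ]
    C_l <- rows$C_mgml[rows$phase == "lean"]
    C_d <- rows$C_mgml[rows$phase == "dense"]
    V_d <- rows$V_uL[rows$phase == "dense"]
    V_O <- sum(rows$V_uL)
    z_b <- settling$boundary_mm(t_i)
    pre_onset <- t_i < settling$onset_min
    frac <- vapply(seq_len(nrow(geometry)), function(k) {
      if (pre_onset) return(if (length(V_d)) V_d / V_O else 0)
      top <- geometry$center_mm[k] + geometry$width_mm[k] / 2
      bot <- geometry$center_mm[k] - geometry$width_mm[k] / 2
      above <- min(max((top - z_b) / (top - bot), 0), 1)
      f_tr <- settling$trapped_lean_frac_initial *
        exp(-(t_i - settling$onset_min) / settling$trapped_decay_tau_min)
      dense_frac <- (1 - above) * (1 - f_tr)
      dense_frac
    }, numeric(1))
    truth[[ti]] <<- tibble::tibble(
      time_min = t_i, slice = geometry$slice,
      lean_frac = 1 - frac, dense_frac = frac,
      boundary_mm = z_b
    )
    purrr::map(seq_len(nrow(geometry)), function(k) {
      slice_traj <- dplyr::bind_rows(
        tibble::tibble(time_min = t_i, phase = "lean",
                       C_mgml = C_l, V_uL = (1 - frac[k]) * geometry$volume_uL[k]),
        tibble::tibble(time_min = t_i, phase = "dense",
                       C_mgml = if (length(C_d)) C_d else 0,
                       V_uL = frac[k] * geometry$volume_uL[k])
      ) |> dplyr::mutate(M_mg = .data$C_mgml * .data$V_uL / 1000)
      class(slice_traj) <- c("phase_trajectory", class(slice_traj))
      sn <- noise_model(
        snr = noise$snr,
        seed = noise$seed + 1000L * ti + k,
        onset_min = noise$onset_min
      )
      args <- c(list(trajectory = slice_traj, calibration = calibration,
                     noise = sn,
                     dT_C = if (!is.null(params)) params$temperature_C - 25 else 0),
                dots)
      s <- do.call(render_spectrum_series, args)[[1]]
      m <- spectrum_meta(s)
      m$slice_index <- geometry$slice[k]
      m$time_min <- t_i
      nmr_spectrum(s$ppm, s$intensity * sensitivity[k], m)
    })
  })
  list(spectra = all_spectra, truth = dplyr::bind_rows(truth),
       geometry = geometry)
}

#' Simulate a relaxation or diffusion decay series
#'
#' Generates inversion-recovery (8 points), CPMG (16 points) or
#' Stejskal-Tanner pulsed-field-gradient (16 gradient increments) data with
#' seeded Gaussian noise.
#'
#' @param kind `"inversion_recovery"`, `"cpmg"` or `"pfg"`.
#' @param true_parameter R1 (1/s), R2 (1/s) or D (m^2/s).
#' @param I0 Signal amplitude.
#' @param n_points Number of samples (defaults: 8 / 16 / 16).
#' @param noise_frac Gaussian noise standard deviation as a fraction of `I0`.
#' @param seed RNG seed.
#' @param big_delta_s,little_delta_s Diffusion time and gradient pulse length
#'   for `kind = "pfg"` (defaults 150 ms and 1.5 ms).
#' @param g_max_T_per_m Maximum gradient strength for `kind = "pfg"`.
#' @return A [decay_series()].
#' @export
simulate_decay_series <- function(kind = c("inversion_recovery", "cpmg", "pfg"),
                                  true_parameter, I0 = 1, n_points = NULL,
                                  noise_frac = 0, seed = 1,
                                  big_delta_s = 0.15, little_delta_s = 0.0015,
                                  g_max_T_per_m = 0.5) {
  kind <- match.arg(kind)
  stopifnot(true_parameter > 0)
  if (is.null(n_points)) n_points <- if (kind == "inversion_recovery") 8 else 16
  set.seed(seed)
  if (kind == "inversion_recovery") {
    x <- seq(0.02, 5, length.out = n_points) / true_parameter
    y <- I0 * (1 - 2 * exp(-x * true_parameter))
  } else if (kind == "cpmg") {
    x <- seq(0.05, 3, length.out = n_points) / true_parameter
    y <- I0 * exp(-x * true_parameter)
  } else {
    x <- seq(g_max_T_per_m / n_points, g_max_T_per_m, length.out = n_points)
    gamma <- 2 * pi * GAMMA_19F_MHZ_PER_T * 1e6
    b <- gamma^2 * x^2 * little_delta_s^2 * (big_delta_s - little_delta_s / 3)
    y <- I0 * exp(-true_parameter * b)
  }
  if (noise_frac > 0) y <- y + stats::rnorm(n_points, 0, noise_frac * I0)
  decay_series(x, y, kind,
               big_delta_s = if (kind == "pfg") big_delta_s,
               little_delta_s = if (kind == "pfg") little_delta_s)
}
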