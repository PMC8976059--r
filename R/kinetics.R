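#' Assemble phase trajectories from a series of deconvolution results
#'
#' For each time point: phase concentrations by inverting the calibration at
#' that time's temperature offset, phase volumes from the deconvoluted area
#' split of the observed volume, and masses as concentration x volume.
#' Single-component time points are recorded as one phase occupying the full
#' observed volume, labelled by the calibrated concentration of the lone
#' peak.
#'
#' @param deconv_series A list of `deconvolution` objects (two-component fits
#'   must already be labelled by [assign_phases()]), in time order.
#' @param times_min Acquisition times (minutes), same length.
#' @param calibration A [calibration_model()].
#' @param V_O Observed volume (microlitres).
#' @param dT_C Temperature offset(s) from the reference; scalar or per-time.
#' @param Y_mM Additive concentration (mM).
#' @param phase_split_mgml Concentration separating lean-like from dense-like
#'   single components.
#' @return A `phase_trajectory` tibble in long format: `time_min`, `phase`,
#'   `C_mgml`, `C_lo`, `C_hi`, `V_uL`, `V_lo`, `V_hi`, `M_mg`, `M_lo`, `M_hi`.
#' @export
build_phase_trajectories <- function(deconv_series, times_min, calibration,
                                     V_O = 236.8, dT_C = 0, Y_mM = 0,
                                     phase_split_mgml = 250) {
  stopifnot(length(deconv_series) == length(times_min))
  dT_C <- rep_len(dT_C, length(times_min))
  rows <- purrr::map(seq_along(deconv_series), function(i) {
    fit <- deconv_series[[i]]
    pk <- fit$peaks
    if (fit$n_components == 2 && !"label" %in% names(pk)) {
      stop("two-component fit at t = ", times_min[i],
           " min has no phase labels; run assign_phases() first", call. = FALSE)
    }
    has_ci <- "ci_center_lo" %in% names(pk)
    d_se <- if (has_ci) (pk$ci_center_hi - pk$ci_center_lo) / 3.92 else 0
    a_se <- if (has_ci) (pk$ci_area_hi - pk$ci_area_lo) / 3.92 else 0
    conc <- shift_to_concentration(calibration, pk$center_ppm,
                                   dT_C = dT_C[i], Y_mM = Y_mM, delta_se = d_se)
    I_T <- sum(pk$area)
    I_T_se <- sqrt(sum(a_se^2))
    vol <- phase_volume(pk$area, I_T, V_O, I_P_se = a_se, I_T_se = I_T_se)
    mass <- phase_mass(conc$C_mgml, vol$V_uL,
                       C_se = (conc$C_hi - conc$C_lo) / 3.92,
                       V_se = (vol$V_hi - vol$V_lo) / 3.92)
    label <- if (fit$n_components == 2) {
      pk$label
    } else {
      if (conc$C_mgml[1] <= phase_split_mgml) "lean" else "dense"
    }
    tibble::tibble(
      time_min = times_min[i], phase = label,
      C_mgml = conc$C_mgml, C_lo = conc$C_lo, C_hi = conc$C_hi,
      V_uL = vol$V_uL, V_lo = vol$V_lo, V_hi = vol$V_hi,
      M_mg = mass$M_mg, M_lo = mass$M_lo, M_hi = mass$M_hi
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phase_trajectory", class(out))
  out
}

moving_average <- function(x, window = 5) {
  sm <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  ifelse(is.na(sm), x, sm)
}

#' Find the kinetic crossover point
#'
#' The crossover is the moment the emerging dense phase reaches its minimum
#' concentration and maximum volume, after which it compacts. Both series
#' are smoothed by a centred moving average; the primary estimate is the
#' concentration minimum, cross-checked against the volume maximum. If the
#' two disagree by more than `max_discord` samples both are reported with a
#' discordance flag.
#'
#' @param trajectory A `phase_trajectory` (dense rows are used); >= 7 points.
#' @param window Smoothing window in samples (default 5).
#' @param max_discord Allowed disagreement in samples (default 3).
#' @return A one-row tibble: `crossover_min`, `crossover_volume_min`,
#'   `discordant`, `found`. `found = FALSE` for monotone series (crossover
#'   not reached within the observation window).
#' @export
find_crossover <- function(trajectory, window = 5, max_discord = 3) {
  d <- trajectory[trajectory$phase == "dense", ]
  d <- d[order(d$time_min), ]
  if (nrow(d) < 7) stop("need at least 7 dense-phase time points", call. = FALSE)
  cs <- moving_average(d$C_mgml, window)
  vs <- moving_average(d$V_uL, window)
  i_c <- which.min(cs)
  i_v <- which.max(vs)
  interior <- function(i) i > 1 && i < nrow(d)
  if (!interior(i_c)) {
    return(tibble::tibble(crossover_min = NA_real_, crossover_volume_min = NA_real_,
                          discordant = FALSE, found = FALSE))
  }
  tibble::tibble(
    crossover_min = d$time_min[i_c],
    crossover_volume_min = d$time_min[i_v],
    discordant = abs(i_c - i_v) > max_discord,
    found = TRUE
  )
}

#' Estimate the lag time before dense-phase growth
#'
#' Lag is the first time the dense volume exceeds a threshold fraction of its
#' maximum over the observation window.
#'
#' @param trajectory A `phase_trajectory`; dense rows are used. Times where
#'   the dense phase is absent count as zero volume.
#' @param threshold_frac Fraction of the maximum dense volume (default 0.05).
#' @param trigger_min Time origin (default 0).
#' @return A one-row tibble: `lag_min`, `defined`.
#' @export
estimate_lag <- function(trajectory, threshold_frac = 0.05, trigger_min = 0) {
  times <- sort(unique(trajectory$time_min))
  d <- trajectory[trajectory$phase == "dense", c("time_min", "V_uL")]
  v <- d$V_uL[match(times, d$time_min)]
  v[is.na(v)] <- 0
  vmax <- max(v)
  if (vmax <= 0) {
    return(tibble::tibble(lag_min = NA_real_, defined = FALSE))
  }
  i <- which(v > threshold_frac * vmax)[1]
  if (is.na(i)) {
    return(tibble::tibble(lag_min = NA_real_, defined = FALSE))
  }
  tibble::tibble(lag_min = times[i] - trigger_min, defined = TRUE)
}

#' Fit a power-law growth exponent
#'
#' Ordinary least squares of `log(value)` on `log(time - trigger)` over a
#' user-selected window; dense-phase volume growing as `t^(1/3)` returns an
#' exponent of 1/3. Nonpositive values are excluded and counted.
#'
#' @param time_min Times (minutes).
#' @param value Dense-phase volume or mass at each time.
#' @param window_min Length-2 window `c(from, to)` in minutes; the default
#'   starts at 5 min to skip the nucleation transient.
#' @param trigger_min Time origin subtracted before taking logs.
#' @return A one-row tibble: `exponent`, `ci_lo`, `ci_hi`, `n_used`,
#'   `n_excluded`.
#' @export
fit_growth_exponent <- function(time_min, value, window_min = c(5, Inf),
                                trigger_min = 0) {
  t_rel <- time_min - trigger_min
  keep <- t_rel >= window_min[1] & t_rel <= window_min[2] & t_rel > 0
  n_excluded <- sum(keep & value <= 0)
  keep <- keep & value > 0
  if (sum(keep) < 6) stop("need at least 6 positive points in the window", call. = FALSE)
  f <- stats::lm(log(value[keep]) ~ log(t_rel[keep]))
  # confint warns on numerically perfect fits (noiseless power laws)
  ci <- suppressWarnings(stats::confint(f, level = 0.95))
  tibble::tibble(
    exponent = stats::coef(f)[[2]],
    ci_lo = ci[2, 1], ci_hi = ci[2, 2],
    n_used = sum(keep), n_excluded = n_excluded
  )
}
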