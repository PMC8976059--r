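#' Slice geometry from gradient physics
#'
#' During a z-gradient of strength `G`, a selective pulse of bandwidth `bw`
#' excites a slice of width `bw / (gamma * G)`; a pulse offset `f` excites a
#' slice centred at `f / (gamma * G)`. Defaults reproduce the acquisition
#' geometry of a 42.4 G/cm gradient with a 16793 Hz selective pulse and 12
#' evenly spaced offsets spanning -93404 to +93404 Hz: twelve roughly 1 mm
#' slices centred at -5.5 to +5.5 mm from the gradient coil centre.
#'
#' Sign convention: positive centre = higher in the tube, so slice index 1
#' (most negative offset) is the bottom slice.
#'
#' @param gradient_G_per_cm Gradient strength in gauss/cm.
#' @param bandwidth_Hz Selective-pulse bandwidth in Hz.
#' @param offsets_Hz Pulse offsets in Hz (one per slice).
#' @param gamma_MHz_per_T Gyromagnetic ratio over 2 pi (MHz/T); 19F default.
#' @param total_volume_uL Observed volume distributed uniformly over slices.
#' @return A `slice_geometry` tibble with columns `slice`, `offset_Hz`,
#'   `center_mm`, `width_mm`, `volume_uL`.
#' @export
compute_slice_geometry <- function(gradient_G_per_cm = 42.4,
                                   bandwidth_Hz = 16793,
                                   offsets_Hz = seq(-93404, 93404, length.out = 12),
                                   gamma_MHz_per_T = GAMMA_19F_MHZ_PER_T,
                                   total_volume_uL = 130.1) {
  if (gradient_G_per_cm <= 0) stop("gradient must be > 0", call. = FALSE)
  G_T_per_m <- gradient_G_per_cm * 1e-4 / 1e-2          # G/cm -> T/m
  hz_per_m <- gamma_MHz_per_T * 1e6 * G_T_per_m
  width_mm <- bandwidth_Hz / hz_per_m * 1000
  centers_mm <- offsets_Hz / hz_per_m * 1000
  out <- tibble::tibble(
    slice = seq_along(offsets_Hz),
    offset_Hz = offsets_Hz,
    center_mm = centers_mm,
    width_mm = width_mm,
    volume_uL = total_volume_uL / length(offsets_Hz)
  )
  class(out) <- c("slice_geometry", class(out))
  out
}

#' Correct slice intensities for gradient nonlinearity
#'
#' Gradient-coil nonlinearity makes slice sensitivity uneven; the
#' concentration-insensitive reference signal (constant across the sample)
#' calibrates it out. Each slice's intensities are scaled by
#' `mean(reference) / reference[slice]`, so a homogeneous sample yields equal
#' probe integrals in every slice after correction. The correction is
#' idempotent: factors recomputed after applying it are all 1.
#'
#' @param slice_spectra A list of [nmr_spectrum()], one per slice.
#' @param reference_integrals Per-slice reference (e.g. TFT) integrals.
#' @return A list with `spectra` (corrected), `factors`, and `usable`
#'   (FALSE where the reference integral was not positive).
#' @export
correct_gradient_nonlinearity <- function(slice_spectra, reference_integrals) {
  stopifnot(length(slice_spectra) == length(reference_integrals))
  usable <- is.finite(reference_integrals) & reference_integrals > 0
  if (!any(usable)) stop("no usable slices: all reference integrals <= 0", call. = FALSE)
  factors <- rep(NA_real_, length(reference_integrals))
  factors[usable] <- mean(reference_integrals[usable]) / reference_integrals[usable]
  corrected <- purrr::map2(slice_spectra, factors, function(s, f) {
    if (is.na(f)) return(s)
    nmr_spectrum(s$ppm, s$intensity * f, spectrum_meta(s))
  })
  list(spectra = corrected, factors = factors, usable = usable)
}

#' Per-slice lean/dense volume fractions
#'
#' Deconvolutes each slice spectrum in the probe window; with two components
#' the area split gives the lean/dense percentages, with one component the
#' calibrated concentration of the single peak decides which phase occupies
#' 100% of the slice.
#'
#' @param slice_spectra A list of corrected [nmr_spectrum()], one per slice.
#' @param calibration A [calibration_model()].
#' @param geometry A [compute_slice_geometry()] result (defines slice order).
#' @param dT_C,Y_mM Conditions, passed to the calibration inversion.
#' @param probe_center_ppm,probe_halfwidth_ppm Probe-region fitting window.
#' @param time_min Optional acquisition time recorded in the output.
#' @return A `slice_profile` tibble: `time_min`, `slice`, `center_mm`,
#'   `lean_pct`, `dense_pct`, `n_components`, `usable`.
#' @export
per_slice_phase_fractions <- function(slice_spectra, calibration, geometry,
                                      dT_C = 0, Y_mM = 0,
                                      probe_center_ppm = -77,
                                      probe_halfwidth_ppm = 1.5,
                                      time_min = NA_real_) {
  stopifnot(length(slice_spectra) == nrow(geometry))
  rows <- purrr::map(seq_along(slice_spectra), function(i) {
    s <- slice_spectra[[i]]
    base <- tibble::tibble(time_min = time_min, slice = geometry$slice[i],
                           center_mm = geometry$center_mm[i],
                           lean_pct = NA_real_, dense_pct = NA_real_,
                           n_components = NA_integer_, usable = FALSE)
    if (is.null(s)) return(base)
    win <- try(spectrum_window(s, probe_center_ppm, probe_halfwidth_ppm), silent = TRUE)
    if (inherits(win, "try-error")) return(base)
    nc <- try(select_n_components(win), silent = TRUE)
    if (inherits(nc, "try-error")) return(base)
    if (nc == 2) {
      fit <- fit_lorentzians(win, 2)
      if (!fit$converged) return(base)
      fit <- assign_phases(fit, calibration, dT_C = dT_C, Y_mM = Y_mM)
      tot <- sum(fit$peaks$area)
      lean <- 100 * fit$peaks$area[fit$peaks$label == "lean"] / tot
      base$lean_pct <- lean
      base$dense_pct <- 100 - lean
    } else {
      fit <- fit_lorentzians(win, 1)
      if (!fit$converged) return(base)
      conc <- shift_to_concentration(calibration, fit$peaks$center_ppm,
                                     dT_C = dT_C, Y_mM = Y_mM)$C_mgml
      # label the lone component by whichever phase concentration is nearer:
      # below the midpoint of typical lean/dense levels counts as lean
      lean_like <- conc <= attr(calibration, "phase_split_mgml") %||% 250
      base$lean_pct <- if (lean_like) 100 else 0
      base$dense_pct <- 100 - base$lean_pct
    }
    base$n_components <- as.integer(nc)
    base$usable <- TRUE
    base
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("slice_profile", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate the dense/lean boundary from a slice profile
#'
#' The boundary is the height at which the dense fraction crosses 50%,
#' linearly interpolated between adjacent slice centres (slices ordered top
#' to bottom). If every slice is at least 50% dense the boundary lies above
#' the observed window (censored above); if none is, below it.
#'
#' @param profile A `slice_profile` for one time point (usable slices only
#'   are considered; needs >= 2).
#' @return A one-row tibble: `boundary_mm`, `censored`
#'   (`"none"`/`"above"`/`"below"`), `multimodal`.
#' @export
locate_boundary <- function(profile) {
  p <- profile[profile$usable & !is.na(profile$dense_pct), ]
  if (nrow(p) < 2) stop("need at least 2 usable slices", call. = FALSE)
  p <- p[order(p$center_mm, decreasing = TRUE), ]   # top first
  d <- p$dense_pct
  if (all(d >= 50)) {
    return(tibble::tibble(boundary_mm = NA_real_, censored = "above", multimodal = FALSE))
  }
  if (all(d < 50)) {
    return(tibble::tibble(boundary_mm = NA_real_, censored = "below", multimodal = FALSE))
  }
  crossings <- which(diff(d >= 50) != 0)
  multimodal <- length(crossings) > 1
  i <- crossings[1]   # topmost crossing
  frac <- (50 - d[i]) / (d[i + 1] - d[i])
  boundary <- p$center_mm[i] + frac * (p$center_mm[i + 1] - p$center_mm[i])
  tibble::tibble(boundary_mm = boundary, censored = "none", multimodal = multimodal)
}

#' Fit two-regime settling rates to a boundary trajectory
#'
#' Layer settling shows a fast initial regime and a much slower late one. A
#' two-segment piecewise-linear model is fitted by exhaustive search of the
#' breakpoint over interior sample times, minimizing total SSE of the two
#' independently fitted lines; slopes are reported in mm/hr as sinking rates
#' (positive = boundary moving down).
#'
#' @param times_min Sample times in minutes.
#' @param boundary_mm Boundary heights in mm (uncensored points only).
#' @param min_seg Minimum points per segment (default 3).
#' @return A `settling_fit` list: `rate_fast_mm_per_hr`, `rate_slow_mm_per_hr`,
#'   `breakpoint_min`, `sse`, `single_segment` flag, and the input data.
#' @export
fit_settling_regimes <- function(times_min, boundary_mm, min_seg = 3) {
  ok <- is.finite(times_min) & is.finite(boundary_mm)
  o <- order(times_min[ok])
  t <- times_min[ok][o]
  z <- boundary_mm[ok][o]
  n <- length(t)
  seg_fit <- function(tt, zz) {
    f <- stats::lm(zz ~ tt)
    list(slope = stats::coef(f)[[2]], sse = sum(stats::resid(f)^2))
  }
  if (n < 6) {
    f <- seg_fit(t, z)
    out <- list(rate_fast_mm_per_hr = -f$slope * 60,
                rate_slow_mm_per_hr = -f$slope * 60,
                breakpoint_min = NA_real_, sse = f$sse,
                single_segment = TRUE,
                data = tibble::tibble(time_min = t, boundary_mm = z))
    class(out) <- "settling_fit"
    return(out)
  }
  # O(n) exhaustive split search: per-prefix OLS slope and SSE from running
  # sums, SSE = Szz - Stz^2 / Stt with centred moments
  pref <- function(tt, zz) {
    k <- seq_along(tt)
    st <- cumsum(tt); sz <- cumsum(zz)
    stt <- cumsum(tt^2); szz <- cumsum(zz^2); stz <- cumsum(tt * zz)
    Stt <- stt - st^2 / k
    Szz <- szz - sz^2 / k
    Stz <- stz - st * sz / k
    slope <- ifelse(Stt > 0, Stz / Stt, 0)
    list(slope = slope, sse = pmax(Szz - ifelse(Stt > 0, Stz^2 / Stt, 0), 0))
  }
  fwd <- pref(t, z)
  rev_ <- pref(rev(t), rev(z))
  i_cand <- seq(min_seg, n - min_seg)
  sse_tot <- fwd$sse[i_cand] + rev_$sse[n - i_cand]
  best_i <- i_cand[which.min(sse_tot)]
  out <- list(rate_fast_mm_per_hr = -fwd$slope[best_i] * 60,
              rate_slow_mm_per_hr = -rev_$slope[n - best_i] * 60,
              breakpoint_min = t[best_i],
              sse = min(sse_tot), single_segment = FALSE,
              data = tibble::tibble(time_min = t, boundary_mm = z))
  class(out) <- "settling_fit"
  out
}

#' @export
print.settling_fit <- function(x, ...) {
  cat(sprintf(
    "<settling_fit: %.4g mm/hr then %.4g mm/hr, breakpoint %s min>\n",
    x$rate_fast_mm_per_hr, x$rate_slow_mm_per_hr,
    if (is.na(x$breakpoint_min)) "NA (single segment)" else format(x$breakpoint_min)
  ))
  invisible(x)
}

#' Detect the onset of macroscopic layer separation
#'
#' Layer separation degrades macroscopic field homogeneity, broadening the
#' external reference line. Onset is the first time the reference half-width
#' exceeds the baseline median (first `n_baseline` points) by more than
#' `threshold_frac`, sustained for at least `persistence` consecutive points.
#'
#' @param time_min Times in minutes.
#' @param halfwidth_Hz Reference signal half-width (Hz) at each time.
#' @param n_baseline Points defining the pre-onset baseline (default 10).
#' @param threshold_frac Fractional exceedance over baseline (default 0.2).
#' @param persistence Consecutive points required (default 3).
#' @return A one-row tibble: `onset_min` (NA when no onset — compatible with
#'   an arrested state), `baseline_Hz`, `detected`.
#' @export
detect_layer_onset <- function(time_min, halfwidth_Hz, n_baseline = 10,
                               threshold_frac = 0.2, persistence = 3) {
  if (length(time_min) < n_baseline) {
    stop("need at least ", n_baseline, " points to establish a baseline", call. = FALSE)
  }
  baseline <- stats::median(halfwidth_Hz[seq_len(n_baseline)])
  exceeds <- halfwidth_Hz > baseline * (1 + threshold_frac)
  run <- 0L
  onset <- NA_real_
  for (i in seq_along(exceeds)) {
    run <- if (exceeds[i]) run + 1L else 0L
    if (run >= persistence) {
      onset <- time_min[i - persistence + 1L]
      break
    }
  }
  tibble::tibble(onset_min = onset, baseline_Hz = baseline, detected = !is.na(onset))
}
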