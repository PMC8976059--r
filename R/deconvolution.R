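#' Area-parameterized Lorentzian lineshape
#'
#' `L(x) = (area / pi) * gamma / ((x - center)^2 + gamma^2)` with
#' `gamma = fwhm_Hz / (2 * freq_MHz)` the half-width at half-maximum in ppm.
#' The profile integrates to `area` over an infinite ppm axis; peak height is
#' `2 * area / (pi * fwhm_ppm)`.
#'
#' @param x Ppm axis.
#' @param center Peak centre (ppm).
#' @param fwhm_Hz Full width at half maximum (Hz), > 0.
#' @param area Integrated area (a.u.).
#' @param freq_MHz Spectrometer frequency (MHz).
#' @return Intensity vector.
#' @export
lorentzian_profile <- function(x, center, fwhm_Hz, area = 1, freq_MHz = 470) {
  if (fwhm_Hz <= 0) stop("`fwhm_Hz` must be > 0", call. = FALSE)
  gamma <- fwhm_Hz / (2 * freq_MHz)
  (area / pi) * gamma / ((x - center)^2 + gamma^2)
}

# model evaluation for a flat-baseline sum of Lorentzians;
# pars = c(centers, fwhms_Hz, areas, baseline)
multi_lorentz <- function(pars, x, n, freq_MHz) {
  y <- rep(pars[3 * n + 1], length(x))
  for (k in seq_len(n)) {
    gamma <- pars[n + k] / (2 * freq_MHz)
    y <- y + (pars[2 * n + k] / pi) * gamma / ((x - pars[k])^2 + gamma^2)
  }
  y
}

#' Deterministic initial parameter guesses for Lorentzian fitting
#'
#' For one component, seeds are the global maximum, the half-height crossing
#' width and the implied area. For two components, a quick single-peak fit is
#' subtracted and the second seed taken at the maximum of the smoothed
#' residual.
#'
#' @param spectrum An [nmr_spectrum()] covering the probe region.
#' @param n Number of components, 1 or 2.
#' @return A named list with `centers`, `fwhm_Hz`, `areas`, `baseline`.
#' @export
initial_guess <- function(spectrum, n = 1) {
  stopifnot(n %in% c(1, 2))
  x <- spectrum$ppm
  y <- spectrum$intensity
  freq <- spectrum_meta(spectrum)$spectrometer_freq_19F
  noise <- stats::mad(y)
  base <- stats::median(y)
  if (max(y) - base < 5 * max(noise, .Machine$double.eps)) {
    stop("no peak detected: spectrum maximum below 5x noise MAD", call. = FALSE)
  }
  seed1 <- peak_seed(x, y, base, freq)
  if (n == 1) {
    return(list(centers = seed1$center, fwhm_Hz = seed1$fwhm_Hz,
                areas = seed1$area, baseline = base))
  }
  fit1 <- try(fit_lorentzians(spectrum, n = 1, seeds = list(
    centers = seed1$center, fwhm_Hz = seed1$fwhm_Hz,
    areas = seed1$area, baseline = base
  )), silent = TRUE)
  if (inherits(fit1, "try-error")) {
    resid <- y - lorentzian_profile(x, seed1$center, seed1$fwhm_Hz, seed1$area, freq) - base
  } else {
    resid <- y - multi_lorentz(fit_params(fit1), x, 1, freq)
  }
  sm <- as.numeric(stats::filter(resid, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- 0
  seed2 <- peak_seed(x, sm + base, base, freq)
  list(centers = c(seed1$center, seed2$center),
       fwhm_Hz = c(seed1$fwhm_Hz, seed2$fwhm_Hz),
       areas = c(seed1$area * 0.7, max(seed2$area, 0.05 * seed1$area)),
       baseline = base)
}

# centre / half-height width / area seed for the tallest feature
peak_seed <- function(x, y, base, freq_MHz) {
  i <- which.max(y)
  height <- y[i] - base
  half <- base + height / 2
  left <- i
  while (left > 1 && y[left] > half) left <- left - 1
  right <- i
  while (right < length(y) && y[right] > half) right <- right + 1
  fwhm_ppm <- max(x[right] - x[left], abs(stats::median(diff(x))))
  fwhm_Hz <- max(fwhm_ppm * freq_MHz, 0.5)
  list(center = x[i], fwhm_Hz = fwhm_Hz,
       area = max(height * pi * fwhm_ppm / 2, .Machine$double.eps))
}

#' Fit a sum of Lorentzians plus a constant baseline
#'
#' Nonlinear least squares (Levenberg-Marquardt) of `n` area-parameterized
#' Lorentzians and a flat baseline against a spectrum. Bounds: FWHM in
#' `[0.1, 5000]` Hz, areas nonnegative, centres inside the ppm axis. On
#' failure the fit is retried from jittered seeds; persistent failure is
#' reported through `converged = FALSE`, never silently.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param n Number of components (1 or 2).
#' @param seeds Optional list as returned by [initial_guess()].
#' @param max_restarts Jittered restarts on non-convergence.
#' @return A `deconvolution` object; see [tidy.deconvolution()].
#' @export
fit_lorentzians <- function(spectrum, n = 1, seeds = NULL, max_restarts = 3) {
  stopifnot(n %in% c(1, 2))
  x <- spectrum$ppm
  y <- spectrum$intensity
  freq <- spectrum_meta(spectrum)$spectrometer_freq_19F
  if (is.null(seeds)) seeds <- initial_guess(spectrum, n)
  p0 <- c(seeds$centers, seeds$fwhm_Hz, seeds$areas, seeds$baseline)
  if (length(p0) != 3 * n + 1) stop("seeds do not match n components", call. = FALSE)
  if (any(seeds$centers < min(x)) || any(seeds$centers > max(x))) {
    stop("seed centres outside the ppm axis", call. = FALSE)
  }
  lower <- c(rep(min(x), n), rep(0.1, n), rep(0, n), -Inf)
  upper <- c(rep(max(x), n), rep(5000, n), rep(Inf, n), Inf)
  p0 <- pmin(pmax(p0, lower), upper)

  resid_fn <- function(p) y - multi_lorentz(p, x, n, freq)
  best <- NULL
  for (attempt in seq_len(max_restarts + 1)) {
    p_try <- if (attempt == 1) p0 else {
      jit <- p0 * (1 + stats::runif(length(p0), -0.15, 0.15))
      pmin(pmax(jit, lower), upper)
    }
    fit <- try(minpack.lm::nls.lm(
      par = p_try, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ok <- fit$info %in% 1:4
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (ok && fit$deviance <= best$deviance) {
      best <- fit
      break
    }
  }
  if (is.null(best)) stop("Lorentzian fit failed on all restarts", call. = FALSE)
  p <- best$par
  ord <- order(p[seq_len(n)])
  peaks <- tibble::tibble(
    component = seq_len(n),
    center_ppm = p[seq_len(n)][ord],
    fwhm_Hz = p[n + seq_len(n)][ord],
    area = p[2 * n + seq_len(n)][ord]
  )
  res <- resid_fn(p)
  structure(
    list(
      peaks = peaks,
      baseline = p[3 * n + 1],
      n_components = n,
      labels = NULL,
      residual_rms = sqrt(mean(res^2)),
      converged = best$info %in% 1:4,
      rss = sum(res^2),
      n_points = length(y),
      freq_MHz = freq,
      spectrum = spectrum
    ),
    class = "deconvolution"
  )
}

fit_params <- function(fit) {
  n <- fit$n_components
  c(fit$peaks$center_ppm, fit$peaks$fwhm_Hz, fit$peaks$area, fit$baseline)
}

#' @export
print.deconvolution <- function(x, ...) {
  cat(sprintf("<deconvolution: %d component%s, residual RMS %.4g, %s>\n",
              x$n_components, if (x$n_components > 1) "s" else "",
              x$residual_rms,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  print(x$peaks)
  invisible(x)
}

deconv_bic <- function(fit) {
  k <- 3 * fit$n_components + 1
  n <- fit$n_points
  # floor the RSS near double precision of the data so that two numerically
  # perfect fits (noiseless input) compare as equal rather than by FP dust
  floor_rss <- (1e-10 * max(abs(fit$spectrum$intensity)))^2 * n
  n * log(max(fit$rss, floor_rss) / n) + k * log(n)
}

#' Choose between one- and two-component deconvolution
#'
#' Fits both models; returns 2 only when the two-component fit improves BIC
#' by more than `delta_bic` and both component areas exceed `area_floor` of
#' the total. Conservative by design so that spectra before the onset of
#' phase separation are not split spuriously.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param delta_bic Required BIC improvement (default 10).
#' @param area_floor Minimum area fraction per component (default 0.02).
#' @return 1 or 2.
#' @export
select_n_components <- function(spectrum, delta_bic = 10, area_floor = 0.02) {
  f1 <- try(fit_lorentzians(spectrum, 1), silent = TRUE)
  f2 <- try(fit_lorentzians(spectrum, 2), silent = TRUE)
  ok1 <- !inherits(f1, "try-error") && f1$converged
  ok2 <- !inherits(f2, "try-error") && f2$converged
  if (!ok1 && !ok2) stop("neither one- nor two-component model converged", call. = FALSE)
  if (!ok2) return(1L)
  if (!ok1) return(2L)
  frac <- f2$peaks$area / sum(f2$peaks$area)
  if (deconv_bic(f1) - deconv_bic(f2) > delta_bic && all(frac > area_floor)) 2L else 1L
}

#' Monte-Carlo 95% confidence intervals for a deconvolution
#'
#' Estimates the residual noise level from the fit, generates `n_reps`
#' synthetic spectra as model + Gaussian noise, refits each (warm-started at
#' the point estimate), and takes the 2.5/97.5 percentiles of each parameter.
#' Reproducible under a fixed seed. If more than 20% of the replicates fail
#' to converge the intervals are flagged unreliable.
#'
#' @param fit A converged `deconvolution`.
#' @param n_reps Number of replicates (>= 50, default 200).
#' @param seed Integer RNG seed (required for reproducibility).
#' @return The `deconvolution` with `ci_*_lo`/`ci_*_hi` columns added to
#'   `$peaks` and fields `mc_sigma`, `mc_failures`, `ci_unreliable`.
#' @export
monte_carlo_ci <- function(fit, n_reps = 200, seed) {
  if (!isTRUE(fit$converged)) stop("Monte-Carlo CIs need a converged fit", call. = FALSE)
  if (n_reps < 50) stop("`n_reps` must be >= 50", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  x <- fit$spectrum$ppm
  y <- fit$spectrum$intensity
  n <- fit$n_components
  freq <- fit$freq_MHz
  p_hat <- fit_params(fit)
  model <- multi_lorentz(p_hat, x, n, freq)
  sigma <- stats::sd(y - model)
  lower <- c(rep(min(x), n), rep(0.1, n), rep(0, n), -Inf)
  upper <- c(rep(max(x), n), rep(5000, n), rep(Inf, n), Inf)

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  draws <- withr_seed(function() {
    out <- matrix(NA_real_, n_reps, length(p_hat))
    fails <- 0L
    for (r in seq_len(n_reps)) {
      y_star <- model + stats::rnorm(length(y), 0, sigma)
      rf <- minpack.lm::nls.lm(
        par = p_hat, lower = lower, upper = upper,
        fn = function(p) y_star - multi_lorentz(p, x, n, freq),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      if (rf$info %in% 1:4) {
        # warm start at the point estimate keeps component identity stable
        out[r, ] <- rf$par
      } else {
        fails <- fails + 1L
      }
    }
    list(mat = out, fails = fails)
  })
  q <- apply(draws$mat, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  idx <- seq_len(n)
  fit$peaks$ci_center_lo <- q[1, idx]
  fit$peaks$ci_center_hi <- q[2, idx]
  fit$peaks$ci_fwhm_lo <- q[1, n + idx]
  fit$peaks$ci_fwhm_hi <- q[2, n + idx]
  fit$peaks$ci_area_lo <- q[1, 2 * n + idx]
  fit$peaks$ci_area_hi <- q[2, 2 * n + idx]
  fit$mc_sigma <- sigma
  fit$mc_failures <- draws$fails
  fit$ci_unreliable <- draws$fails > 0.2 * n_reps
  fit
}

#' Label deconvoluted components as lean or dense phase
#'
#' Each fitted centre is converted to a protein concentration by inverting
#' the calibration model; the lower-concentration component is the lean
#' phase, the higher-concentration one the dense phase. When the centres are
#' indistinguishable (closer than their combined centre CIs, or than
#' `tie_tol_ppm` when no CIs are present) the narrower peak is labelled lean.
#'
#' @param fit A two-component `deconvolution`.
#' @param calibration A [calibration_model()] with nonzero concentration
#'   coefficient.
#' @param dT_C Temperature offset from the 25 degree reference (degrees C).
#' @param Y_mM Additive (YCl3) concentration in mM.
#' @param tie_tol_ppm Fallback centre-distinguishability tolerance.
#' @return The fit with a `label` column (`"lean"`/`"dense"`) in `$peaks`.
#' @export
assign_phases <- function(fit, calibration, dT_C = 0, Y_mM = 0, tie_tol_ppm = 1e-9) {
  if (fit$n_components != 2) stop("phase labels need a two-component fit", call. = FALSE)
  if (calibration$coefficients[["theta_C"]] == 0) {
    stop("calibration has theta_C = 0: shift carries no concentration information",
         call. = FALSE)
  }
  conc <- shift_to_concentration(calibration, fit$peaks$center_ppm,
                                 dT_C = dT_C, Y_mM = Y_mM)$C_mgml
  tol <- tie_tol_ppm
  if ("ci_center_lo" %in% names(fit$peaks)) {
    halfw <- (fit$peaks$ci_center_hi - fit$peaks$ci_center_lo) / 2
    tol <- max(tol, sum(halfw))
  }
  if (abs(diff(fit$peaks$center_ppm)) < tol) {
    lean_idx <- which.min(fit$peaks$fwhm_Hz)
  } else {
    lean_idx <- which.min(conc)
  }
  fit$peaks$label <- ifelse(seq_len(2) == lean_idx, "lean", "dense")
  fit$labels <- fit$peaks$label
  fit
}
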