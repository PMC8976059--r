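# shared fixtures: all synthetic, built in code at test time

# fixture calibration with known coefficients (dense downfield of lean)
fix_cal <- function() calibration_model(delta0 = -77.000, theta_C = 0.0025,
                                        theta_T = 0.010, theta_Y = -0.005)

# probe-region spectrum holding one or two Lorentzians (+ optional noise)
make_probe_spectrum <- function(centers, fwhm_Hz, areas, snr = Inf, seed = NULL,
                                n = 2048, ppm_range = c(-78.5, -75.5),
                                baseline = 0, freq_MHz = 470) {
  x <- seq(ppm_range[1], ppm_range[2], length.out = n)
  y <- rep(baseline, n)
  for (k in seq_along(centers)) {
    y <- y + lorentzian_profile(x, centers[k], fwhm_Hz[k], areas[k], freq_MHz)
  }
  if (is.finite(snr)) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(n, 0, max(y) / snr)
  }
  nmr_spectrum(x, y, acquisition_meta(spectrometer_freq_19F = freq_MHz))
}

# brute-force grid-search oracle for the two-Lorentzian fit: best residual
# RMS over a parameter grid (baseline fixed at 0, total area from integral)
grid_search_rms <- function(spectrum, n_center = 9, n_fwhm = 6, n_frac = 9) {
  x <- spectrum$ppm
  y <- spectrum$intensity
  freq <- spectrum_meta(spectrum)$spectrometer_freq_19F
  total <- spectrum_integral(spectrum)
  centers <- seq(min(x), max(x), length.out = n_center)
  fwhms <- exp(seq(log(5), log(200), length.out = n_fwhm))
  fracs <- seq(0.1, 0.9, length.out = n_frac)
  best <- Inf
  for (c1 in centers) for (c2 in centers) for (w1 in fwhms) for (w2 in fwhms) {
    for (fr in fracs) {
      m <- lorentzian_profile(x, c1, w1, fr * total, freq) +
        lorentzian_profile(x, c2, w2, (1 - fr) * total, freq)
      rms <- sqrt(mean((y - m)^2))
      if (rms < best) best <- rms
    }
  }
  best
}
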