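test_that("lorentzian profile has the closed-form height, symmetry and area", {
  freq <- 470
  # gamma of 1 ppm corresponds to fwhm = 2 * freq Hz; height at centre = 1/pi
  x0 <- -77
  h <- lorentzian_profile(x0, x0, 2 * freq, area = 1, freq_MHz = freq)
  expect_equal(h, 1 / pi, tolerance = 1e-12)
  d <- seq(0.01, 2, by = 0.13)
  expect_equal(lorentzian_profile(x0 + d, x0, 30, 2, freq),
               lorentzian_profile(x0 - d, x0, 30, 2, freq))
  # trapezoid quadrature over +/- 500 gamma recovers the area within 0.1%
  gamma_ppm <- 20 / (2 * freq)
  xg <- seq(x0 - 500 * gamma_ppm, x0 + 500 * gamma_ppm, length.out = 200001)
  y <- lorentzian_profile(xg, x0, 20, 0.7, freq)
  integ <- sum(diff(xg) * (y[-1] + y[-length(y)]) / 2)
  # tail mass outside +/- 500 gamma is 2/(pi*500) ~ 0.13%
  expect_equal(integ, 0.7, tolerance = 2e-3)
  expect_error(lorentzian_profile(xg, x0, -5, 1), "fwhm")
})

test_that("initial guesses land near the true peaks and reject flat spectra", {
  s1 <- make_probe_spectrum(-77.2, 20, 1)
  g1 <- initial_guess(s1, 1)
  step <- median(diff(s1$ppm))
  expect_lt(abs(g1$centers - (-77.2)), 1.5 * step)
  s2 <- make_probe_spectrum(c(-77.4, -76.8), c(25, 25), c(0.5, 0.5))
  g2 <- initial_guess(s2, 2)
  expect_lt(min(abs(g2$centers - (-77.4))), 2.5 * step)
  expect_lt(min(abs(g2$centers - (-76.8))), 2.5 * step)
  flat <- nmr_spectrum(s1$ppm, rep(0, nrow(s1)))
  expect_error(initial_guess(flat, 1), "no peak")
})

test_that("noiseless Lorentzians are recovered essentially exactly", {
  s1 <- make_probe_spectrum(-77.0, 20, 1)
  f1 <- fit_lorentzians(s1, 1)
  expect_true(f1$converged)
  expect_equal(f1$peaks$center_ppm, -77.0, tolerance = 1e-6)
  expect_equal(f1$peaks$fwhm_Hz, 20, tolerance = 1e-5)
  expect_equal(f1$peaks$area, 1, tolerance = 1e-6)

  s2 <- make_probe_spectrum(c(-77.30, -77.05), c(15, 80), c(0.6, 0.4))
  f2 <- fit_lorentzians(s2, 2)
  expect_equal(f2$peaks$center_ppm, c(-77.30, -77.05), tolerance = 1e-4)
  expect_equal(f2$peaks$fwhm_Hz, c(15, 80), tolerance = 1e-3)
  expect_equal(f2$peaks$area, c(0.6, 0.4), tolerance = 1e-4)
})

test_that("two-peak recovery at SNR 100 stays within stated bounds", {
  errs_c <- errs_a <- NULL
  for (r in 1:10) {
    s <- make_probe_spectrum(c(-77.30, -77.05), c(15, 80), c(0.6, 0.4),
                             snr = 100, seed = 100 + r)
    f <- fit_lorentzians(s, 2)
    errs_c <- c(errs_c, abs(f$peaks$center_ppm - c(-77.30, -77.05)))
    errs_a <- c(errs_a, abs(f$peaks$area - c(0.6, 0.4)) / c(0.6, 0.4))
  }
  expect_lt(max(errs_c), 0.005)
  expect_lt(max(errs_a), 0.03)
})

test_that("fitted areas close to the spectrum integral (noiseless, no baseline)", {
  s <- make_probe_spectrum(c(-77.5, -76.9), c(20, 60), c(0.3, 0.7),
                           ppm_range = c(-80, -74))
  f <- fit_lorentzians(s, 2)
  expect_equal(sum(f$peaks$area), spectrum_integral(s), tolerance = 0.02)
})

test_that("model selection splits only genuinely two-component spectra", {
  one <- make_probe_spectrum(-77.1, 25, 1, snr = 100, seed = 7)
  expect_identical(select_n_components(one), 1L)
  two <- make_probe_spectrum(c(-77.4, -76.9), c(20, 40), c(0.5, 0.5),
                             snr = 100, seed = 8)
  expect_identical(select_n_components(two), 2L)
  # two coincident identical peaks are indistinguishable from one
  co <- make_probe_spectrum(c(-77.1, -77.1), c(30, 30), c(0.5, 0.5))
  expect_identical(select_n_components(co), 1L)
})

test_that("Monte-Carlo CIs collapse without noise and reproduce under a seed", {
  s <- make_probe_spectrum(-77.2, 20, 1)
  f <- fit_lorentzians(s, 1)
  f <- monte_carlo_ci(f, n_reps = 60, seed = 11)
  expect_lt(f$peaks$ci_center_hi - f$peaks$ci_center_lo, 1e-8)
  expect_lt(f$peaks$ci_area_hi - f$peaks$ci_area_lo, 1e-8)
  sn <- make_probe_spectrum(-77.2, 20, 1, snr = 100, seed = 12)
  fn <- fit_lorentzians(sn, 1)
  a <- monte_carlo_ci(fn, n_reps = 60, seed = 13)
  b <- monte_carlo_ci(fn, n_reps = 60, seed = 13)
  expect_identical(a$peaks, b$peaks)
  expect_error(monte_carlo_ci(fn, n_reps = 10, seed = 1), "n_reps")
})

test_that("Monte-Carlo CI width scales with the noise level", {
  width_at <- function(snr) {
    w <- numeric(5)
    for (r in 1:5) {
      s <- make_probe_spectrum(-77.2, 20, 1, snr = snr, seed = 500 + r)
      f <- monte_carlo_ci(fit_lorentzians(s, 1), n_reps = 100, seed = 600 + r)
      w[r] <- f$peaks$ci_center_hi - f$peaks$ci_center_lo
    }
    median(w)
  }
  w100 <- width_at(100)
  w200 <- width_at(200)
  expect_equal(w100 / w200, 2, tolerance = 0.2)
})

test_that("phase labels follow calibrated concentration with width tie-break", {
  cal <- fix_cal()
  s <- make_probe_spectrum(c(-77.30, -77.05), c(15, 80), c(0.6, 0.4))
  f <- assign_phases(fit_lorentzians(s, 2), cal)
  pk <- f$peaks
  # theta_C > 0: upfield (more negative) centre = lower concentration = lean
  expect_identical(pk$label[pk$center_ppm == min(pk$center_ppm)], "lean")
  expect_identical(pk$label[pk$center_ppm == max(pk$center_ppm)], "dense")
  # labels survive shuffled component order in the input spectrum
  s_sw <- make_probe_spectrum(c(-77.05, -77.30), c(80, 15), c(0.4, 0.6))
  f_sw <- assign_phases(fit_lorentzians(s_sw, 2), cal)
  expect_identical(dplyr::arrange(f_sw$peaks, center_ppm)$label,
                   dplyr::arrange(pk, center_ppm)$label)
  # coincident centres: the narrow peak is the lean phase
  f_tie <- fit_lorentzians(s, 2)
  f_tie$peaks$center_ppm <- c(-77.2, -77.2)
  f_tie$peaks$fwhm_Hz <- c(15, 80)
  f_tie <- assign_phases(f_tie, cal)
  expect_identical(f_tie$peaks$label, c("lean", "dense"))
  # a concentration-blind calibration cannot label
  expect_error(assign_phases(fit_lorentzians(s, 2),
                             calibration_model(theta_C = 0)), "theta_C")
})

test_that("nonlinear fit is at least as good as a dense grid-search oracle", {
  s <- make_probe_spectrum(c(-77.35, -76.95), c(20, 60), c(0.55, 0.45),
                           snr = 50, seed = 21, n = 512)
  fit <- fit_lorentzians(s, 2)
  oracle <- grid_search_rms(s)
  expect_lte(fit$residual_rms, oracle)
})

test_that("tidy and glance expose the deconvolution surface", {
  s <- make_probe_spectrum(c(-77.4, -76.9), c(20, 40), c(0.5, 0.5))
  f <- fit_lorentzians(s, 2)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  g <- glance(f)
  expect_equal(g$n_components, 2)
  expect_true(g$converged)
})
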