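test_that("slice geometry reproduces the acquisition numbers", {
  g <- compute_slice_geometry()
  expect_equal(nrow(g), 12)
  expect_equal(g$width_mm[1], 0.99, tolerance = 0.01)
  expect_equal(round(g$width_mm[1]), 1)
  expect_equal(max(g$center_mm), 5.50, tolerance = 0.01)
  expect_equal(min(g$center_mm), -5.50, tolerance = 0.01)
  expect_equal(g$center_mm[g$offset_Hz == 0], numeric(0))  # no zero offset slice
  # equally spaced centres
  expect_equal(sd(diff(g$center_mm)), 0, tolerance = 1e-12)
  expect_error(compute_slice_geometry(gradient_G_per_cm = 0), "gradient")
})

test_that("slice centres are linear in the pulse offset", {
  g1 <- compute_slice_geometry(offsets_Hz = c(-50000, 0, 50000))
  g2 <- compute_slice_geometry(offsets_Hz = 2 * c(-50000, 0, 50000))
  expect_equal(g2$center_mm, 2 * g1$center_mm)
  expect_equal(g1$center_mm[2], 0)
})

test_that("reference-based correction equalizes a homogeneous sample", {
  sp <- lapply(1:4, function(i) make_probe_spectrum(-77.1, 25, 1, n = 256))
  # uniform reference -> no change
  c0 <- correct_gradient_nonlinearity(sp, rep(2, 4))
  expect_equal(c0$factors, rep(1, 4))
  # one slice at 50% sensitivity: its intensities are (roughly) doubled
  sp2 <- sp
  sp2[[4]] <- nmr_spectrum(sp[[4]]$ppm, sp[[4]]$intensity * 0.5)
  c1 <- correct_gradient_nonlinearity(sp2, c(2, 2, 2, 1))
  expect_equal(c1$factors[4] / c1$factors[1], 2, tolerance = 1e-12)
  # smooth 10% roll-off: post-correction probe integrals uniform to 0.1%
  roll <- c(0.9, 1, 1, 0.9)
  sp3 <- lapply(1:4, function(i) {
    nmr_spectrum(sp[[i]]$ppm, sp[[i]]$intensity * roll[i])
  })
  c2 <- correct_gradient_nonlinearity(sp3, 2 * roll)
  ints <- vapply(c2$spectra, spectrum_integral, numeric(1))
  expect_lt(diff(range(ints)) / mean(ints), 0.001)
  # idempotence: recomputed factors after correction are all 1
  refs_after <- 2 * roll * c2$factors
  c3 <- correct_gradient_nonlinearity(c2$spectra, refs_after)
  expect_equal(c3$factors, rep(1, 4), tolerance = 1e-12)
  # dead reference marks a slice unusable
  c4 <- correct_gradient_nonlinearity(sp, c(2, 2, 0, 2))
  expect_false(c4$usable[3])
})

test_that("per-slice fractions recover the synthesized area split", {
  cal <- fix_cal()
  geom <- compute_slice_geometry(offsets_Hz = c(-40000, 40000))
  lean_d <- predict_shift(cal, 80)
  dense_d <- predict_shift(cal, 360)
  pure_lean <- make_probe_spectrum(lean_d, 15, 1)
  split <- make_probe_spectrum(c(lean_d, dense_d), c(15, 80), c(0.3, 0.7),
                               snr = 100, seed = 31, n = 4096)
  prof <- per_slice_phase_fractions(list(pure_lean, split), cal, geom)
  expect_equal(prof$lean_pct[1], 100)
  expect_equal(prof$dense_pct[1], 0)
  expect_equal(prof$lean_pct[2], 30, tolerance = 2)
  expect_equal(prof$dense_pct[2], 70, tolerance = 2)
  expect_equal(prof$lean_pct + prof$dense_pct, c(100, 100))
})

test_that("boundary location interpolates the 50% dense crossing", {
  prof <- tibble::tibble(
    time_min = 0, slice = 1:4, center_mm = c(1.5, 0.5, -0.5, -1.5),
    dense_pct = c(0, 0, 100, 100), lean_pct = 100 - dense_pct,
    n_components = 2L, usable = TRUE
  )
  b <- locate_boundary(prof)
  expect_equal(b$boundary_mm, 0.0)
  expect_identical(b$censored, "none")
  # 20%/80% at +5.5/+4.5 crosses 50% at +5.0
  prof2 <- tibble::tibble(
    time_min = 0, slice = 1:2, center_mm = c(5.5, 4.5),
    dense_pct = c(20, 80), lean_pct = 100 - dense_pct,
    n_components = 2L, usable = TRUE
  )
  expect_equal(locate_boundary(prof2)$boundary_mm, 5.0)
  all_dense <- dplyr::mutate(prof, dense_pct = 90)
  expect_identical(locate_boundary(all_dense)$censored, "above")
  all_lean <- dplyr::mutate(prof, dense_pct = 10)
  expect_identical(locate_boundary(all_lean)$censored, "below")
  expect_error(locate_boundary(prof[1, ]), "2 usable")
})

test_that("two-regime settling rates are recovered exactly without noise", {
  sp <- settling_sim_params()   # 0.154 then 0.004 mm/hr, break 1100 min
  t <- seq(150, 2000, by = 25)
  z <- sp$boundary_mm(t)
  f <- fit_settling_regimes(t, z)
  expect_equal(f$rate_fast_mm_per_hr, 0.154, tolerance = 1e-10)
  expect_equal(f$rate_slow_mm_per_hr, 0.004, tolerance = 1e-10)
  expect_lte(abs(f$breakpoint_min - 1100), 25)
  # single-slope data: both regimes agree
  z1 <- 5 - 0.1 * t / 60
  f1 <- fit_settling_regimes(t, z1)
  expect_equal(f1$rate_fast_mm_per_hr, f1$rate_slow_mm_per_hr, tolerance = 1e-8)
  # short series falls back to one line with a flag
  f2 <- fit_settling_regimes(t[1:4], z[1:4])
  expect_true(f2$single_segment)
})

test_that("settling rates survive 0.05 mm position noise within 5%", {
  sp <- settling_sim_params()
  t <- seq(150, 2000, by = 25)
  set.seed(41)
  z <- sp$boundary_mm(t) + rnorm(length(t), 0, 0.05)
  f <- fit_settling_regimes(t, z)
  expect_lt(abs(f$rate_fast_mm_per_hr - 0.154) / 0.154, 0.05)
  # the slow rate is tiny against this noise level; its least-squares
  # standard error (~0.002 mm/hr) bounds what any estimator can resolve
  expect_lt(abs(f$rate_slow_mm_per_hr - 0.004), 0.004)
})

test_that("layer onset is the first persistent reference broadening", {
  tm <- seq(0, 300, by = 10)
  w <- ifelse(tm >= 140, 6, 3)
  on <- detect_layer_onset(tm, w)
  expect_equal(on$onset_min, 140)
  flat <- detect_layer_onset(tm, rep(3, length(tm)))
  expect_false(flat$detected)
  spike <- rep(3, length(tm))
  spike[tm == 80] <- 9
  expect_false(detect_layer_onset(tm, spike)$detected)
  expect_error(detect_layer_onset(1:5, rep(3, 5)), "baseline")
})
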