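test_that("trajectories built from noiseless deconvolutions match ground truth", {
  cal <- fix_cal()
  p <- llps_sim_params("45C", t_max_min = 60, dt_min = 5)
  truth <- simulate_phase_trajectory(p)
  spectra <- render_spectrum_series(truth, cal, noise = noise_model(snr = Inf),
                                    n_points = 16384)
  times <- vapply(spectra, function(s) spectrum_meta(s)$time_min, numeric(1))
  dT <- p$temperature_C - 25
  fits <- lapply(spectra, function(s) {
    win <- spectrum_window(s, -77, 1.5)
    nc <- select_n_components(win)
    f <- fit_lorentzians(win, nc)
    if (nc == 2) f <- assign_phases(f, cal, dT_C = dT, Y_mM = 20) else f
  })
  tr <- build_phase_trajectories(fits, times, cal, V_O = p$V_O,
                                 dT_C = dT, Y_mM = 20)
  joined <- dplyr::inner_join(tr, truth, by = c("time_min", "phase"),
                              suffix = c("", "_true"))
  two_comp <- joined |>
    dplyr::group_by(time_min) |>
    dplyr::filter(dplyr::n() == 2, all(V_uL_true > 1)) |>
    dplyr::ungroup()
  expect_gt(nrow(two_comp), 10)
  expect_lt(max(abs(two_comp$C_mgml - two_comp$C_mgml_true) / two_comp$C_mgml_true),
            1e-3)
  expect_lt(max(abs(two_comp$V_uL - two_comp$V_uL_true) / two_comp$V_uL_true),
            1e-2)
})

test_that("pre-onset single-peak times occupy the full observed volume as lean", {
  cal <- fix_cal()
  s <- make_probe_spectrum(predict_shift(cal, 200, 20, 20), 15, 1)
  f <- fit_lorentzians(s, 1)
  tr <- build_phase_trajectories(list(f, f), c(0, 1), cal, V_O = 236.8,
                                 dT_C = 20, Y_mM = 20)
  expect_identical(tr$phase, c("lean", "lean"))
  expect_equal(tr$V_uL, c(236.8, 236.8))
})

test_that("unlabelled two-component fits are rejected", {
  s <- make_probe_spectrum(c(-77.4, -76.9), c(20, 40), c(0.5, 0.5))
  f <- fit_lorentzians(s, 2)
  expect_error(build_phase_trajectories(list(f), 0, fix_cal()), "assign_phases")
})

test_that("crossover is found at a constructed extremum, not on monotone series", {
  t <- seq(0, 120, by = 1)
  parab <- tibble::tibble(
    time_min = t, phase = "dense",
    C_mgml = 300 + 0.05 * (t - 60)^2,
    V_uL = 100 - 0.01 * (t - 60)^2, M_mg = 1
  )
  cx <- find_crossover(parab)
  expect_true(cx$found)
  expect_equal(cx$crossover_min, 60)
  expect_equal(cx$crossover_volume_min, 60)
  expect_false(cx$discordant)
  mono <- dplyr::mutate(parab, C_mgml = 500 - t)
  expect_false(find_crossover(mono)$found)
  expect_error(find_crossover(parab[1:5, ]), "7")
})

test_that("crossover on simulated noiseless trajectories hits the analytic value", {
  for (preset in c("45C", "50C-arrested")) {
    p <- llps_sim_params(preset)
    tr <- simulate_phase_trajectory(p)
    cx <- find_crossover(tr)
    expect_true(cx$found)
    expect_lt(abs(cx$crossover_min - p$crossover_min), 2 * p$dt_min)
  }
})

test_that("lag is the first threshold crossing of the dense volume", {
  t <- seq(0, 100, by = 1)
  step <- dplyr::bind_rows(
    tibble::tibble(time_min = t, phase = "lean", C_mgml = 200,
                   V_uL = ifelse(t < 20, 236.8, 136.8), M_mg = 1),
    tibble::tibble(time_min = t, phase = "dense", C_mgml = 400,
                   V_uL = ifelse(t < 20, 0, 100), M_mg = 1)
  )
  expect_equal(estimate_lag(step)$lag_min, 20)
  expect_equal(estimate_lag(step, threshold_frac = 0.001)$lag_min, 20)
  immediate <- dplyr::mutate(step, V_uL = ifelse(phase == "dense", 50 + time_min, 100))
  expect_equal(estimate_lag(immediate)$lag_min, 0)
  never <- dplyr::filter(step, phase == "lean")
  expect_false(estimate_lag(never)$defined)
})

test_that("the built-in simulator lag is recovered at a tight threshold", {
  p <- llps_sim_params("40C", t_max_min = 120)   # 15 min lag
  tr <- simulate_phase_trajectory(p)
  lag <- estimate_lag(tr, threshold_frac = 0.005)
  expect_lt(abs(lag$lag_min - 15), 2 * p$dt_min)
})

test_that("growth exponent is exact on noiseless power laws", {
  t <- seq(1, 100, by = 0.5)
  for (expo in c(1 / 3, 0.25, 0.1, 1)) {
    res <- fit_growth_exponent(t, 2.7 * t^expo, window_min = c(1, Inf))
    expect_equal(res$exponent, expo, tolerance = 1e-10)
  }
  # nonpositive values are excluded and counted
  v <- 2.7 * t^(1 / 3)
  v[10] <- -1
  res <- fit_growth_exponent(t, v, window_min = c(1, Inf))
  expect_equal(res$n_excluded, 1)
  expect_equal(res$exponent, 1 / 3, tolerance = 1e-3)
  expect_error(fit_growth_exponent(t[1:4], v[1:4], window_min = c(1, Inf)), "6")
})

test_that("growth-exponent CI covers the truth in most noisy replicates", {
  t <- seq(1, 100, length.out = 100)
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    set.seed(700 + r)
    v <- 2 * t^(1 / 3) * exp(rnorm(100, 0, 0.05))
    res <- fit_growth_exponent(t, v, window_min = c(1, Inf))
    if (res$ci_lo <= 1 / 3 && 1 / 3 <= res$ci_hi) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
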