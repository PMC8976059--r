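test_that("simulated trajectories conserve mass exactly at every time", {
  for (preset in c("40C", "45C", "50C-arrested")) {
    p <- llps_sim_params(preset)
    tr <- simulate_phase_trajectory(p)
    totals <- tr |>
      dplyr::group_by(time_min) |>
      dplyr::summarise(total = sum(M_mg), .groups = "drop")
    expect_lt(max(abs(totals$total - p$M_total_mg)), 1e-12 * p$M_total_mg)
  }
})

test_that("the dense-concentration minimum sits at the analytic crossover", {
  p <- llps_sim_params("45C", dt_min = 0.01)
  tr <- simulate_phase_trajectory(p)
  d <- tr[tr$phase == "dense", ]
  t_min <- d$time_min[which.min(d$C_mgml)]
  expect_lt(abs(t_min - p$crossover_min), 0.02)
})

test_that("arrested mode freezes the dense volume and keeps compacting", {
  p <- llps_sim_params("50C-arrested", t_max_min = 200)
  expect_true(p$arrested)
  tr <- simulate_phase_trajectory(p)
  d <- tr[tr$phase == "dense", ]
  post <- d[d$time_min > p$crossover_min + 1, ]
  expect_lt(diff(range(post$V_uL)), 1e-12)
  # concentration keeps rising after the crossover
  expect_true(all(diff(post$C_mgml) > 0))
})

test_that("presets order final concentration up and final volume down with T", {
  ends <- lapply(c("40C", "45C", "50C-arrested"), function(pr) {
    p <- llps_sim_params(pr, t_max_min = 2000)
    tr <- simulate_phase_trajectory(p)
    d <- tr[tr$phase == "dense", ]
    d[which.max(d$time_min), ]
  })
  C_fin <- vapply(ends, function(e) e$C_mgml, numeric(1))
  V_fin <- vapply(ends, function(e) e$V_uL, numeric(1))
  expect_true(all(diff(C_fin) > 0))
  expect_true(all(diff(V_fin) < 0))
})

test_that("impossible parameter sets are rejected before generation", {
  expect_error(
    llps_sim_params(C_dense_initial = 900, C_dense_min = 850,
                    C_dense_final = 900, C_lean_final = 10,
                    peak_volume_ratio = 1.9),
    "total mass"
  )
  expect_error(llps_sim_params(tau1_min = 50, tau2_min = 10), "tau1")
})

test_that("rendered spectra encode the trajectory exactly when noiseless", {
  cal <- fix_cal()
  p <- llps_sim_params("45C", t_max_min = 60, dt_min = 10)
  tr <- simulate_phase_trajectory(p)
  spectra <- render_spectrum_series(tr, cal, noise = noise_model(snr = Inf),
                                    n_points = 8192)
  truth <- attr(spectra, "truth")
  late <- truth[truth$dense_area > 0, ]
  # centre separation equals theta_C times the concentration difference
  d <- tr[tr$phase == "dense", ]
  l <- tr[tr$phase == "lean", ]
  for (i in seq_len(nrow(late))) {
    t_i <- late$time_min[i]
    dC <- d$C_mgml[d$time_min == t_i] - l$C_mgml[l$time_min == t_i]
    expect_equal(late$dense_center_ppm[i] - late$lean_center_ppm[i],
                 0.0025 * dC, tolerance = 1e-12)
    # area ratio equals the volume ratio
    expect_equal(late$dense_area[i] / late$lean_area[i],
                 d$V_uL[d$time_min == t_i] / l$V_uL[l$time_min == t_i],
                 tolerance = 1e-9)
  }
})

test_that("a fixed seed reproduces spectra byte-identically", {
  cal <- fix_cal()
  p <- llps_sim_params("45C", t_max_min = 10, dt_min = 5)
  tr <- simulate_phase_trajectory(p)
  a <- render_spectrum_series(tr, cal, noise = noise_model(snr = 100, seed = 9),
                              n_points = 2048)
  b <- render_spectrum_series(tr, cal, noise = noise_model(snr = 100, seed = 9),
                              n_points = 2048)
  expect_identical(a[[2]]$intensity, b[[2]]$intensity)
  c2 <- render_spectrum_series(tr, cal, noise = noise_model(snr = 100, seed = 10),
                               n_points = 2048)
  expect_false(identical(a[[2]]$intensity, c2$intensity))
})

test_that("reference broadening turns on only after the settling onset", {
  nm <- noise_model(snr = 100, onset_min = 140, broadening_amp_Hz = 6,
                    broadening_tau_min = 60)
  expect_equal(nm$extra_width_Hz(100), 0)
  expect_gt(nm$extra_width_Hz(200), 0)
  expect_lt(nm$extra_width_Hz(200), 6)
})

test_that("slice series is uniform pre-onset and lean above the boundary", {
  cal <- fix_cal()
  p <- llps_sim_params("40C", t_max_min = 1400)
  tr <- simulate_phase_trajectory(p)
  settle <- settling_sim_params()
  geom <- compute_slice_geometry()
  sim <- simulate_slice_series(tr, settle, geom, cal,
                               times_min = c(100, 600, 1300),
                               noise = noise_model(snr = Inf),
                               n_points = 2048)
  truth <- sim$truth
  pre <- truth[truth$time_min == 100, ]
  expect_lt(diff(range(pre$dense_frac)), 1e-12)
  # top slice turns >= 99% lean once the boundary has passed below it
  late <- truth[truth$time_min == 1300, ]
  z_b <- late$boundary_mm[1]
  top <- late[which.max(geom$center_mm[match(late$slice, geom$slice)]), ]
  top_bottom_edge <- max(geom$center_mm) - geom$width_mm[1] / 2
  expect_gt(top_bottom_edge, z_b)
  expect_gte(top$lean_frac, 0.99)
  expect_error(
    simulate_slice_series(tr, settle, geom, cal, times_min = 2000),
    "span"
  )
})

test_that("noiseless slice analysis recovers the generated boundary", {
  cal <- fix_cal()
  p <- llps_sim_params("40C", t_max_min = 900)
  tr <- simulate_phase_trajectory(p)
  settle <- settling_sim_params(trapped_lean_frac_initial = 0.15)
  geom <- compute_slice_geometry()
  sim <- simulate_slice_series(tr, settle, geom, cal, times_min = 700,
                               noise = noise_model(snr = Inf),
                               n_points = 4096)
  prof <- per_slice_phase_fractions(sim$spectra[[1]], cal, geom,
                                    dT_C = 15, Y_mM = 20, time_min = 700)
  b <- locate_boundary(prof)
  expect_identical(b$censored, "none")
  expect_lt(abs(b$boundary_mm - settle$boundary_mm(700)), geom$width_mm[1] / 2)
})

test_that("decay series match the requested acquisition sizes", {
  expect_equal(nrow(simulate_decay_series("inversion_recovery", 1)), 8)
  expect_equal(nrow(simulate_decay_series("cpmg", 10)), 16)
  s <- simulate_decay_series("pfg", 1e-9)
  expect_equal(nrow(s), 16)
  expect_identical(attr(s, "kind"), "pfg")
  expect_equal(attr(s, "pfg_params")$big_delta_s, 0.15)
})
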