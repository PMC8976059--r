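#' Linear chemical-shift calibration model
#'
#' The probe chemical shift is linear in protein concentration, temperature
#' offset and additive concentration:
#' `delta = delta0 + theta_C * C + theta_T * dT + theta_Y * Y`,
#' where `delta0` is the shift of the free probe at the 25 degree reference
#' temperature. This constructor builds a model from known coefficients; use
#' [fit_calibration()] to estimate them from observations.
#'
#' The default coefficients are synthetic fixture values (the measured
#' coefficients for a given probe/protein pair must be supplied by the user);
#' their signs are chosen so that the dense, higher-concentration phase
#' resonates downfield of the lean phase.
#'
#' @param delta0 Shift of the free probe at the reference temperature (ppm).
#' @param theta_C Concentration coefficient, ppm per (mg/mL).
#' @param theta_T Temperature coefficient, ppm per degree C.
#' @param theta_Y Additive coefficient, ppm per mM.
#' @param covariance Optional 4x4 coefficient covariance (symmetric PSD).
#' @param ref_temperature_C Reference temperature (degrees C).
#' @return A `calibration_model` object.
#' @export
calibration_model <- function(delta0 = -77.000, theta_C = 0.0025,
                              theta_T = 0.010, theta_Y = -0.005,
                              covariance = matrix(0, 4, 4),
                              ref_temperature_C = 25) {
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))) ||
      any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    stop("`covariance` must be symmetric positive semi-definite", call. = FALSE)
  }
  dimnames(covariance) <- list(c("delta0", "theta_C", "theta_T", "theta_Y"),
                               c("delta0", "theta_C", "theta_T", "theta_Y"))
  structure(
    list(
      coefficients = c(delta0 = delta0, theta_C = theta_C,
                       theta_T = theta_T, theta_Y = theta_Y),
      covariance = covariance,
      ref_temperature_C = ref_temperature_C,
      fit = NULL
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>  delta = delta0 + theta_C*C + theta_T*dT + theta_Y*Y\n")
  print(x$coefficients)
  invisible(x)
}

#' Fit the shift calibration by ordinary least squares
#'
#' @param observations A data frame with columns `delta` (ppm), `C` (mg/mL),
#'   `dT` (degrees C relative to the reference) and `Y` (mM). At least 5 rows.
#' @param ref_temperature_C Reference temperature the `dT` column refers to.
#' @return A `calibration_model` with coefficient covariance and the
#'   underlying `lm` fit attached.
#' @export
fit_calibration <- function(observations, ref_temperature_C = 25) {
  req <- c("delta", "C", "dT", "Y")
  if (!all(req %in% names(observations))) {
    stop("`observations` needs columns delta, C, dT, Y", call. = FALSE)
  }
  if (nrow(observations) < 5) stop("need at least 5 observations", call. = FALSE)
  for (v in c("C", "dT", "Y")) {
    if (stats::var(observations[[v]]) == 0) {
      stop(sprintf("coefficient for `%s` is unidentifiable: column has no variation (theta_%s)",
                   v, if (v == "C") "C" else if (v == "dT") "T" else "Y"), call. = FALSE)
    }
  }
  fit <- stats::lm(delta ~ C + dT + Y, data = observations)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient calibration design; unidentifiable: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  co <- stats::coef(fit)
  vc <- stats::vcov(fit)
  m <- calibration_model(delta0 = co[["(Intercept)"]], theta_C = co[["C"]],
                         theta_T = co[["dT"]], theta_Y = co[["Y"]],
                         covariance = unname(vc),
                         ref_temperature_C = ref_temperature_C)
  m$fit <- fit
  m
}

#' Predict a probe chemical shift from the calibration model
#'
#' @param model A [calibration_model()].
#' @param C_mgml Protein concentration (mg/mL).
#' @param dT_C Temperature offset from the reference (degrees C).
#' @param Y_mM Additive concentration (mM).
#' @return Predicted shift(s) in ppm.
#' @export
predict_shift <- function(model, C_mgml, dT_C = 0, Y_mM = 0) {
  b <- model$coefficients
  b[["delta0"]] + b[["theta_C"]] * C_mgml + b[["theta_T"]] * dT_C + b[["theta_Y"]] * Y_mM
}

#' Invert the calibration: chemical shift to concentration
#'
#' `C = (delta - delta0 - theta_T * dT - theta_Y * Y) / theta_C`, with a 95%
#' interval by first-order propagation of the shift uncertainty and the
#' coefficient covariance. Negative concentrations are floored at zero in
#' `C_mgml` with the unfloored value retained in `C_unfloored`.
#'
#' @param model A [calibration_model()] with `theta_C != 0`.
#' @param delta_ppm Observed shift(s), ppm.
#' @param dT_C,Y_mM Conditions at observation time.
#' @param delta_se Optional standard error(s) of the shift (ppm) for CI
#'   propagation (e.g. from Monte-Carlo deconvolution CIs / 3.92).
#' @return A tibble with columns `C_mgml`, `C_lo`, `C_hi`, `C_unfloored`,
#'   `floored`.
#' @export
shift_to_concentration <- function(model, delta_ppm, dT_C = 0, Y_mM = 0,
                                   delta_se = 0) {
  b <- model$coefficients
  if (b[["theta_C"]] == 0) {
    stop("theta_C = 0: cannot invert shift to concentration", call. = FALSE)
  }
  k <- max(length(delta_ppm), length(dT_C), length(Y_mM))
  delta_ppm <- rep_len(delta_ppm, k)
  dT_C <- rep_len(dT_C, k)
  Y_mM <- rep_len(Y_mM, k)
  delta_se <- rep_len(delta_se, k)
  C <- (delta_ppm - b[["delta0"]] - b[["theta_T"]] * dT_C - b[["theta_Y"]] * Y_mM) /
    b[["theta_C"]]
  # delta method: gradient of C wrt (delta0, theta_C, theta_T, theta_Y, delta)
  se <- vapply(seq_len(k), function(i) {
    g <- c(-1 / b[["theta_C"]],
           -C[i] / b[["theta_C"]],
           -dT_C[i] / b[["theta_C"]],
           -Y_mM[i] / b[["theta_C"]])
    v <- drop(t(g) %*% model$covariance %*% g) + (delta_se[i] / b[["theta_C"]])^2
    sqrt(max(v, 0))
  }, numeric(1))
  tibble::tibble(
    C_mgml = pmax(C, 0),
    C_lo = C - 1.96 * se,
    C_hi = C + 1.96 * se,
    C_unfloored = C,
    floored = C < 0
  )
}

#' Phase volume from deconvoluted integrals
#'
#' `V_P = (I_P / I_T) * V_O`: the fraction of the total probe integral in a
#' phase, times the NMR-observed volume.
#'
#' @param I_P Deconvoluted probe integral in the phase (a.u.).
#' @param I_T Total probe integral (a.u.), > 0.
#' @param V_O NMR-observed volume (microlitres).
#' @param I_P_se,I_T_se Optional standard errors for CI propagation.
#' @return A tibble with `V_uL`, `V_lo`, `V_hi`, `clamped`.
#' @export
phase_volume <- function(I_P, I_T, V_O = 236.8, I_P_se = 0, I_T_se = 0) {
  if (any(I_T <= 0)) stop("`I_T` must be > 0", call. = FALSE)
  if (any(I_P < 0)) stop("`I_P` must be >= 0", call. = FALSE)
  clamped <- I_P > I_T
  if (any(clamped)) {
    warning("I_P exceeds I_T for ", sum(clamped), " value(s); flagged, value retained")
  }
  V <- (I_P / I_T) * V_O
  # first-order propagation for the ratio
  rel_var <- ifelse(I_P > 0, (I_P_se / I_P)^2, 0) + (I_T_se / I_T)^2
  se <- abs(V) * sqrt(rel_var)
  tibble::tibble(V_uL = V, V_lo = V - 1.96 * se, V_hi = V + 1.96 * se,
                 clamped = clamped)
}

#' Phase mass from concentration and volume
#'
#' `M_P = C_P * V_P`, with volume in microlitres converted to millilitres so
#' the mass comes out in milligrams.
#'
#' @param C_mgml Phase concentration (mg/mL).
#' @param V_uL Phase volume (microlitres).
#' @param C_se,V_se Optional standard errors (same units) for CI propagation.
#' @return A tibble with `M_mg`, `M_lo`, `M_hi`.
#' @export
phase_mass <- function(C_mgml, V_uL, C_se = 0, V_se = 0) {
  M <- C_mgml * V_uL / 1000
  var_M <- (V_uL / 1000)^2 * C_se^2 + (C_mgml / 1000)^2 * V_se^2
  se <- sqrt(var_M)
  tibble::tibble(M_mg = M, M_lo = M - 1.96 * se, M_hi = M + 1.96 * se)
}

#' Audit mass conservation along a phase trajectory
#'
#' Sums lean and dense mass at each time point and flags times where the
#' total deviates from the expected total by more than `tol_frac`.
#'
#' @param trajectory A long tibble with columns `time_min`, `phase`
#'   (`"lean"`/`"dense"`) and `M_mg`, as built by
#'   [build_phase_trajectories()] or [simulate_phase_trajectory()].
#' @param expected_total_mg Expected total mass in the observed volume (mg).
#' @param tol_frac Fractional tolerance (default 0.05).
#' @return A list with `per_time` (tibble: time_min, total_mg, deviation,
#'   flagged), `max_deviation`, `n_flagged`, `n_excluded` (times missing a
#'   phase).
#' @export
check_mass_conservation <- function(trajectory, expected_total_mg, tol_frac = 0.05) {
  wide <- trajectory |>
    dplyr::select("time_min", "phase", "M_mg") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "M_mg")
  if (!"lean" %in% names(wide)) wide$lean <- NA_real_
  if (!"dense" %in% names(wide)) wide$dense <- NA_real_
  complete <- !is.na(wide$lean) & !is.na(wide$dense)
  per_time <- wide |>
    dplyr::filter(complete) |>
    dplyr::mutate(
      total_mg = .data$lean + .data$dense,
      deviation = abs(.data$total_mg - expected_total_mg) / expected_total_mg,
      flagged = .data$deviation > tol_frac
    ) |>
    dplyr::select("time_min", "total_mg", "deviation", "flagged")
  list(
    per_time = per_time,
    max_deviation = if (nrow(per_time)) max(per_time$deviation) else NA_real_,
    n_flagged = sum(per_time$flagged),
    n_excluded = sum(!complete)
  )
}
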