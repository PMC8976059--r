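#' Dynamic viscosity of water
#'
#' Vogel-type correlation `eta(T) = A * 10^(B / (T_K - C))` with
#' `A = 2.414e-5 Pa s`, `B = 247.8 K`, `C = 140 K`, matching tabulated pure
#' water viscosity to within about 0.3% between 0 and 100 degrees C. Strictly
#' decreasing over that range.
#'
#' @param T_C Temperature in degrees Celsius, in (0, 100).
#' @return Viscosity in mPa s (= cP).
#' @export
water_viscosity <- function(T_C) {
  if (any(T_C <= 0 | T_C >= 100)) {
    stop("`T_C` must be within (0, 100) degrees C", call. = FALSE)
  }
  T_K <- T_C + 273.15
  1000 * 2.414e-5 * 10^(247.8 / (T_K - 140))
}

#' Temperature scaling of the transverse relaxation rate
#'
#' Assuming relaxation is dominated by rotational tumbling, the
#' Stokes-Einstein-Debye proportionality of R2 to the rotational correlation
#' time gives `R2(T) = R2(T_ref) * (eta_T * T_ref) / (eta_ref * T)` with
#' temperatures in kelvin. The effective hydrodynamic radius cancels.
#'
#' @param R2_ref Reference relaxation rate (1/s).
#' @param T_ref_C,T_C Reference and target temperatures (degrees C).
#' @param viscosity_fn Viscosity correlation; defaults to [water_viscosity()].
#' @return Scaled rate(s) in 1/s.
#' @export
scale_R2 <- function(R2_ref, T_ref_C, T_C, viscosity_fn = water_viscosity) {
  Tr <- T_ref_C + 273.15
  Tt <- T_C + 273.15
  R2_ref * (viscosity_fn(T_C) * Tr) / (viscosity_fn(T_ref_C) * Tt)
}

#' Stokes-Einstein temperature scaling of the diffusion coefficient
#'
#' `D(T) = D(T_ref) * (eta_ref * T) / (eta_T * T_ref)`, the exact reciprocal
#' of the [scale_R2()] factor.
#'
#' @param DL_ref Reference diffusion coefficient (m^2/s).
#' @inheritParams scale_R2
#' @return Scaled coefficient(s) in m^2/s.
#' @export
scale_DL <- function(DL_ref, T_ref_C, T_C, viscosity_fn = water_viscosity) {
  Tr <- T_ref_C + 273.15
  Tt <- T_C + 273.15
  DL_ref * (viscosity_fn(T_ref_C) * Tt) / (viscosity_fn(T_C) * Tr)
}

#' Crowding-limited diffusion coefficient
#'
#' Expected probe diffusion at protein volume fraction `phi`:
#' `D(phi) = D_diluted * (1 - phi)^3 / (1 + 3/2 phi + 2 phi^2 + 3 phi^3)`,
#' with `phi = C * specific_volume / 1000` computed from the protein
#' concentration in mg/mL and a protein specific volume in mL/g (0.735 for
#' serum albumin).
#'
#' @param DL_diluted Diffusion coefficient in dilute solution (m^2/s).
#' @param C_mgml Protein concentration (mg/mL).
#' @param specific_volume Protein specific volume (mL/g).
#' @return Expected crowded diffusion coefficient(s) (m^2/s).
#' @export
crowding_DL <- function(DL_diluted, C_mgml, specific_volume = 0.735) {
  phi <- C_mgml * specific_volume / 1000
  if (any(phi < 0 | phi >= 1)) {
    stop("volume fraction must lie in [0, 1)", call. = FALSE)
  }
  DL_diluted * (1 - phi)^3 / (1 + 1.5 * phi + 2 * phi^2 + 3 * phi^3)
}

# shared Levenberg-Marquardt decay fit with Monte-Carlo 95% CIs
fit_decay <- function(x, y, model_fn, p0, lower, upper, par_names,
                      n_mc = 200, seed = 1) {
  resid_fn <- function(p) y - model_fn(p, x)
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  converged <- fit$info %in% 1:4
  p <- fit$par
  res <- resid_fn(p)
  ci <- matrix(NA_real_, 2, length(p))
  if (converged && n_mc > 0) {
    sigma <- stats::sd(res)
    yhat <- model_fn(p, x)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    draws <- matrix(NA_real_, n_mc, length(p))
    for (r in seq_len(n_mc)) {
      y_star <- yhat + stats::rnorm(length(y), 0, sigma)
      rf <- minpack.lm::nls.lm(par = p, lower = lower, upper = upper,
                               fn = function(q) y_star - model_fn(q, x),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      if (rf$info %in% 1:4) draws[r, ] <- rf$par
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }
  names(p) <- par_names
  structure(
    list(parameters = p, ci95_lo = stats::setNames(ci[1, ], par_names),
         ci95_hi = stats::setNames(ci[2, ], par_names),
         residual_rms = sqrt(mean(res^2)), converged = converged),
    class = "relax_fit"
  )
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("<relax_fit (%s): residual RMS %.4g, %s>\n",
              if (is.null(x$kind)) "decay" else x$kind, x$residual_rms,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  print(x$parameters)
  invisible(x)
}

#' Fit an inversion-recovery longitudinal relaxation series
#'
#' Model `I(t) = I0 * (1 - 2 * exp(-t * R1))`; returns `R1 = 1/T1`.
#'
#' @param series A [decay_series()] of kind `inversion_recovery`
#'   (>= 4 points).
#' @param n_mc Monte-Carlo replicates for the 95% CI (0 disables).
#' @param seed RNG seed for the Monte-Carlo CI.
#' @return A `relax_fit` with parameters `R1` and `I0`.
#' @export
fit_t1_inversion_recovery <- function(series, n_mc = 200, seed = 1) {
  stopifnot(attr(series, "kind") == "inversion_recovery", nrow(series) >= 4)
  x <- series$x
  y <- series$y
  model <- function(p, t) p[2] * (1 - 2 * exp(-t * p[1]))
  span <- max(x[x > 0])
  p0 <- c(1 / max(span / 3, .Machine$double.eps), max(abs(y)))
  f <- fit_decay(x, y, model, p0, lower = c(1e-6, 0), upper = c(Inf, Inf),
                 par_names = c("R1", "I0"), n_mc = n_mc, seed = seed)
  f$kind <- "inversion_recovery"
  f
}

#' Fit a CPMG transverse relaxation decay
#'
#' Model `I(t) = I0 * exp(-t * R2)`; returns `R2 = 1/T2`.
#'
#' @param series A [decay_series()] of kind `cpmg` (>= 4 points).
#' @inheritParams fit_t1_inversion_recovery
#' @return A `relax_fit` with parameters `R2` and `I0`.
#' @export
fit_t2_decay <- function(series, n_mc = 200, seed = 1) {
  stopifnot(attr(series, "kind") == "cpmg", nrow(series) >= 4)
  x <- series$x
  y <- series$y
  model <- function(p, t) p[2] * exp(-t * p[1])
  # log-linear seed over positive signal
  pos <- y > 0
  sl <- if (sum(pos) >= 2) -stats::coef(stats::lm(log(y[pos]) ~ x[pos]))[[2]] else 1
  p0 <- c(max(sl, 1e-3), max(y))
  f <- fit_decay(x, y, model, p0, lower = c(1e-6, 0), upper = c(Inf, Inf),
                 par_names = c("R2", "I0"), n_mc = n_mc, seed = seed)
  f$kind <- "cpmg"
  f
}

# 19F gyromagnetic ratio, gamma / 2 pi in MHz/T
GAMMA_19F_MHZ_PER_T <- 40.078

#' Fit a Stejskal-Tanner pulsed-field-gradient diffusion decay
#'
#' Model `I(g) = I0 * exp(-D * gamma^2 * g^2 * delta_g^2 * (Delta - delta_g/3))`
#' with `gamma` the 19F gyromagnetic ratio (2 pi x 40.078 MHz/T), gradient
#' strength `g` in T/m, diffusion time `Delta` and gradient pulse length
#' `delta_g` in seconds.
#'
#' @param series A [decay_series()] of kind `pfg` with `pfg_params` set
#'   (>= 5 gradient points).
#' @inheritParams fit_t1_inversion_recovery
#' @return A `relax_fit` with parameters `D` (m^2/s) and `I0`.
#' @export
fit_stejskal_tanner <- function(series, n_mc = 200, seed = 1) {
  stopifnot(attr(series, "kind") == "pfg", nrow(series) >= 5)
  pp <- attr(series, "pfg_params")
  gamma <- 2 * pi * GAMMA_19F_MHZ_PER_T * 1e6   # rad / (s T)
  b_per_D <- gamma^2 * series$x^2 * pp$little_delta_s^2 *
    (pp$big_delta_s - pp$little_delta_s / 3)
  y <- series$y
  model <- function(p, b) p[2] * exp(-p[1] * b)
  pos <- y > 0 & b_per_D > 0
  sl <- if (sum(pos) >= 2) {
    -stats::coef(stats::lm(log(y[pos]) ~ b_per_D[pos]))[[2]]
  } else 1e-9
  p0 <- c(max(sl, 1e-14), max(y))
  f <- fit_decay(b_per_D, y, model, p0, lower = c(1e-16, 0), upper = c(Inf, Inf),
                 par_names = c("D", "I0"), n_mc = n_mc, seed = seed)
  f$kind <- "pfg"
  f
}
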