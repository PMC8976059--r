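#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a deconvolution result
#'
#' @param x A `deconvolution` from [fit_lorentzians()].
#' @param ... Unused.
#' @return One row per fitted peak: centre, width, area, and any Monte-Carlo
#'   CI columns / phase labels present.
#' @export
tidy.deconvolution <- function(x, ...) {
  x$peaks
}

#' One-row fit summary of a deconvolution
#' @inheritParams tidy.deconvolution
#' @return A one-row tibble: `n_components`, `residual_rms`, `baseline`,
#'   `converged`, `bic`.
#' @export
glance.deconvolution <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    residual_rms = x$residual_rms,
    baseline = x$baseline,
    converged = x$converged,
    bic = deconv_bic(x)
  )
}

#' Tidy a calibration model
#' @param x A [calibration_model()].
#' @param ... Unused.
#' @return One row per coefficient with standard errors from the covariance.
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = sqrt(diag(x$covariance))
  )
}

#' One-row summary of a calibration fit
#' @inheritParams tidy.calibration_model
#' @return A one-row tibble with the reference temperature and, when fitted
#'   from data, residual sigma and R-squared.
#' @export
glance.calibration_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(ref_temperature_C = x$ref_temperature_C,
                          sigma = NA_real_, r.squared = NA_real_,
                          nobs = NA_integer_))
  }
  s <- summary(x$fit)
  tibble::tibble(ref_temperature_C = x$ref_temperature_C,
                 sigma = s$sigma, r.squared = s$r.squared,
                 nobs = stats::nobs(x$fit))
}

#' Tidy a relaxation/diffusion fit
#' @param x A `relax_fit`.
#' @param ... Unused.
#' @return One row per parameter with 95% Monte-Carlo bounds.
#' @export
tidy.relax_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$parameters),
    estimate = unname(x$parameters),
    ci_lo = unname(x$ci95_lo),
    ci_hi = unname(x$ci95_hi)
  )
}

#' Tidy a two-regime settling fit
#' @param x A `settling_fit`.
#' @param ... Unused.
#' @return One row per regime with its rate in mm/hr.
#' @export
tidy.settling_fit <- function(x, ...) {
  tibble::tibble(
    regime = c("fast", "slow"),
    rate_mm_per_hr = c(x$rate_fast_mm_per_hr, x$rate_slow_mm_per_hr),
    breakpoint_min = x$breakpoint_min
  )
}

#' One-row summary of a settling fit
#' @inheritParams tidy.settling_fit
#' @return A one-row tibble: breakpoint, SSE, single-segment flag.
#' @export
glance.settling_fit <- function(x, ...) {
  tibble::tibble(breakpoint_min = x$breakpoint_min, sse = x$sse,
                 single_segment = x$single_segment,
                 nobs = nrow(x$data))
}
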