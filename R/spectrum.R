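#' Construct a 1D NMR spectrum
#'
#' A spectrum is a tibble with columns `ppm` and `intensity`, carrying
#' acquisition metadata as an attribute. The ppm axis is stored in ascending
#' order; descending input is reordered together with the intensities.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of intensities (arbitrary units), finite.
#' @param meta Acquisition metadata, see [acquisition_meta()].
#'
#' @return A tibble of class `nmr_spectrum` with columns `ppm`, `intensity`
#'   and a `meta` attribute.
#' @export
#' @examples
#' s <- nmr_spectrum(c(-78, -77, -76), c(0, 5, 0))
#' spectrum_meta(s)$spectrometer_freq_19F
nmr_spectrum <- function(ppm, intensity, meta = acquisition_meta()) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("`ppm` and `intensity` must have the same length", call. = FALSE)
  }
  if (length(ppm) < 2) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  d <- diff(ppm)
  if (any(d == 0) || (!all(d > 0) && !all(d < 0))) {
    stop("`ppm` axis must be strictly monotone (duplicated or non-monotone values found)",
         call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("`intensity` must be finite everywhere", call. = FALSE)
  }
  if (d[1] < 0) {
    o <- order(ppm)
    ppm <- ppm[o]
    intensity <- intensity[o]
  }
  out <- tibble::tibble(ppm = ppm, intensity = intensity)
  attr(out, "meta") <- meta
  class(out) <- c("nmr_spectrum", class(out))
  out
}

#' Acquisition metadata for a spectrum
#'
#' @param spectrometer_freq_19F 19F spectrometer frequency in MHz (470 for a
#'   500 MHz instrument).
#' @param time_min Minutes since the kinetic trigger (e.g. temperature jump).
#' @param temperature_C Sample temperature in degrees Celsius.
#' @param slice_index Integer slice index for spatially-selective spectra, or
#'   `NA` for bulk detection.
#' @param em_lb_Hz Exponential line broadening applied during processing (Hz).
#'
#' @return A list of class `acquisition_meta`.
#' @export
acquisition_meta <- function(spectrometer_freq_19F = 470,
                             time_min = NA_real_,
                             temperature_C = NA_real_,
                             slice_index = NA_integer_,
                             em_lb_Hz = 0) {
  if (!is.numeric(spectrometer_freq_19F) || spectrometer_freq_19F <= 0) {
    stop("`spectrometer_freq_19F` must be > 0", call. = FALSE)
  }
  if (!is.na(em_lb_Hz) && em_lb_Hz < 0) {
    stop("`em_lb_Hz` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      spectrometer_freq_19F = spectrometer_freq_19F,
      time_min = as.numeric(time_min),
      temperature_C = as.numeric(temperature_C),
      slice_index = as.integer(slice_index),
      em_lb_Hz = as.numeric(em_lb_Hz)
    ),
    class = "acquisition_meta"
  )
}

#' Extract the metadata attribute of a spectrum
#' @param spectrum An `nmr_spectrum`.
#' @return The `acquisition_meta` list.
#' @export
spectrum_meta <- function(spectrum) {
  m <- attr(spectrum, "meta")
  if (is.null(m)) acquisition_meta() else m
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  m <- spectrum_meta(x)
  cat(sprintf(
    "<nmr_spectrum: %d points, %.3f to %.3f ppm, %g MHz%s%s>\n",
    nrow(x), min(x$ppm), max(x$ppm), m$spectrometer_freq_19F,
    if (!is.na(m$time_min)) sprintf(", t = %g min", m$time_min) else "",
    if (!is.na(m$slice_index)) sprintf(", slice %d", m$slice_index) else ""
  ))
  NextMethod()
}

#' Restrict a spectrum to a ppm window
#'
#' @param spectrum An `nmr_spectrum`.
#' @param center Window centre in ppm.
#' @param halfwidth Half-width of the window in ppm.
#' @return An `nmr_spectrum` restricted to `center +/- halfwidth`.
#' @export
spectrum_window <- function(spectrum, center, halfwidth) {
  keep <- abs(spectrum$ppm - center) <= halfwidth
  if (sum(keep) < 2) stop("window contains fewer than 2 points", call. = FALSE)
  nmr_spectrum(spectrum$ppm[keep], spectrum$intensity[keep], spectrum_meta(spectrum))
}

#' Trapezoidal integral of a spectrum
#' @param spectrum An `nmr_spectrum`.
#' @return The trapezoid integral of intensity over ppm (a.u. x ppm).
#' @export
spectrum_integral <- function(spectrum) {
  x <- spectrum$ppm
  y <- spectrum$intensity
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
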