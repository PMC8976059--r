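#' Read a two-column ASCII spectrum with a metadata sidecar
#'
#' Reads an exported processed spectrum: two whitespace- or comma-delimited
#' numeric columns (ppm, intensity), with `#`-prefixed comment lines allowed.
#' Metadata live in a separate plain-text sidecar of `key: value` lines with
#' the keys of [acquisition_meta()]; absent keys fall back to the defaults.
#'
#' @param path Path to the two-column spectrum file.
#' @param sidecar Optional path to the sidecar metadata file.
#' @return An [nmr_spectrum()].
#' @export
read_spectrum_xy <- function(path, sidecar = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no data lines in ", path, call. = FALSE)
  parts <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  n_fields <- lengths(parts)
  bad <- which(n_fields != 2)
  if (length(bad) > 0) {
    stop(sprintf("parse error in %s at line %d: expected 2 columns, found %d",
                 path, idx[bad[1]], n_fields[bad[1]]), call. = FALSE)
  }
  vals <- suppressWarnings(vapply(parts, as.numeric, numeric(2)))
  nan_col <- which(colSums(is.na(vals)) > 0)
  if (length(nan_col) > 0) {
    stop(sprintf("parse error in %s at line %d: non-numeric field",
                 path, idx[nan_col[1]]), call. = FALSE)
  }
  meta <- if (!is.null(sidecar)) read_sidecar(sidecar) else acquisition_meta()
  nmr_spectrum(vals[1, ], vals[2, ], meta)
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  values <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  defaults <- acquisition_meta()
  get <- function(key, default) {
    i <- match(key, keys)
    if (is.na(i) || values[i] %in% c("", "NA")) default else as.numeric(values[i])
  }
  acquisition_meta(
    spectrometer_freq_19F = get("spectrometer_freq_19F", defaults$spectrometer_freq_19F),
    time_min = get("time_min", defaults$time_min),
    temperature_C = get("temperature_C", defaults$temperature_C),
    slice_index = get("slice_index", defaults$slice_index),
    em_lb_Hz = get("em_lb_Hz", defaults$em_lb_Hz)
  )
}

#' Write a spectrum as two-column ASCII plus sidecar
#'
#' Inverse of [read_spectrum_xy()]: values are written at full double
#' precision so a round trip reproduces the spectrum exactly.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param path Output path for the two-column file.
#' @param sidecar_path Optional output path for the metadata sidecar.
#' @return Invisibly, `path`.
#' @export
write_spectrum_xy <- function(spectrum, path, sidecar_path = NULL) {
  if (!inherits(spectrum, "nmr_spectrum")) {
    spectrum <- nmr_spectrum(spectrum$ppm, spectrum$intensity)
  }
  lines <- sprintf("%.17g %.17g", spectrum$ppm, spectrum$intensity)
  writeLines(c("# ppm intensity", lines), path)
  if (!is.null(sidecar_path)) {
    m <- spectrum_meta(spectrum)
    kv <- vapply(names(m), function(k) {
      v <- m[[k]]
      sprintf("%s: %s", k, if (is.na(v)) "NA" else format(v, digits = 17))
    }, "")
    writeLines(kv, sidecar_path)
  }
  invisible(path)
}

#' Convert a ppm offset to Hz and back
#'
#' On a spectrometer whose 19F frequency is `freq_MHz`, 1 ppm corresponds to
#' `freq_MHz` Hz. Used to express fitted linewidths in Hz.
#'
#' @param delta_ppm Offset in ppm.
#' @param hz Offset in Hz.
#' @param freq_MHz Spectrometer frequency in MHz (> 0).
#' @return The converted offset.
#' @export
ppm_to_hz <- function(delta_ppm, freq_MHz = 470) {
  stopifnot(freq_MHz > 0)
  delta_ppm * freq_MHz
}

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, freq_MHz = 470) {
  stopifnot(freq_MHz > 0)
  hz / freq_MHz
}

#' Process a complex free-induction decay into a spectrum
#'
#' Applies exponential apodization (`exp(-pi * lb_Hz * t)`, the EM window),
#' discrete-Fourier transforms, and returns the real (absorptive) spectrum on
#' a ppm axis centred at `center_ppm`. A pure exponentially decaying signal of
#' intrinsic Lorentzian FWHM `w` Hz yields, within digital resolution, a
#' Lorentzian of FWHM `w + lb_Hz`.
#'
#' @param fid Complex time-domain vector (first point at t = 0).
#' @param dwell Dwell time between points in seconds.
#' @param lb_Hz Exponential line broadening in Hz (>= 0).
#' @param freq_MHz Spectrometer frequency (MHz), sets the ppm scale.
#' @param center_ppm Carrier position: ppm value at zero frequency offset.
#' @param meta Optional [acquisition_meta()]; `em_lb_Hz` is overwritten with
#'   `lb_Hz`.
#' @return An [nmr_spectrum()] of the same length as `fid`.
#' @export
process_fid <- function(fid, dwell, lb_Hz = 0, freq_MHz = 470,
                        center_ppm = 0, meta = acquisition_meta()) {
  if (lb_Hz < 0) stop("`lb_Hz` must be >= 0", call. = FALSE)
  n <- length(fid)
  t <- (seq_len(n) - 1) * dwell
  apodized <- fid * exp(-pi * lb_Hz * t)
  # halve the t=0 point so the discrete sum matches the continuous FT of a
  # one-sided decay (avoids a constant baseline offset)
  apodized[1] <- apodized[1] / 2
  spec <- stats::fft(apodized)
  # fftshift: map bin k to frequency (k - n/2)/(n*dwell)
  half <- ceiling(n / 2)
  spec <- c(spec[(half + 1):n], spec[1:half])
  freq_hz <- ((seq_len(n) - 1) - (n - half)) / (n * dwell)
  ppm <- center_ppm + freq_hz / freq_MHz
  meta$em_lb_Hz <- lb_Hz
  nmr_spectrum(ppm, Re(spec), meta)
}

#' Synthesize a complex FID from Lorentzian line parameters
#'
#' Each component contributes `area * exp(2i*pi*f*t - pi*fwhm_Hz*t)` with
#' `f` the offset of `center_ppm` from the carrier; [process_fid()] turns the
#' sum into the corresponding Lorentzian absorption spectrum.
#'
#' @param centers_ppm,fwhm_Hz,areas Per-component parameter vectors.
#' @param n Number of time-domain points.
#' @param dwell Dwell time (s).
#' @param freq_MHz Spectrometer frequency (MHz).
#' @param carrier_ppm Carrier position in ppm.
#' @return A complex vector of length `n`.
#' @export
synthesize_fid <- function(centers_ppm, fwhm_Hz, areas, n, dwell,
                           freq_MHz = 470, carrier_ppm = 0) {
  stopifnot(length(centers_ppm) == length(fwhm_Hz),
            length(centers_ppm) == length(areas), all(fwhm_Hz > 0))
  t <- (seq_len(n) - 1) * dwell
  fid <- complex(real = numeric(n), imaginary = numeric(n))
  for (k in seq_along(centers_ppm)) {
    f <- (centers_ppm[k] - carrier_ppm) * freq_MHz
    fid <- fid + areas[k] * exp(2i * pi * f * t - pi * fwhm_Hz[k] * t)
  }
  # scale so the absorption-mode integral over ppm equals the requested areas
  fid * 2 * dwell * freq_MHz
}

#' Read a decay series (relaxation or gradient) from CSV
#'
#' @param path CSV with columns `x` and `y` (x in seconds for relaxation, in
#'   T/m for pulsed-field-gradient data).
#' @param kind One of `"inversion_recovery"`, `"cpmg"`, `"pfg"`.
#' @param big_delta_s,little_delta_s Diffusion time and gradient pulse length
#'   in seconds (required when `kind = "pfg"`).
#' @return A `decay_series` tibble with attributes `kind` and `pfg_params`.
#' @export
read_decay_series <- function(path, kind, big_delta_s = NULL, little_delta_s = NULL) {
  df <- utils::read.csv(path)
  decay_series(df$x, df$y, kind, big_delta_s, little_delta_s)
}

#' Construct a decay series
#' @param x Time (s) or gradient strength (T/m); nonnegative, strictly increasing.
#' @param y Signal values; finite.
#' @inheritParams read_decay_series
#' @return A `decay_series` tibble.
#' @export
decay_series <- function(x, y, kind = c("inversion_recovery", "cpmg", "pfg"),
                         big_delta_s = NULL, little_delta_s = NULL) {
  kind <- match.arg(kind)
  if (any(x < 0) || any(diff(x) <= 0)) {
    stop("`x` must be nonnegative and strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(y))) stop("`y` must be finite", call. = FALSE)
  if (kind == "pfg" && (is.null(big_delta_s) || is.null(little_delta_s))) {
    stop("`big_delta_s` and `little_delta_s` are required for pfg series", call. = FALSE)
  }
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  attr(out, "kind") <- kind
  attr(out, "pfg_params") <- if (kind == "pfg") {
    list(big_delta_s = big_delta_s, little_delta_s = little_delta_s)
  }
  class(out) <- c("decay_series", class(out))
  out
}
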