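#' Acquisition parameters for 1D proton NMR
#'
#' Bundles the instrument settings that determine the digital properties of a
#' simulated or imported FID: a 500 MHz proton frequency, a 16 ppm spectral
#' window digitized into 65,536 complex points, 128 scans with a 1.5 s
#' relaxation delay (metadata only; scan-by-scan acquisition is not modeled),
#' and a 0.5 Hz exponential line-broadening applied before Fourier
#' transformation. The carrier (centre of the spectral window) defaults to
#' 4.7 ppm, near the water resonance, the usual choice when the solvent is
#' presaturated.
#'
#' @param frequency_mhz spectrometer proton frequency in MHz.
#' @param spectral_window_ppm width of the acquired window in ppm.
#' @param n_points number of complex points; must be a power of two.
#' @param n_scans number of accumulated scans (metadata only).
#' @param relaxation_delay_s inter-scan delay in seconds (metadata only).
#' @param line_broadening_hz exponential apodization strength in Hz.
#' @param carrier_ppm chemical shift at the centre of the window.
#' @return an object of class `acq_params`.
#' @examples
#' acq <- acq_params()
#' acq$n_points
#' @export
acq_params <- function(frequency_mhz = 500,
                       spectral_window_ppm = 16,
                       n_points = 65536L,
                       n_scans = 128L,
                       relaxation_delay_s = 1.5,
                       line_broadening_hz = 0.5,
                       carrier_ppm = 4.7) {
  if (!is_number(frequency_mhz) || frequency_mhz <= 0) {
    abort("frequency_mhz must be a positive number", "urinmr_validation_error")
  }
  if (!is_number(spectral_window_ppm) || spectral_window_ppm <= 0) {
    abort("spectral_window_ppm must be a positive number", "urinmr_validation_error")
  }
  if (!is_count(n_points) || n_points <= 0 ||
      bitwAnd(as.integer(n_points), as.integer(n_points) - 1L) != 0L) {
    abort("n_points must be a positive power of two", "urinmr_validation_error")
  }
  if (!is_number(line_broadening_hz) || line_broadening_hz < 0) {
    abort("line_broadening_hz must be >= 0", "urinmr_validation_error")
  }
  structure(
    list(
      frequency_mhz = frequency_mhz,
      spectral_window_ppm = spectral_window_ppm,
      n_points = as.integer(n_points),
      n_scans = as.integer(n_scans),
      relaxation_delay_s = relaxation_delay_s,
      line_broadening_hz = line_broadening_hz,
      carrier_ppm = carrier_ppm
    ),
    class = "acq_params"
  )
}

# Sweep width in Hz.
sw_hz <- function(acq) acq$spectral_window_ppm * acq$frequency_mhz

# Dwell time in seconds.
dwell_s <- function(acq) 1 / sw_hz(acq)

#' Chemical-shift axis for an acquisition
#'
#' Returns the ppm axis in the NMR display convention: descending from the
#' high-frequency (left) edge of the window to the low-frequency (right) edge,
#' centred on the carrier.
#'
#' @param acq an [acq_params()] object.
#' @return numeric vector of length `acq$n_points`, strictly decreasing.
#' @export
ppm_axis <- function(acq) {
  n <- acq$n_points
  f_hz <- (seq_len(n) - 1 - n / 2) * sw_hz(acq) / n # ascending
  rev(acq$carrier_ppm + f_hz / acq$frequency_mhz)
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("<acq_params> %g MHz, %g ppm window, %d points, lb %g Hz, carrier %g ppm\n",
              x$frequency_mhz, x$spectral_window_ppm, x$n_points,
              x$line_broadening_hz, x$carrier_ppm))
  invisible(x)
}
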