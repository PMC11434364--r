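# FID -> phased, baseline-corrected, ppm-calibrated absorptive spectrum.

new_spectrum <- function(intensity, cplx, ppm, acq, sample_id,
                         phase0 = 0, phase1 = 0, calibrated = FALSE) {
  structure(list(intensity = intensity, cplx = cplx, ppm = ppm, acq = acq,
                 phase0 = phase0, phase1 = phase1, calibrated = calibrated,
                 sample_id = sample_id),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> '%s': %d points, %.2f..%.2f ppm, phase (%.1f, %.1f) deg%s\n",
              x$sample_id, length(x$intensity), x$ppm[1], x$ppm[length(x$ppm)],
              x$phase0, x$phase1,
              if (x$calibrated) ", calibrated" else ""))
  invisible(x)
}

#' Apodize and Fourier-transform a FID
#'
#' Multiplies the FID by a decaying exponential `exp(-pi * lb * t)` (adding
#' `lb` Hz to every Lorentzian linewidth), zero-fills to the acquisition's
#' point count, halves the first point (the standard discrete-FT convention
#' that removes the baseline offset), and Fourier-transforms. The real part
#' becomes the spectrum intensity; the complex spectrum is retained for
#' phasing. Phases are initialized to zero and the ppm axis is descending.
#'
#' @param fid an `nmr_fid`.
#' @return an uncalibrated `nmr_spectrum` of length `acq$n_points`.
#' @export
apodize_and_transform <- function(fid) {
  stopifnot(inherits(fid, "nmr_fid"))
  sig <- fid$signal
  if (length(sig) == 0) {
    abort("FID is empty", "urinmr_validation_error")
  }
  if (any(!is.finite(Re(sig))) || any(!is.finite(Im(sig)))) {
    abort("FID contains non-finite values", "urinmr_validation_error")
  }
  acq <- fid$acq
  n <- acq$n_points
  if (length(sig) > n) {
    abort("FID longer than acq$n_points", "urinmr_validation_error")
  }
  t <- (seq_along(sig) - 1) * dwell_s(acq)
  sig <- sig * exp(-pi * acq$line_broadening_hz * t)
  if (length(sig) < n) sig <- c(sig, complex(length.out = n - length(sig)))
  sig[1] <- sig[1] / 2
  spec_c <- stats::fft(sig)
  # reorder: fftshift to ascending frequency, then reverse to descending ppm
  shift <- c((n / 2 + 1):n, 1:(n / 2))
  cplx <- rev(spec_c[shift])
  new_spectrum(Re(cplx), cplx, ppm_axis(acq), acq, fid$sample_id)
}

#' Apply zero- and first-order phase to a spectrum
#'
#' Rotates the retained complex spectrum by
#' `phase0 + phase1 * (i/n - pivot)` degrees, with the pivot at the centre of
#' the axis, and updates the real intensities. The `phase0`/`phase1` fields
#' accumulate the total phase applied since transformation.
#'
#' @param spec an `nmr_spectrum` that still carries its complex part.
#' @param phase0 zero-order phase in degrees.
#' @param phase1 first-order (linear) phase in degrees across the window.
#' @param pivot pivot position as a fraction of the axis (default centre).
#' @return the rotated spectrum.
#' @export
apply_phase <- function(spec, phase0, phase1 = 0, pivot = 0.5) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  if (is.null(spec$cplx)) {
    abort("spectrum no longer carries its complex part; phase before baseline correction",
          "urinmr_validation_error")
  }
  n <- length(spec$cplx)
  frac <- (seq_len(n) / n) - pivot
  theta <- (phase0 + phase1 * frac) * pi / 180
  spec$cplx <- spec$cplx * exp(1i * theta)
  spec$intensity <- Re(spec$cplx)
  spec$phase0 <- spec$phase0 + phase0
  spec$phase1 <- spec$phase1 + phase1
  spec
}

# Strong line centres for phasing: local maxima of the phase-invariant
# modulus, outside the residual-water neighbourhood (whose broad noisy top
# spawns spurious maxima), thinned greedily (strongest first) only enough
# to avoid duplicate maxima of one line. All lines of a multiplet are
# deliberately kept: the dispersion of a line's sibling biases the two
# window sums antisymmetrically, so the pair cancels in the phase fit.
phase_line_centers <- function(mod, ppm, min_sep_pts, rel_threshold = 0.003,
                               exclude = c(4.55, 5.05), max_lines = 48L) {
  centers <- which(diff(sign(diff(mod))) == -2) + 1L
  centers <- centers[mod[centers] >= rel_threshold * max(mod)]
  if (!is.null(ppm)) {
    centers <- centers[ppm[centers] < exclude[1] | ppm[centers] > exclude[2]]
  }
  centers <- centers[order(mod[centers], decreasing = TRUE)]
  kept <- integer()
  for (i in centers) {
    if (length(kept) >= max_lines) break
    if (!length(kept) || all(abs(kept - i) >= min_sep_pts)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Automatic phase correction
#'
#' Estimates zero- and first-order phase without an operator. The local
#' phase error of every strong line is read off at its centre: line centres
#' are local maxima of the phase-invariant modulus, refined to sub-grid
#' position by parabolic interpolation, and the complex spectrum value at
#' the refined centre (quadratic interpolation through the three
#' surrounding points) has argument equal to the local phase error, because
#' the dispersion component vanishes at an in-phase line's centre. A
#' weighted circular regression of these local phases on axis position then
#' yields the two phase orders: for each candidate linear coefficient the
#' optimal zero-order term is the circular mean (closed form), and the
#' linear coefficient is found by a one-dimensional search. One
#' outlier-rejection pass guards against centres sitting on dispersion
#' tails of distant strong lines rather than on true line centres. The
#' residual-water neighbourhood is excluded throughout.
#'
#' @param spec an `nmr_spectrum` carrying its complex part.
#' @param max_phase1 search bound (degrees) on the first-order term.
#' @return the phased spectrum; `phase0`/`phase1` accumulate the correction.
#' @export
auto_phase <- function(spec, max_phase1 = 180) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  if (all(spec$intensity == 0) &&
      (is.null(spec$cplx) || all(Mod(spec$cplx) == 0))) {
    return(spec)
  }
  if (is.null(spec$cplx)) {
    abort("spectrum no longer carries its complex part; cannot re-phase",
          "urinmr_validation_error")
  }
  n <- length(spec$cplx)
  h_hz <- sw_hz(spec$acq) / n
  min_sep <- max(3L, as.integer(round(3 / h_hz)))
  mod <- Mod(spec$cplx)
  centers <- phase_line_centers(mod, spec$ppm, min_sep_pts = min_sep)
  centers <- centers[centers > 1L & centers < n]
  if (!length(centers)) return(spec)

  zl <- vapply(centers, function(i) {
    # Sub-grid refinement exploiting the Lorentzian form: 1/|c|^2 is an
    # exact parabola in position and 1/c is exactly linear across an
    # isolated line, so the centre and the complex value there follow from
    # low-order interpolation of those transforms.
    q <- 1 / mod[(i - 1L):(i + 1L)]^2
    denom <- q[1] - 2 * q[2] + q[3]
    t <- if (denom > 0) 0.5 * (q[1] - q[3]) / denom else 0
    t <- max(-0.5, min(0.5, t))
    u <- 1 / spec$cplx[(i - 1L):(i + 1L)]
    u_hat <- u[1] * t * (t - 1) / 2 + u[2] * (1 - t^2) + u[3] * t * (t + 1) / 2
    1 / u_hat
  }, complex(1))
  phi <- Arg(zl)                 # local phase error per line, radians
  wl <- Mod(zl)
  fracl <- (centers / n) - 0.5

  # Weak lines riding on a strong neighbour's dispersion tail report a
  # biased local phase; restrict the fit to lines carrying a meaningful
  # share of the total weight (with a fallback for sparse spectra).
  strong <- wl >= 0.01 * sum(wl)
  if (sum(strong) < 3) {
    strong <- rank(-wl) <= 5
  }
  phi <- phi[strong]; wl <- wl[strong]; fracl <- fracl[strong]

  fit_p0 <- function(p1) {
    s <- sum(wl * exp(1i * (phi + p1 * fracl * pi / 180)))
    list(p0 = -Arg(s) * 180 / pi, value = Mod(s))
  }
  search <- function() {
    grid <- seq(-max_phase1, max_phase1, by = 2)
    vals <- vapply(grid, function(p1) fit_p0(p1)$value, numeric(1))
    p1_0 <- grid[which.max(vals)]
    opt <- stats::optimize(function(p1) -fit_p0(p1)$value,
                           interval = c(p1_0 - 2, p1_0 + 2), tol = 1e-8)
    p1 <- opt$minimum
    c(p0 = fit_p0(p1)$p0, p1 = p1)
  }
  par <- search()
  # Robust rejection: lines inconsistent with the fitted ramp (typically
  # sitting on a strong neighbour's dispersion tail) are dropped and the
  # ramp refitted.
  for (pass in 1:2) {
    resid <- Arg(exp(1i * (phi + (par[1] + par[2] * fracl) * pi / 180)))
    keep <- abs(resid) <= 10 * pi / 180
    if (sum(keep) < 3 || all(keep)) break
    phi <- phi[keep]; wl <- wl[keep]; fracl <- fracl[keep]
    par <- search()
  }
  p0 <- ((par[1] + 180) %% 360) - 180
  apply_phase(spec, p0, par[2])
}

# Cache of sparse system templates for the asymmetric least-squares smoother,
# keyed by (n, lambda).
.als_env <- new.env(parent = emptyenv())

als_system <- function(n, lambda) {
  key <- sprintf("%d_%g", n, lambda)
  sys <- .als_env[[key]]
  if (is.null(sys)) {
    # second-difference operator, built directly for speed
    i <- rep(seq_len(n - 2L), 3L)
    j <- c(seq_len(n - 2L), seq_len(n - 2L) + 1L, seq_len(n - 2L) + 2L)
    D <- Matrix::sparseMatrix(i = i, j = j,
                              x = rep(c(1, -2, 1), each = n - 2L),
                              dims = c(n - 2L, n))
    A <- methods::as(lambda * Matrix::crossprod(D) + Matrix::Diagonal(n),
                     "CsparseMatrix")
    col <- rep(seq_len(n), diff(A@p))
    pos <- which(A@i + 1L == col)
    sys <- list(A = A, pos = pos, dtd_diag = A@x[pos] - 1)
    .als_env[[key]] <- sys
  }
  sys
}

#' Asymmetric least-squares baseline estimate
#'
#' Whittaker smoother with asymmetric weights (weight `p` above the current
#' baseline, `1 - p` below), the standard peak-preserving baseline model for
#' spectra whose peaks all point one way. `lambda` controls smoothness on
#' the reference 65,536-point grid and is internally rescaled by
#' `(n/65536)^4` so the smoothing bandwidth is the same in ppm units at any
#' digital resolution. With point noise present the asymmetric weights make
#' the estimate ride slightly below the noise mean; window integration in
#' the quantification stage removes that smooth offset again through its
#' local linear baseline.
#'
#' @param y numeric vector of intensities.
#' @param lambda smoothness penalty on the 65,536-point reference grid.
#' @param p asymmetry parameter in (0, 1); small values hug the minima.
#' @param max_iter maximum reweighting iterations.
#' @return the estimated baseline, same length as `y`.
#' @export
als_baseline <- function(y, lambda = 1e10, p = 0.01, max_iter = 10L) {
  n <- length(y)
  lambda_eff <- lambda * (n / 65536)^4
  sys <- als_system(n, lambda_eff)
  A <- sys$A
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    A@x[sys$pos] <- sys$dtd_diag + w
    # drop any factorization cached in place by a previous solve: it does
    # not track the modified matrix entries
    A@factors <- list()
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  z
}

#' Baseline correction
#'
#' Estimates a slowly varying baseline by asymmetric least squares (see
#' [als_baseline()]) and subtracts it. Narrow peaks are preserved; constant
#' offsets and slow drifts are removed. The complex part of the spectrum is
#' dropped: phasing must precede baseline correction.
#'
#' @param spec a phased `nmr_spectrum`.
#' @param lambda,p,max_iter smoother parameters, see [als_baseline()].
#' @return the corrected spectrum.
#' @export
baseline_correct <- function(spec, lambda = 1e10, p = 0.01, max_iter = 10L) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  base <- als_baseline(spec$intensity, lambda = lambda, p = p,
                       max_iter = max_iter)
  spec$intensity <- spec$intensity - base
  spec$cplx <- NULL
  spec
}

#' Chemical-shift calibration on the TSP reference
#'
#' Locates the maximum within a search window around 0 ppm and shifts the
#' ppm axis so that maximum sits exactly at 0.00 ppm. Calibration fails
#' (with a `urinmr_calibration_error`) if no peak rises convincingly above
#' the noise floor, estimated from a signal-free region at the left edge of
#' the spectrum.
#'
#' @param spec an `nmr_spectrum`.
#' @param search_window half-width (ppm) of the search interval around 0.
#' @param noise_region ppm interval assumed signal-free for the noise floor.
#' @param snr_min minimum peak height in noise-sd units.
#' @return the calibrated spectrum (`calibrated = TRUE`).
#' @export
calibrate_ppm <- function(spec, search_window = 0.5,
                          noise_region = c(9.7, 10.5), snr_min = 10) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  win <- which(abs(spec$ppm) <= search_window)
  if (!length(win)) {
    abort("search window around 0 ppm lies outside the spectrum",
          "urinmr_calibration_error")
  }
  peak <- win[which.max(spec$intensity[win])]
  height <- spec$intensity[peak]
  noise_idx <- which(spec$ppm >= noise_region[1] & spec$ppm <= noise_region[2])
  sigma <- if (length(noise_idx) > 10) stats::mad(spec$intensity[noise_idx]) else 0
  floor_abs <- 1e-3 * max(abs(spec$intensity))
  if (!is.finite(height) || height <= 0 ||
      height <= snr_min * sigma || height <= floor_abs) {
    abort("no reference peak above the noise threshold near 0 ppm",
          "urinmr_calibration_error")
  }
  spec$ppm <- spec$ppm - spec$ppm[peak]
  spec$calibrated <- TRUE
  spec
}

#' Full FID processing chain
#'
#' Composes [apodize_and_transform()], [auto_phase()], [baseline_correct()]
#' and [calibrate_ppm()], in that order, with their default settings.
#'
#' @param fid an `nmr_fid`.
#' @param phase run automatic phasing (disable only for synthetic FIDs known
#'   to be in pure absorption).
#' @param lambda,p baseline smoother parameters.
#' @param search_window,snr_min calibration parameters.
#' @return a calibrated `nmr_spectrum`.
#' @export
process_fid <- function(fid, phase = TRUE, lambda = 1e10, p = 0.01,
                        search_window = 0.5, snr_min = 10) {
  spec <- apodize_and_transform(fid)
  if (phase) spec <- auto_phase(spec)
  spec <- baseline_correct(spec, lambda = lambda, p = p)
  calibrate_ppm(spec, search_window = search_window, snr_min = snr_min)
}
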