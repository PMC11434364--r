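# Shared fixtures: everything is generated in code at test time.

default_lib <- generate_metabolite_library()

# Small, well-resolved acquisition for fast tests: a short acquisition of a
# rapidly decaying signal, zero-filled onto a finer grid.
test_acq <- function(n_points = 16384L) acq_params(n_points = n_points)

test_t2 <- 0.15

# A quiet multi-singlet sample whose lines are isolated and spread across
# the axis; the workhorse for phasing and calibration tests.
singlet_panel_fid <- function(acq = acq_params(n_points = 32768L),
                              seed = 3, noise_sd = 0.002) {
  simulate_fid(c(Formate = 0.5, Sarcosine = 0.5, Creatinine = 2,
                 Acetate = 0.5, Trigonelline = 0.3),
               acq, default_lib, seed = seed, t2_s = test_t2,
               noise_sd = noise_sd, water = list(amplitude = 0),
               n_acquire = 6144L)
}

# Fully processed small spectrum carrying the whole default panel.
panel_spectrum <- function(seed = 5, jitter_sd = 0, noise_sd = 0,
                           water_amplitude = 50,
                           acq = test_acq(), concentrations = NULL) {
  if (is.null(concentrations)) {
    concentrations <- default_base_concentrations() * 0.9
  }
  fid <- simulate_fid(concentrations, acq, default_lib,
                      jitter_sd = jitter_sd, noise_sd = noise_sd,
                      seed = seed, t2_s = test_t2,
                      water = list(amplitude = water_amplitude, cv = 0))
  process_fid(fid)
}

# Reduced-size cohort design used by unit tests (the full 65,536-point
# design is exercised in the acceptance suite).
reduced_design <- function(...) {
  cohort_design(acq = acq_params(n_points = 16384L), t2_s = test_t2, ...)
}

# Independent trapezoid oracle (plain grid trapezoid with linear edge
# interpolation), kept separate from the package's integration code.
oracle_trapz <- function(ppm, y, lo, hi) {
  o <- order(ppm)
  ppm <- ppm[o]; y <- y[o]
  xs <- sort(unique(c(lo, hi, ppm[ppm > lo & ppm < hi])))
  ys <- stats::approx(ppm, y, xout = xs)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

# Numeric full-width-at-half-maximum of the tallest peak, by linear
# interpolation of the half-height crossings (in Hz).
oracle_fwhm_hz <- function(spec) {
  i0 <- which.max(spec$intensity)
  half <- spec$intensity[i0] / 2
  f_hz <- spec$ppm * spec$acq$frequency_mhz
  lo <- i0
  while (spec$intensity[lo] > half) lo <- lo - 1L
  hi <- i0
  while (spec$intensity[hi] > half) hi <- hi + 1L
  f_left <- stats::approx(spec$intensity[c(lo, lo + 1L)],
                          f_hz[c(lo, lo + 1L)], xout = half)$y
  f_right <- stats::approx(spec$intensity[c(hi - 1L, hi)],
                           f_hz[c(hi - 1L, hi)], xout = half)$y
  abs(f_left - f_right)
}

# True per-signal concentrations (mg/mL) implied by a cohort's truth matrix.
true_signal_mg <- function(cohort, lib = default_lib) {
  cmp <- vapply(lib$entries, `[[`, character(1), "compound")
  mw <- vapply(lib$entries, `[[`, numeric(1), "mw")
  out <- cohort$truth[, cmp, drop = FALSE] %*% diag(mw / 1000)
  colnames(out) <- names(lib$entries)
  out
}
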