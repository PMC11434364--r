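# Internal helpers shared across modules.

abort <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "urinmr_error"), ...))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Round half away from zero
#'
#' Predictive-value arithmetic uses conventional rounding (0.5 rounds up),
#' not the round-half-even rule of [base::round()].
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Trapezoidal integral of a tabulated curve over an exact ppm window
#'
#' The ppm axis may be descending (NMR convention). Window edges that fall
#' between grid points are handled by linear interpolation, so integrals over
#' adjacent windows telescope exactly: the sum over a partition equals the
#' integral over its union.
#'
#' @param ppm numeric axis, strictly monotone.
#' @param y intensities, same length as `ppm`.
#' @param lo,hi window limits in ppm, `lo < hi`.
#' @return the integral of `y` over `[lo, hi]` in intensity x ppm units.
#' @keywords internal
trapz_window <- function(ppm, y, lo, hi) {
  if (!is_number(lo) || !is_number(hi) || lo >= hi) {
    abort("integration window must satisfy lo < hi", "urinmr_validation_error")
  }
  n <- length(ppm)
  descending <- ppm[1] > ppm[n]
  # subset to the window neighbourhood (plus one bracketing point per side
  # for edge interpolation) before any reordering, so the cost does not
  # scale with the full axis length
  sel <- which(if (descending) ppm <= hi & ppm >= lo else
                 ppm >= lo & ppm <= hi)
  if (length(sel)) {
    sub <- max(1L, min(sel) - 1L):min(n, max(sel) + 1L)
  } else {
    after <- if (descending) which(ppm < lo) else which(ppm > hi)
    if (!length(after) || after[1] == 1L) return(0)
    sub <- (after[1] - 1L):after[1]
  }
  ppm <- ppm[sub]
  y <- y[sub]
  if (descending) {
    ppm <- rev(ppm)
    y <- rev(y)
  }
  lo <- max(lo, ppm[1])
  hi <- min(hi, ppm[length(ppm)])
  if (lo >= hi) return(0)
  inside <- which(ppm > lo & ppm < hi)
  y_lo <- stats::approx(ppm, y, xout = lo, rule = 2)$y
  y_hi <- stats::approx(ppm, y, xout = hi, rule = 2)$y
  xs <- c(lo, ppm[inside], hi)
  ys <- c(y_lo, y[inside], y_hi)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

#' @noRd
check_named_list <- function(x, allowed, required = character(), where = "config") {
  if (!is.list(x)) {
    abort(sprintf("%s must be a list", where), "urinmr_validation_error")
  }
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown %s field(s): %s", where, paste(unknown, collapse = ", ")),
          "urinmr_validation_error")
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("%s is missing required section(s): %s", where,
                  paste(missing, collapse = ", ")),
          "urinmr_validation_error")
  }
  invisible(x)
}

# Derive a bounded stage seed from a user seed; keeps every derived seed a
# valid 32-bit integer.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + offset) %% .Machine$integer.max)
}
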