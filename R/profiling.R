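# Untargeted profiling: fixed-width binning with water exclusion, and PCA.

#' Binning configuration
#'
#' Fixed-width bucketing of a calibrated spectrum. Bin edges are anchored at
#' integer multiples of the bin width counted from 0 ppm, so the default
#' residual-water exclusion (4.65-4.95 ppm) lands exactly on whole bins.
#'
#' @param bin_width bin width in ppm.
#' @param exclusions list of `c(low, high)` ppm intervals flagged as
#'   excluded (bins intersecting one are kept in the table but masked).
#' @param ppm_range analysis limits `c(low, high)`; the default covers the
#'   metabolite region and leaves out the TSP reference.
#' @return an object of class `binning_config`.
#' @export
binning_config <- function(bin_width = 0.05,
                           exclusions = list(c(4.65, 4.95)),
                           ppm_range = c(0.5, 9.5)) {
  if (!is_number(bin_width) || bin_width <= 0) {
    abort("bin_width must be > 0", "urinmr_validation_error")
  }
  if (ppm_range[1] >= ppm_range[2]) {
    abort("ppm_range must satisfy low < high", "urinmr_validation_error")
  }
  for (ex in exclusions) {
    if (ex[1] >= ex[2]) {
      abort("exclusion intervals must satisfy low < high", "urinmr_validation_error")
    }
    if (ex[1] < ppm_range[1] || ex[2] > ppm_range[2]) {
      abort("exclusion intervals must lie within ppm_range", "urinmr_validation_error")
    }
  }
  structure(list(bin_width = bin_width, exclusions = exclusions,
                 ppm_range = ppm_range),
            class = "binning_config")
}

bin_edges <- function(cfg) {
  w <- cfg$bin_width
  lo <- ceiling(cfg$ppm_range[1] / w - 1e-9) * w
  hi <- floor(cfg$ppm_range[2] / w + 1e-9) * w
  seq(lo, hi, by = w)
}

#' Bin one spectrum
#'
#' Integrates the intensity over consecutive `bin_width`-ppm intervals by the
#' trapezoidal rule (window edges interpolated, so bins telescope: the sum of
#' a run of bins equals the integral over their union). Bins whose interior
#' intersects an exclusion interval are flagged, not dropped.
#'
#' @param spec a calibrated `nmr_spectrum`.
#' @param cfg a [binning_config()].
#' @return list with `values` (one integral per bin), `edges` (length
#'   `nbins + 1`), and `included` (logical mask, `FALSE` for excluded bins).
#' @export
bin_spectrum <- function(spec, cfg = binning_config()) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  if (!isTRUE(spec$calibrated)) {
    abort("spectrum must be calibrated before binning", "urinmr_validation_error")
  }
  edges <- bin_edges(cfg)
  nb <- length(edges) - 1L
  values <- vapply(seq_len(nb), function(i) {
    trapz_window(spec$ppm, spec$intensity, edges[i], edges[i + 1])
  }, numeric(1))
  included <- rep(TRUE, nb)
  # overlap must be of positive length (tolerance guards shared edges
  # against floating-point representation of the 0.05 grid)
  for (ex in cfg$exclusions) {
    included <- included &
      !(edges[-length(edges)] < ex[2] - 1e-9 & edges[-1] > ex[1] + 1e-9)
  }
  list(values = values, edges = edges, included = included)
}

#' Bin a set of spectra into a sample-by-bin table
#'
#' @param spectra list of calibrated `nmr_spectrum` objects.
#' @param cfg a [binning_config()].
#' @return an object of class `bin_table`: `matrix` (samples x bins),
#'   `edges`, `included`, `sample_ids`.
#' @export
bin_spectra <- function(spectra, cfg = binning_config()) {
  rows <- lapply(spectra, bin_spectrum, cfg = cfg)
  mat <- do.call(rbind, lapply(rows, `[[`, "values"))
  edges <- rows[[1]]$edges
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  colnames(mat) <- sprintf("bin_%.3f", centers)
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  rownames(mat) <- ids
  structure(list(matrix = mat, edges = edges, included = rows[[1]]$included,
                 sample_ids = ids),
            class = "bin_table")
}

#' Principal component analysis of a bin table
#'
#' Unsupervised PCA of the sample-by-bin matrix: excluded bins are dropped
#' from the fitted matrix, columns are mean-centred (no unit-variance
#' scaling by default), and the decomposition is computed by singular value
#' decomposition via [stats::prcomp()].
#'
#' @param bins a [bin_spectra()] table.
#' @param n_components number of components to return; truncated (with a
#'   warning) if it exceeds the matrix rank.
#' @param scale. scale columns to unit variance before decomposition.
#' @return an object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (bins x components, orthonormal), `explained_variance`
#'   (per component, non-increasing; sums to the total column variance over
#'   the full decomposition), `proportion` (fraction of total variance).
#' @export
pca_bins <- function(bins, n_components = 2L, scale. = FALSE) {
  stopifnot(inherits(bins, "bin_table"))
  x <- bins$matrix[, bins$included, drop = FALSE]
  if (nrow(x) < 2) {
    abort("PCA requires at least 2 samples", "urinmr_validation_error")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  rank <- sum(fit$sdev > fit$sdev[1] * 1e-12)
  if (n_components > rank) {
    warning(sprintf("n_components = %d exceeds the matrix rank %d; truncating",
                    n_components, rank))
    n_components <- rank
  }
  keep <- seq_len(n_components)
  structure(
    list(scores = fit$x[, keep, drop = FALSE],
         loadings = fit$rotation[, keep, drop = FALSE],
         explained_variance = fit$sdev[keep]^2,
         proportion = fit$sdev[keep]^2 / sum(fit$sdev^2),
         total_variance = sum(fit$sdev^2)),
    class = "pca_result"
  )
}
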