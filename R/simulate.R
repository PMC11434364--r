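#' Simulate a free induction decay for one urine sample
#'
#' Builds the complex time-domain signal of a 1D proton spectrum as a sum of
#' exponentially decaying complex sinusoids, one per resonance line of every
#' compound present: amplitude proportional to in-tube concentration times
#' proton count (times the line's multiplet weight), frequency set by the
#' line's chemical shift relative to the carrier. Each compound's lines share
#' one random chemical-shift jitter per call (all signals of a compound move
#' together, as pH-driven shifts do). A broad residual-water resonance and
#' complex white noise are added on top. The TSP reference singlet is always
#' included at `tsp_mm` unless that is zero.
#'
#' @param concentrations named numeric vector, in-tube concentration (mM) per
#'   compound; names must be library compounds; values must be >= 0.
#' @param acq an [acq_params()] object.
#' @param lib a metabolite library from [generate_metabolite_library()].
#' @param jitter_sd standard deviation (ppm) of the per-compound shift jitter.
#' @param noise_sd standard deviation of the additive white noise on each of
#'   the real and imaginary channels, per point, in amplitude units
#'   (mM x protons).
#' @param seed integer seed; the call is fully deterministic given it.
#' @param tsp_mm in-tube TSP concentration (mM); the default 0.58 mM follows
#'   from a 5.8 mM stock diluted 70/700 into the tube.
#' @param water residual-water component: list with `amplitude` (same units
#'   as metabolite amplitudes; 0 suppresses the component), `center_ppm`, and
#'   `width_hz` (full width at half maximum; broad relative to metabolite
#'   lines), and `cv` (relative per-call amplitude variability).
#' @param t2_s effective transverse relaxation time of metabolite lines in
#'   seconds; the natural linewidth is `1/(pi * t2_s)` Hz.
#' @param n_acquire number of time-domain points actually synthesized
#'   (default: all of `acq$n_points`). A short acquisition of an
#'   already-decayed signal is zero-filled to `acq$n_points` during
#'   processing, the usual way to interpolate the digital grid cheaply.
#' @param sample_id identifier stored on the FID.
#' @return an object of class `nmr_fid`: list with `signal` (complex vector
#'   of length `acq$n_points`), `acq`, `sample_id`.
#' @examples
#' lib <- generate_metabolite_library()
#' acq <- acq_params(n_points = 4096L)
#' fid <- simulate_fid(c(Sarcosine = 0.5), acq, lib, seed = 1)
#' length(fid$signal)
#' @export
simulate_fid <- function(concentrations, acq, lib,
                         jitter_sd = 0, noise_sd = 0, seed = NULL,
                         tsp_mm = 0.58,
                         water = list(amplitude = 50, center_ppm = 4.79,
                                      width_hz = 18, cv = 0),
                         t2_s = 0.8, n_acquire = NULL, sample_id = "sample") {
  stopifnot(inherits(acq, "acq_params"), inherits(lib, "metabolite_library"))
  if (length(concentrations) && is.null(names(concentrations))) {
    abort("concentrations must be a named vector", "urinmr_validation_error")
  }
  if (any(concentrations < 0)) {
    abort("concentrations must be >= 0", "urinmr_validation_error")
  }
  unknown <- setdiff(names(concentrations), library_compounds(lib))
  if (length(unknown)) {
    abort(sprintf("unknown compound name(s): %s", paste(unknown, collapse = ", ")),
          "urinmr_lookup_error")
  }
  water <- utils::modifyList(list(amplitude = 50, center_ppm = 4.79,
                                  width_hz = 18, cv = 0), as.list(water))
  if (!is.null(seed)) set.seed(seed)

  n <- if (is.null(n_acquire)) acq$n_points else min(acq$n_points,
                                                     as.integer(n_acquire))
  h <- dwell_s(acq)
  sig <- complex(length.out = n)

  # One shared shift jitter per compound (draw even at zero concentration so
  # the random stream is stable under concentration changes).
  compounds <- library_compounds(lib)
  jitters <- if (jitter_sd > 0) stats::rnorm(length(compounds), 0, jitter_sd)
             else numeric(length(compounds))
  names(jitters) <- compounds

  add_line <- function(amp, ppm, t2) {
    f_hz <- (ppm - acq$carrier_ppm) * acq$frequency_mhz
    z <- exp(complex(real = -h / t2, imaginary = 2 * pi * f_hz * h))
    amp * c(1 + 0i, cumprod(rep(z, n - 1L)))
  }

  for (entry in lib$entries) {
    conc <- concentrations[entry$compound]
    if (is.na(conc) || conc == 0) next
    dppm <- jitters[entry$compound]
    for (k in seq_len(nrow(entry$lines))) {
      amp <- conc * entry$protons * entry$lines$weight[k]
      sig <- sig + add_line(amp, entry$lines$ppm[k] + dppm, t2_s)
    }
  }
  if (tsp_mm > 0) {
    ref <- lib$reference
    sig <- sig + add_line(tsp_mm * ref$protons, ref$lines$ppm[1], t2_s)
  }
  if (water$amplitude > 0) {
    w_amp <- water$amplitude *
      if (water$cv > 0) stats::rlnorm(1, -log(1 + water$cv^2) / 2,
                                      sqrt(log(1 + water$cv^2))) else 1
    t2_w <- 1 / (pi * water$width_hz)
    sig <- sig + add_line(w_amp, water$center_ppm, t2_w)
  }
  if (noise_sd > 0) {
    sig <- sig + complex(real = stats::rnorm(n, 0, noise_sd),
                         imaginary = stats::rnorm(n, 0, noise_sd))
  }
  structure(list(signal = sig, acq = acq, sample_id = sample_id),
            class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> '%s': %d complex points, %g ppm window at %g MHz\n",
              x$sample_id, length(x$signal), x$acq$spectral_window_ppm,
              x$acq$frequency_mhz))
  invisible(x)
}

#' Design of a synthetic obesity cohort
#'
#' Encodes the statistical structure of the simulated study population:
#' 23 subjects with visceral fat in the 9-16 kg range and 52 above 16 kg
#' (75 in total), log-normal between-subject variation of urinary
#' concentrations, fold-change effects applied to the high-visceral-fat group
#' for sarcosine, trigonelline and phenylalanine (the default multipliers
#' 2.1, 2.5 and 2.0 echo the roughly two- to three-fold group mean ratios
#' reported for these markers), per-compound chemical-shift jitter, and
#' additive spectral noise.
#'
#' @param n_low_vf,n_high_vf group sizes (low: visceral fat 9-16 kg; high:
#'   > 16 kg). Both must be >= 2 for the downstream statistics to be defined.
#' @param base_concentrations named vector of median urinary concentrations
#'   (mM, in neat urine) per compound; defaults bundled with the package.
#' @param effect_multipliers named vector of fold-changes applied to the
#'   high-visceral-fat group; 1.0 leaves a compound null.
#' @param log_normal_cv coefficient of variation of the between-subject
#'   log-normal concentration distribution.
#' @param shift_jitter_sd per-compound chemical-shift jitter sd in ppm.
#' @param noise_sd additive complex noise sd per FID point (amplitude units).
#' @param anthropometrics named list of `c(mean, sd)` pairs for `age`,
#'   `bmi`, `abdominal_circumference`, `fat_percent`; plus `female_fraction`.
#' @param visceral_fat list with `low = c(mean, sd)` and `high = c(mean, sd)`
#'   of the truncated normal draws inside (9, 16] and (16, 28] kg. The
#'   defaults give a cohort mean near 17.5 kg.
#' @param acq acquisition parameters for the simulated FIDs.
#' @param sample_volume_ul,buffer_volume_ul volumes mixed into the NMR tube;
#'   the in-tube dilution factor is `sample/(sample + buffer)`.
#' @param tsp_stock_mm TSP concentration of the buffer stock (mM).
#' @param water residual-water component passed to [simulate_fid()].
#' @param t2_s effective T2 of metabolite lines (seconds).
#' @param synthesize_fids if `FALSE`, only concentrations and the subject
#'   table are generated (fast mode for statistical calibration studies).
#' @param seed integer seed.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_low_vf = 23L, n_high_vf = 52L,
                          base_concentrations = default_base_concentrations(),
                          effect_multipliers = c(Sarcosine = 2.1,
                                                 Trigonelline = 2.5,
                                                 Phenylalanine = 2.0),
                          log_normal_cv = 0.5,
                          shift_jitter_sd = 0.008,
                          noise_sd = 0.01,
                          anthropometrics = list(
                            age = c(38.3, 10),
                            bmi = c(34.81, 4.5),
                            abdominal_circumference = c(108, 12),
                            fat_percent = c(43.47, 6),
                            female_fraction = 0.72
                          ),
                          visceral_fat = list(low = c(14.0, 1.6),
                                              high = c(19.2, 2.0)),
                          acq = acq_params(),
                          sample_volume_ul = 630,
                          buffer_volume_ul = 70,
                          tsp_stock_mm = 5.8,
                          water = list(amplitude = 50, center_ppm = 4.79,
                                       width_hz = 18, cv = 0.2),
                          t2_s = 0.8,
                          synthesize_fids = TRUE,
                          seed = 20240491L) {
  if (!is_count(n_low_vf) || !is_count(n_high_vf) || n_low_vf < 2 || n_high_vf < 2) {
    abort("group sizes n_low_vf and n_high_vf must be integers >= 2",
          "urinmr_design_error")
  }
  if (any(effect_multipliers <= 0)) {
    abort("effect multipliers must be > 0", "urinmr_design_error")
  }
  if (log_normal_cv < 0) {
    abort("log_normal_cv must be >= 0", "urinmr_design_error")
  }
  structure(
    list(n_low_vf = as.integer(n_low_vf), n_high_vf = as.integer(n_high_vf),
         base_concentrations = base_concentrations,
         effect_multipliers = effect_multipliers,
         log_normal_cv = log_normal_cv,
         shift_jitter_sd = shift_jitter_sd, noise_sd = noise_sd,
         anthropometrics = anthropometrics, visceral_fat = visceral_fat,
         acq = acq, sample_volume_ul = sample_volume_ul,
         buffer_volume_ul = buffer_volume_ul, tsp_stock_mm = tsp_stock_mm,
         water = water, t2_s = t2_s,
         synthesize_fids = isTRUE(synthesize_fids), seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Default median urinary concentrations of the panel compounds
#'
#' Order-of-magnitude spot-urine values (mM in neat urine): abundant solutes
#' (urea, creatinine, citrate, hippurate) in the millimolar range, amino
#' acids and organic acids in the 0.05-0.5 mM range. Urea is set well below
#' its physiological tens-of-millimolar level to mimic the partial signal
#' loss its exchangeable protons suffer under water presaturation.
#'
#' @return named numeric vector (mM) with one entry per panel compound.
#' @export
default_base_concentrations <- function() {
  c(Valine = 0.05, `2-Methylglutarate` = 0.05, PropyleneGlycol = 0.05,
    `3-Hydroxybutyrate` = 0.06, Methylmalonate = 0.05,
    `3-Hydroxyisovalerate` = 0.04, Lactate = 0.15,
    `2-Hydroxyisobutyrate` = 0.06, Alanine = 0.30, Lipids = 0.10,
    Acetate = 0.15, Nacetylglucosamine = 0.10, Piruvate = 0.08,
    Citrate = 2.5, Sarcosine = 0.05, Creatinine = 10,
    AcetylcholineCholine = 0.06, Carnitine = 0.10, Methanol = 0.10,
    Creatine = 0.50, Glucose = 0.30, Urea = 50, Phenylalanine = 0.08,
    Hippurate = 2.0, Formate = 0.06, Trigonelline = 0.10)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws subject anthropometrics (visceral fat structured into the 9-16 kg
#' and > 16 kg groups), per-subject true urinary concentrations (log-normal
#' around the design's base values, with the design's fold-changes applied in
#' the high-visceral-fat group), and -- unless `design$synthesize_fids` is
#' `FALSE` -- one FID per subject at the in-tube dilution implied by the
#' design's volumes. The subject table records the true concentrations so
#' recovery of the quantification stage can be measured.
#'
#' @param design a [cohort_design()].
#' @return an object of class `nmr_cohort`: list with `fids` (list of
#'   `nmr_fid`, or `NULL` in fast mode), `subjects` (data.frame), `truth`
#'   (matrix of true urinary concentrations, mM, samples x compounds), and
#'   `design`.
#' @examples
#' d <- cohort_design(synthesize_fids = FALSE, seed = 1)
#' ch <- simulate_cohort(d)
#' nrow(ch$subjects)  # 75
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  n_lo <- design$n_low_vf
  n_hi <- design$n_high_vf
  n <- n_lo + n_hi
  high <- c(rep(FALSE, n_lo), rep(TRUE, n_hi))
  ids <- sprintf("S%03d", seq_len(n))

  vf <- numeric(n)
  vf[!high] <- rtruncnorm1(n_lo, design$visceral_fat$low[1],
                           design$visceral_fat$low[2], 9, 16)
  vf[high] <- rtruncnorm1(n_hi, design$visceral_fat$high[1],
                          design$visceral_fat$high[2], 16, 28)

  an <- design$anthropometrics
  subjects <- data.frame(
    id = ids,
    sex = ifelse(stats::runif(n) < an$female_fraction, "F", "M"),
    age = pmin(65, pmax(18, round(stats::rnorm(n, an$age[1], an$age[2])))),
    bmi = pmax(25.01, stats::rnorm(n, an$bmi[1], an$bmi[2])),
    abdominal_circumference = pmax(81, stats::rnorm(n, an$abdominal_circumference[1],
                                                    an$abdominal_circumference[2])),
    visceral_fat = vf,
    fat_percent = pmin(60, pmax(15, stats::rnorm(n, an$fat_percent[1],
                                                 an$fat_percent[2]))),
    stringsAsFactors = FALSE
  )

  base <- design$base_concentrations
  cv <- design$log_normal_cv
  sdlog <- sqrt(log(1 + cv^2))
  truth <- matrix(0, n, length(base), dimnames = list(ids, names(base)))
  for (cmp in names(base)) {
    mult <- ifelse(high, design$effect_multipliers[cmp], 1)
    mult[is.na(mult)] <- 1
    centre <- base[cmp] * mult
    truth[, cmp] <- if (cv > 0) {
      centre * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    } else centre
  }

  fids <- NULL
  if (design$synthesize_fids) {
    lib <- generate_metabolite_library(frequency_mhz = design$acq$frequency_mhz)
    dilution <- design$sample_volume_ul /
      (design$sample_volume_ul + design$buffer_volume_ul)
    tsp_mm <- design$tsp_stock_mm * design$buffer_volume_ul /
      (design$sample_volume_ul + design$buffer_volume_ul)
    fids <- lapply(seq_len(n), function(i) {
      simulate_fid(truth[i, ] * dilution, design$acq, lib,
                   jitter_sd = design$shift_jitter_sd,
                   noise_sd = design$noise_sd,
                   seed = stage_seed(design$seed, 1000L + i),
                   tsp_mm = tsp_mm, water = design$water,
                   t2_s = design$t2_s, sample_id = ids[i])
    })
    names(fids) <- ids
  }

  structure(list(fids = fids, subjects = subjects, truth = truth,
                 design = design),
            class = "nmr_cohort")
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat(sprintf("<nmr_cohort> %d subjects (%d low-VF / %d high-VF), %s\n",
              nrow(x$subjects), x$design$n_low_vf, x$design$n_high_vf,
              if (is.null(x$fids)) "concentrations only"
              else sprintf("%d FIDs of %d points", length(x$fids),
                           x$design$acq$n_points)))
  invisible(x)
}
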