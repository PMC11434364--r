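test_that("transform zero-fills to the acquisition size and keeps zero FIDs zero", {
  acq <- acq_params() # 65,536 points
  fid <- simulate_fid(c(Sarcosine = 0.5), acq, default_lib, seed = 1,
                      t2_s = test_t2, n_acquire = 1024L)
  spec <- apodize_and_transform(fid)
  expect_length(spec$intensity, 65536L)
  expect_length(spec$ppm, 65536L)
  expect_true(all(diff(spec$ppm) < 0)) # descending axis

  zero <- structure(list(signal = complex(1024), acq = test_acq(4096L),
                         sample_id = "z"), class = "nmr_fid")
  expect_true(all(apodize_and_transform(zero)$intensity == 0))
})

test_that("transform rejects empty or oversized FIDs", {
  acq <- test_acq(4096L)
  empty <- structure(list(signal = complex(0), acq = acq, sample_id = "e"),
                     class = "nmr_fid")
  expect_error(apodize_and_transform(empty), class = "urinmr_validation_error")
  long <- structure(list(signal = complex(8192), acq = acq, sample_id = "l"),
                    class = "nmr_fid")
  expect_error(apodize_and_transform(long), class = "urinmr_validation_error")
})

test_that("the Fourier step is linear", {
  acq <- test_acq(4096L)
  f1 <- simulate_fid(c(Sarcosine = 0.5), acq, default_lib, seed = 2,
                     t2_s = test_t2, tsp_mm = 0, water = list(amplitude = 0))
  f2 <- simulate_fid(c(Citrate = 1), acq, default_lib, seed = 3,
                     t2_s = test_t2, tsp_mm = 0, water = list(amplitude = 0))
  mix <- f1
  mix$signal <- 2 * f1$signal - 0.5 * f2$signal
  s_mix <- apodize_and_transform(mix)$intensity
  s_lin <- 2 * apodize_and_transform(f1)$intensity -
    0.5 * apodize_and_transform(f2)$intensity
  expect_equal(s_mix, s_lin, tolerance = 1e-9)
})

test_that("exponential apodization adds its width to a Lorentzian line", {
  acq <- acq_params() # lb = 0.5 Hz on the full grid
  t2 <- 0.8
  fid <- simulate_fid(c(Sarcosine = 1), acq, default_lib, seed = 1,
                      t2_s = t2, tsp_mm = 0, water = list(amplitude = 0))
  spec <- apodize_and_transform(fid)
  expected <- 1 / (pi * t2) + acq$line_broadening_hz
  expect_lt(abs(oracle_fwhm_hz(spec) - expected) / expected, 0.05)
})

test_that("automatic phasing is a fixed point on absorptive spectra", {
  spec <- apodize_and_transform(singlet_panel_fid())
  phased <- auto_phase(spec)
  expect_lt(abs(phased$phase0), 1)
  expect_lt(abs(phased$phase1), 2)
})

test_that("known phase errors are recovered", {
  spec <- apodize_and_transform(singlet_panel_fid())
  m30 <- apply_phase(spec, 30, 0)
  r30 <- auto_phase(m30)
  expect_lt(abs((r30$phase0 - m30$phase0) + 30), 1)

  m <- apply_phase(spec, 20, 40)
  r <- auto_phase(m)
  expect_lt(abs((r$phase0 - m$phase0) + 20), 2)
  expect_lt(abs((r$phase1 - m$phase1) + 40), 2)
})

test_that("an all-zero spectrum passes through phasing unchanged", {
  zero <- structure(list(signal = complex(256), acq = test_acq(4096L),
                         sample_id = "z"), class = "nmr_fid")
  spec <- apodize_and_transform(zero)
  phased <- auto_phase(spec)
  expect_identical(phased$phase0, 0)
  expect_identical(phased$phase1, 0)
})

test_that("baseline correction removes offsets and slow drifts but keeps peaks", {
  spec <- apodize_and_transform(singlet_panel_fid(noise_sd = 0))
  n <- length(spec$intensity)
  free <- spec$ppm > 5.7 & spec$ppm < 7.0 # signal-free region

  # constant offset
  off <- spec
  off$intensity <- spec$intensity + 100
  corr <- baseline_correct(off)
  expect_lt(abs(median(corr$intensity[free])), 1) # < 1% of the offset

  # slow sinusoidal drift
  drift <- spec
  amp <- 50
  drift$intensity <- spec$intensity + amp * sin(2 * pi * seq_len(n) / n * 3)
  corr2 <- baseline_correct(drift)
  base0 <- baseline_correct(spec)
  expect_lt(max(abs(corr2$intensity[free] - base0$intensity[free])), 0.05 * amp)

  # a genuinely isolated narrow peak keeps its integral
  iso <- apodize_and_transform(simulate_fid(
    c(Sarcosine = 0.5), acq_params(n_points = 32768L), default_lib,
    seed = 3, t2_s = test_t2, tsp_mm = 0, water = list(amplitude = 0),
    n_acquire = 6144L))
  iso_corr <- baseline_correct(iso)
  raw_int <- oracle_trapz(iso$ppm, iso$intensity, 2.705, 2.755)
  cor_int <- oracle_trapz(iso_corr$ppm, iso_corr$intensity, 2.705, 2.755)
  expect_lt(abs(cor_int - raw_int) / raw_int, 0.01)
})

test_that("calibration pins the reference to 0 ppm and is idempotent", {
  spec <- baseline_correct(auto_phase(apodize_and_transform(
    singlet_panel_fid())))
  shifted <- spec
  shifted$ppm <- spec$ppm + 0.02 # reference now sits at +0.02
  cal <- calibrate_ppm(shifted)
  grid_step <- abs(spec$ppm[1] - spec$ppm[2])
  win <- which(abs(cal$ppm) <= 0.1)
  peak_ppm <- cal$ppm[win[which.max(cal$intensity[win])]]
  expect_lt(abs(peak_ppm), grid_step / 2 + 1e-12)
  expect_true(cal$calibrated)

  cal2 <- calibrate_ppm(cal)
  expect_lt(max(abs(cal2$ppm - cal$ppm)), grid_step + 1e-12)
})

test_that("calibration fails without a reference peak", {
  acq <- test_acq(8192L)
  fid <- simulate_fid(c(Creatinine = 5), acq, default_lib, seed = 4,
                      t2_s = test_t2, tsp_mm = 0, water = list(amplitude = 0))
  spec <- apodize_and_transform(fid)
  expect_error(calibrate_ppm(spec), class = "urinmr_calibration_error")
})

test_that("process_fid equals its four stages applied in order", {
  fid <- simulate_fid(c(Sarcosine = 0.5, Creatinine = 5), test_acq(8192L),
                      default_lib, seed = 9, t2_s = test_t2,
                      noise_sd = 0.005, water = list(amplitude = 20, cv = 0))
  by_stages <- calibrate_ppm(baseline_correct(auto_phase(
    apodize_and_transform(fid))))
  composed <- process_fid(fid)
  expect_identical(composed$intensity, by_stages$intensity)
  expect_identical(composed$ppm, by_stages$ppm)

  # determinism of the whole chain
  fid2 <- simulate_fid(c(Sarcosine = 0.5, Creatinine = 5), test_acq(8192L),
                       default_lib, seed = 9, t2_s = test_t2,
                       noise_sd = 0.005, water = list(amplitude = 20, cv = 0))
  expect_identical(process_fid(fid2)$intensity, composed$intensity)
})
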