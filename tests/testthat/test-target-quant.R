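test_that("the configuration implies a 0.58 mM in-tube reference", {
  cfg <- quant_config()
  expect_equal(urinmr:::tsp_tube_mm(cfg), 5.8 * 70 / 700)
  expect_error(quant_config(sample_volume = 0), class = "urinmr_validation_error")
  expect_error(quant_config(tsp_stock_concentration = -1),
               class = "urinmr_validation_error")
})

test_that("alignment recovers injected shifts and clips at its bound", {
  cfg <- quant_config()
  spec <- panel_spectrum(seed = 8)
  grid_step <- abs(spec$ppm[1] - spec$ppm[2])

  # fixed point: unjittered spectrum
  al0 <- align_region(spec, library_entry(default_lib, "Sarcosine"), cfg)
  expect_lt(abs(al0$shift), grid_step + 1e-12)
  expect_identical(al0$flag, "aligned")

  # known +0.010 ppm displacement, via a library whose entry sits 0.010 low
  lib_lo <- generate_metabolite_library(
    overrides = list(Sarcosine = list(center_ppm = 2.73 - 0.010,
                                      window = c(2.695, 2.745))))
  al <- align_region(spec, library_entry(lib_lo, "Sarcosine"), cfg)
  expect_lt(abs(al$shift - 0.010), grid_step + 1e-12)

  # displacement beyond the bound clips (formate is isolated, so the
  # correlator has nothing closer to lock onto)
  lib_far <- generate_metabolite_library(
    overrides = list(Formate = list(center_ppm = 8.46 - 0.05,
                                    window = c(8.385, 8.435))))
  al_far <- align_region(spec, library_entry(lib_far, "Formate"), cfg)
  expect_identical(al_far$flag, "clipped")
  expect_equal(abs(al_far$shift), cfg$max_alignment_shift)
})

test_that("alignment validates its inputs", {
  cfg <- quant_config()
  spec <- panel_spectrum(seed = 8)
  uncal <- spec
  uncal$calibrated <- FALSE
  e <- library_entry(default_lib, "Sarcosine")
  expect_error(align_region(uncal, e, cfg), class = "urinmr_validation_error")
  e$window <- c(14, 14.2) # outside the spectrum
  expect_error(align_region(spec, e, cfg), class = "urinmr_validation_error")
})

test_that("a window of 20 linewidths captures at least 96% of a Lorentzian", {
  acq <- acq_params(n_points = 32768L)
  fid <- simulate_fid(c(Sarcosine = 1), acq, default_lib, seed = 1,
                      t2_s = test_t2, tsp_mm = 0, water = list(amplitude = 0),
                      n_acquire = 6144L)
  spec <- apodize_and_transform(fid)
  fwhm_ppm <- oracle_fwhm_hz(spec) / acq$frequency_mhz
  narrow <- integrate_region(spec, 2.73 + c(-20, 20) * fwhm_ppm)
  total <- integrate_region(spec, c(2.73 - 1.5, 2.73 + 1.5))
  expect_gte(narrow / total, 0.96)
})

test_that("integration is linear and behaves like noise on empty windows", {
  spec <- panel_spectrum(seed = 8)
  w <- c(2.705, 2.755)
  doubled <- spec
  doubled$intensity <- 2 * spec$intensity
  expect_equal(integrate_region(doubled, w), 2 * integrate_region(spec, w),
               tolerance = 1e-12)
  expect_error(integrate_region(spec, c(2, 2)), class = "urinmr_validation_error")
  expect_error(integrate_region(spec, c(13.9, 14.5)),
               class = "urinmr_validation_error")

  # pure-noise window: |integral| bounded by 3x its propagated sd
  acq <- test_acq(16384L)
  noise_fid <- simulate_fid(c(Sarcosine = 0), acq, default_lib, seed = 21,
                            noise_sd = 0.01, tsp_mm = 0,
                            water = list(amplitude = 0))
  nspec <- apodize_and_transform(noise_fid)
  sigma <- sd(nspec$intensity) # white in both domains
  h <- abs(nspec$ppm[1] - nspec$ppm[2])
  m <- sum(nspec$ppm >= 6.0 & nspec$ppm <= 6.5)
  analytic_sd <- sigma * h * sqrt(m)
  expect_lt(abs(integrate_region(nspec, c(6.0, 6.5))), 3 * analytic_sd)
})

test_that("integral ratios convert to mg/mL by the reference arithmetic", {
  expect_equal(concentration_from_integrals(0, 1, 3, 89.09), 0)
  # equal integrals, 3 protons, sarcosine: 0.58 * 3 * (700/630) * 89.09/1000
  expect_equal(concentration_from_integrals(1, 1, 3, 89.09),
               0.58 * 3 * (700 / 630) * 89.09 / 1000, tolerance = 1e-12)
  expect_error(concentration_from_integrals(1, 0, 3, 89.09),
               class = "urinmr_reference_error")
  expect_error(concentration_from_integrals(1, 1, 0, 89.09),
               class = "urinmr_validation_error")
  # negative integrals propagate, not floored
  expect_lt(concentration_from_integrals(-1, 1, 3, 89.09), 0)
})

test_that("panel quantification recovers a noiseless reduced cohort", {
  d <- reduced_design(n_low_vf = 4L, n_high_vf = 6L, shift_jitter_sd = 0,
                      noise_sd = 0, seed = 5,
                      water = list(amplitude = 50, cv = 0))
  ch <- simulate_cohort(d)
  spectra <- lapply(ch$fids, process_fid)
  conc <- quantify_panel(spectra, default_lib, quant_config())
  expect_identical(colnames(conc$matrix), names(default_lib$entries))
  rel <- conc$matrix / true_signal_mg(ch) - 1
  # the reduced grid's broader lines carry extra window-truncation bias;
  # the full-resolution accuracy bound lives in the acceptance suite
  expect_lt(median(abs(rel)), 0.05)
})

test_that("recovery ranks track the truth on the reduced default cohort", {
  d <- reduced_design()
  ch <- simulate_cohort(d)
  spectra <- lapply(ch$fids, process_fid)
  conc <- quantify_panel(spectra, default_lib, quant_config())
  tm <- true_signal_mg(ch)
  rho <- vapply(seq_len(ncol(conc$matrix)), function(j) {
    cor(conc$matrix[, j], tm[, j], method = "spearman")
  }, numeric(1))
  expect_gt(min(rho), 0.95)
})

test_that("concentrations are invariant to overall spectrum scale", {
  spec <- panel_spectrum(seed = 8)
  scaled <- spec
  scaled$intensity <- 7.3 * spec$intensity
  c1 <- quantify_panel(list(spec), default_lib, quant_config())
  c2 <- quantify_panel(list(scaled), default_lib, quant_config())
  expect_equal(c2$matrix, c1$matrix, tolerance = 1e-9)
})

test_that("raising one compound's concentration raises its estimate", {
  base <- default_base_concentrations() * 0.9
  up <- base
  up["Sarcosine"] <- up["Sarcosine"] * 1.5
  s1 <- panel_spectrum(seed = 4, concentrations = base)
  s2 <- panel_spectrum(seed = 4, concentrations = up)
  c1 <- quantify_panel(list(s1), default_lib, quant_config())
  c2 <- quantify_panel(list(s2), default_lib, quant_config())
  expect_gt(c2$matrix[1, "Sarcosine"], c1$matrix[1, "Sarcosine"])
})

test_that("samples without a usable reference are flagged, not dropped", {
  acq <- test_acq()
  good <- panel_spectrum(seed = 2, acq = acq)
  no_tsp_fid <- simulate_fid(default_base_concentrations() * 0.9, acq,
                             default_lib, seed = 3, t2_s = test_t2,
                             tsp_mm = 0, water = list(amplitude = 50, cv = 0),
                             noise_sd = 0.01, sample_id = "no_ref")
  bad <- apodize_and_transform(no_tsp_fid)
  bad <- baseline_correct(auto_phase(bad))
  bad$calibrated <- TRUE # force past calibration to exercise the TSP gate
  expect_warning(
    conc <- quantify_panel(list(good, bad), default_lib, quant_config()),
    "no_ref")
  expect_identical(conc$excluded, "no_ref")
  expect_true(all(is.na(conc$matrix["no_ref", ])))
  expect_false(anyNA(conc$matrix[1, ]))
})
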