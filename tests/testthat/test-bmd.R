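test_that("two-point internal calibration is exact at both reference points", {
  pair <- calibration_pair(hu_fat_ref = -100, hu_muscle_ref = 55,
                           density_fat_equiv = 0, density_muscle_equiv = 62)
  cal <- internal_calibration(muscle_roi_mean = 55, fat_roi_mean = -100, pair)
  expect_equal(cal$slope, 0.4)  # 62 mg/ml over 155 HU
  expect_equal(apply_calibration(cal, -100), 0)
  expect_equal(apply_calibration(cal, 55), 62)
  expect_error(internal_calibration(10, 10, pair), "degenerate")
  expect_error(calibration_pair(hu_fat_ref = 50, hu_muscle_ref = -100), "must exceed")
})

test_that("noiseless phantom BMD is recovered within 1 mg/ml", {
  sp <- bmd_spec(noise_sd_hu = 0, infiltration = 0, true_bmd_mg_ml = 100)
  ph <- build_phantom(sp)
  ls <- label_vertebrae(ph$volume$conventional, sp$spacing_mm)
  pair <- default_calibration_pair(sp$basis, sp$base_soft_fraction)
  conv <- ph$volume$conventional
  cal <- internal_calibration(mean(conv[ph$truth$muscle_ref_mask]),
                              mean(conv[ph$truth$fat_ref_mask]), pair)
  b <- measure_bmd(conv, ls, 3:5, NULL, cal)
  expect_equal(b$bmd_mg_ml, 100, tolerance = 0.01)
  expect_false(b$fallback_used)
  expect_equal(b$vertebrae_used, "3,4,5")
})

test_that("noisy-phantom BMD recovery has median absolute error below 5 mg/ml", {
  errs <- vapply(1:50, function(s) {
    true_bmd <- 70 + 3 * (s %% 20)
    sp <- bmd_spec(infiltration = 0, true_bmd_mg_ml = true_bmd, seed = 1000 + s)
    ph <- build_phantom(sp)
    ls <- label_vertebrae(ph$volume$conventional, sp$spacing_mm)
    pair <- default_calibration_pair(sp$basis, sp$base_soft_fraction)
    conv <- ph$volume$conventional
    cal <- internal_calibration(mean(conv[ph$truth$muscle_ref_mask]),
                                mean(conv[ph$truth$fat_ref_mask]), pair)
    measure_bmd(conv, ls, 3:5, NULL, cal)$bmd_mg_ml - true_bmd
  }, 1.0)
  expect_lt(stats::median(abs(errs)), 5)
})

test_that("a constant scanner-drift offset cancels in the in-body calibration", {
  sp <- bmd_spec(noise_sd_hu = 0, true_bmd_mg_ml = 90)
  ph <- build_phantom(sp)
  ls <- label_vertebrae(ph$volume$conventional, sp$spacing_mm)
  pair <- default_calibration_pair(sp$basis, sp$base_soft_fraction)
  bmd_at_drift <- function(offset) {
    conv <- ph$volume$conventional + offset
    cal <- internal_calibration(mean(conv[ph$truth$muscle_ref_mask]),
                                mean(conv[ph$truth$fat_ref_mask]), pair)
    measure_bmd(conv, ls, 3:5, NULL, cal)$bmd_mg_ml
  }
  expect_equal(bmd_at_drift(40), bmd_at_drift(0), tolerance = 1e-9)
  expect_equal(bmd_at_drift(-25), bmd_at_drift(0), tolerance = 1e-9)
})

test_that("a lesioned target vertebra triggers the caudal fallback", {
  # lesion centered in vertebra 4 (a default target, z range 56-70 mm)
  sp <- bmd_spec(noise_sd_hu = 0, true_bmd_mg_ml = 100,
                 lesions = list(list(center_mm = c(22, 22, 63), radius_mm = 5)))
  ph <- build_phantom(sp)
  lesion_mask <- ph$truth$label_map == -1L
  expect_gt(sum(lesion_mask), 0)
  ls <- label_vertebrae(ph$volume$conventional, sp$spacing_mm)
  pair <- default_calibration_pair(sp$basis, sp$base_soft_fraction)
  conv <- ph$volume$conventional
  cal <- internal_calibration(mean(conv[ph$truth$muscle_ref_mask]),
                              mean(conv[ph$truth$fat_ref_mask]), pair)
  b <- measure_bmd(conv, ls, 3:5, lesion_mask, cal)
  expect_true(b$fallback_used)
  expect_false(grepl("4", b$vertebrae_used))
  expect_true(grepl("2", b$vertebrae_used))
  expect_equal(b$bmd_mg_ml, 100, tolerance = 0.01)
  # with every measurable vertebra lesioned the measurement fails
  all_lesioned <- array(TRUE, dim(conv))
  expect_error(measure_bmd(conv, ls, 3:5, all_lesioned, cal), "no measurable")
})
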