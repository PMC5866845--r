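test_that("calibration recovers an exact line and absorbs constant offsets", {
  std <- data.frame(concentration_ug_per_L = c(0.0095, 0.76, 1.52),
                    response = 100 * c(0.0095, 0.76, 1.52))
  cal <- fit_calibration(std)
  expect_equal(cal$slope, 100)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$valid_range, c(0.0095, 1.52))
  # constant offset goes into the intercept, slope unchanged
  off <- std; off$response <- off$response + 37
  cal2 <- fit_calibration(off)
  expect_equal(cal2$slope, 100)
  expect_equal(cal2$intercept, 37)
})

test_that("blank correction subtracts the mean blank before fitting", {
  std <- data.frame(concentration_ug_per_L = c(0.0095, 0.7648, 1.52),
                    response = 50 + 250 * c(0.0095, 0.7648, 1.52))
  blk <- data.frame(response = c(49, 50, 51))
  cal <- fit_calibration(std, blk)
  expect_equal(cal$slope, 250, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$blank_response, 50)
})

test_that("calibration rejects degenerate designs", {
  expect_error(fit_calibration(
    data.frame(concentration_ug_per_L = c(1, 1, 2),
               response = c(1, 1, 2))), ">= 3 distinct")
  expect_error(fit_calibration(
    data.frame(concentration_ug_per_L = c(1, 2, 3),
               response = c(3, 2, 1))), "non-positive slope")
})

test_that("tetrol quantification inverts the calibration line and is linear", {
  std <- data.frame(concentration_ug_per_L = c(0.01, 0.5, 1.5),
                    response = 20 + 100 * c(0.01, 0.5, 1.5))
  cal <- fit_calibration(std)
  # a fitted standard point maps back to its concentration x 600 uL
  expect_equal(quantify_tetrol(20 + 100 * 0.5, cal), 0.5 * 600)
  # response at the intercept -> zero amount (flagged below range)
  expect_warning(amt0 <- quantify_tetrol(20, cal), "outside the calibration")
  expect_equal(amt0, 0)
  # doubling the blank-corrected response doubles the amount
  r1 <- 20 + 100 * 0.3
  r2 <- 20 + 2 * 100 * 0.3
  expect_equal(quantify_tetrol(r2, cal) / quantify_tetrol(r1, cal), 2)
})

test_that("adduct rate matches the independent mole-ratio conversion", {
  # oracle: (1000e-12 g / 320.34 g/mol) / (25e-6 g / 330 g/mol) * 1e8
  oracle <- (1000e-12 / 320.34) / (25e-6 / 330) * 1e8
  expect_equal(oracle, 4120.6, tolerance = 1e-4)
  expect_equal(adduct_rate(1000, 25), oracle)
  expect_equal(adduct_rate(0, 25), 0)
  # doubling the DNA mass halves the rate
  expect_equal(adduct_rate(1000, 50), oracle / 2)
  expect_error(adduct_rate(10, 0), "> 0")
  expect_warning(r <- adduct_rate(-5, 25), "truncated")
  expect_equal(r, 0)
})

test_that("the noiseless pipeline round-trips the configured adduct rates", {
  cfg <- synthetic_config(seed = 13, hplc_cv = 0)
  res <- suppressWarnings(quantify_adducts(simulate_hplc(cfg)))
  cal <- attr(res, "calibration")
  expect_equal(cal$slope, cfg$calib_slope, tolerance = 1e-9)
  expect_gte(cal$r_squared, 0.98)
  for (trt in names(cfg$true_adduct_rate)) {
    expect_equal(res$adduct_rate[res$treatment == trt],
                 cfg$true_adduct_rate[[trt]], tolerance = 1e-6)
  }
})

test_that("standards at the printed range endpoints recover a synthetic slope of 250", {
  cfg <- synthetic_config(seed = 2, hplc_cv = 0, calib_slope = 250)
  h <- simulate_hplc(cfg, n_standards = 3)
  expect_equal(range(h$concentration_ug_per_L[h$kind == "standard"]),
               c(0.0095, 1.52))
  cal <- fit_calibration(h[h$kind == "standard", ], h[h$kind == "blank", ])
  expect_equal(cal$slope, 250, tolerance = 1e-9)
})

test_that("dose fold change divides mean rates and flags a zero denominator", {
  res <- tibble::tibble(treatment = c("lo", "hi"), adduct_rate = c(2, 34))
  expect_equal(dose_fold_change(res, "lo", "hi"), 17)
  expect_equal(dose_fold_change(res, "lo", "lo"), 1)
  zero <- tibble::tibble(treatment = c("lo", "hi"), adduct_rate = c(0, 5))
  expect_error(dose_fold_change(zero, "lo", "hi"), "undefined")
  expect_error(dose_fold_change(res, "absent", "hi"), "not present")
})

test_that("a configured 16.5-fold truth yields an estimated ratio above 16", {
  cfg <- synthetic_config(seed = 17, hplc_cv = 0)
  res <- suppressWarnings(quantify_adducts(simulate_hplc(cfg)))
  expect_gt(dose_fold_change(res, "BaP_0.3", "BaP_3"), 16)
})

test_that("strictly increasing responses at fixed DNA mass give strictly increasing rates", {
  std <- data.frame(concentration_ug_per_L = c(0.01, 0.5, 1.5),
                    response = 100 * c(0.01, 0.5, 1.5))
  cal <- fit_calibration(std)
  responses <- seq(10, 140, by = 10)
  rates <- adduct_rate(quantify_tetrol(responses, cal), 25)
  expect_true(all(diff(rates) > 0))
})
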