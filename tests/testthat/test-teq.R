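test_that("equi-effective dose returns exact nodes and log-interpolates between them", {
  expect_equal(equieffective_dose(
    dose_response_curve("x", c(1, 10), c(40, 80)), 40), 1)
  # midpoint on log10 dose between (1, 20) and (100, 60)
  expect_equal(equieffective_dose(
    dose_response_curve("x", c(1, 100), c(20, 60)), 40), 10)
  # quarter/three-quarter points on the same segment
  expect_equal(equieffective_dose(
    dose_response_curve("x", c(1, 100), c(20, 60)), 30), 10^0.5)
  expect_equal(equieffective_dose(
    dose_response_curve("x", c(1, 100), c(20, 60)), 50), 10^1.5)
})

test_that("equi-effective dose refuses to extrapolate beyond the curve", {
  crv <- dose_response_curve("x", c(1, 10), c(20, 60))
  expect_error(equieffective_dose(crv, 80), "exceeds the maximum")
  expect_error(equieffective_dose(crv, 5), "below the lowest")
})

test_that("non-monotone curves are isotonically cleaned before interpolation", {
  # noise dip at the middle dose; PAVA pools (40, 35) -> (37.5, 37.5)
  crv <- dose_response_curve("x", c(1, 10, 100), c(40, 35, 60))
  d <- equieffective_dose(crv, 50)
  expect_gt(d, 10)
  expect_lt(d, 100)
  # monotone output: higher level never maps to a smaller dose
  d2 <- equieffective_dose(crv, 55)
  expect_gte(d2, d)
})

test_that("TEF derivation reproduces the 1.0 : 0.1 : 0.05 ranking from the stated equi-effective doses", {
  tt <- compute_tefs(gjic_curves(), reference = "B[a]P", effect_level = 40)
  tefs <- setNames(tt$tef, tt$compound)
  expect_identical(tefs[["B[a]P"]], 1.0)
  expect_equal(tefs[["Flthn"]], 0.1)
  expect_equal(tefs[["1-MeA"]], 0.05)
  expect_equal(attr(tt, "ref_dose"), 1)
  expect_equal(attr(tt, "effect_level"), 40)
})

test_that("TEFs are invariant to a common rescaling of equi-effective doses", {
  ed <- c("B[a]P" = 1, "Flthn" = 10, "1-MeA" = 20)
  t1 <- tef_table(ed, "B[a]P")
  t2 <- tef_table(2 * ed, "B[a]P")
  expect_equal(t1$tef, t2$tef)
})

test_that("the reference compound's TEF is exactly 1 under randomized monotone curves", {
  set.seed(42)
  for (i in 1:20) {
    doses <- sort(stats::runif(4, 0.1, 50))
    effects <- sort(stats::runif(4, 5, 90))
    crvs <- list(ref = dose_response_curve("ref", doses, effects),
                 other = dose_response_curve("other", doses * 3, effects))
    lev <- stats::runif(1, min(effects), max(effects))
    tt <- compute_tefs(crvs, "ref", lev)
    expect_identical(tt$tef[tt$compound == "ref"], 1.0)
    expect_equal(tt$tef[tt$compound == "other"], 1 / 3, tolerance = 1e-10)
  }
})

test_that("TEQ dose is the TEF-weighted dose sum", {
  tt <- tef_table(c("B[a]P" = 1, "Flthn" = 10, "1-MeA" = 20), "B[a]P")
  m <- mixture_spec(c("B[a]P" = 1, "Flthn" = 5, "1-MeA" = 5), "m10")
  expect_equal(teq_dose(m, tt), 1.75)
  expect_equal(teq_dose(mixture_spec(c("B[a]P" = 3), "pure"), tt), 3)
  expect_error(
    teq_dose(mixture_spec(c(Pyrene = 1), "unk"), tt), "Pyrene")
})

test_that("additive model reproduces the predicted 43 / 55 / 70 % inhibition triple", {
  tt <- compute_tefs(gjic_curves(), "B[a]P", 40)
  preds <- dplyr::bind_rows(lapply(gjic_mixtures(), predict_additive,
                                   tefs = tt))
  expect_equal(round(preds$predicted_inhibition), c(43, 55, 70))
  expect_equal(round(preds$predicted_foc), c(57, 45, 30))
  expect_equal(preds$predicted_foc, 100 - preds$predicted_inhibition)
  expect_false(any(preds$capped))
})

test_that("additive model is anchored, additive, and homogeneous", {
  tt <- tef_table(c(ref = 2, a = 8, b = 20), "ref", effect_level = 35)
  # anchor identity: TEQ = ref_dose -> predicted = effect_level
  anchor <- predict_additive(mixture_spec(c(ref = 2), "anchor"), tt)
  expect_equal(anchor$predicted_inhibition, 35)

  set.seed(7)
  for (i in 1:20) {
    doses <- stats::runif(3, 0.01, 3)
    names(doses) <- c("ref", "a", "b")
    mix <- mixture_spec(doses, "mix")
    whole <- predict_additive(mix, tt)
    parts <- vapply(names(doses), function(cmp) {
      d <- setNames(doses[[cmp]], cmp)
      predict_additive(mixture_spec(d, cmp), tt)$predicted_inhibition
    }, numeric(1))
    expect_equal(whole$predicted_inhibition, sum(parts), tolerance = 1e-12)
    # homogeneity (pre-cap): scaling doses scales TEQ and prediction
    alpha <- stats::runif(1, 0.1, 2)
    scaled <- predict_additive(mixture_spec(alpha * doses, "s"), tt)
    expect_equal(scaled$teq_dose, alpha * whole$teq_dose)
    if (!scaled$capped && !whole$capped) {
      expect_equal(scaled$predicted_inhibition,
                   alpha * whole$predicted_inhibition, tolerance = 1e-12)
    }
  }
})

test_that("predicted inhibition is capped at 100 and flagged", {
  tt <- tef_table(c(ref = 1), "ref", effect_level = 40)
  p <- predict_additive(mixture_spec(c(ref = 10), "huge"), tt)
  expect_equal(p$predicted_inhibition, 100)
  expect_equal(p$predicted_foc, 0)
  expect_true(p$capped)
})

test_that("prediction-vs-observation comparison gives the +4/+7/-4 deviations", {
  tt <- compute_tefs(gjic_curves(), "B[a]P", 40)
  preds <- dplyr::bind_rows(lapply(gjic_mixtures(), predict_additive,
                                   tefs = tt))
  cmp <- compare_predictions(preds)
  expect_equal(cmp$deviation, c(4, 7, -4))
  expect_equal(attr(cmp, "mean_abs_deviation"), 5)
  # identical observed and predicted -> zero deviations
  self <- compare_predictions(
    preds, setNames(preds$predicted_inhibition, preds$mixture))
  expect_equal(self$deviation, rep(0, 3))
  expect_error(compare_predictions(preds, c(nope = 1)), "no observed value")
})

test_that("endpoint misapplication ratio recovers the 100-fold warning factor", {
  # co-carcinogenic (GJIC) vs carcinogenicity TEF for fluoranthene
  expect_equal(tef_misapplication_ratio(0.1, 0.001), 100)
  expect_equal(tef_misapplication_ratio(0.05, 0.05), 1)
  expect_error(tef_misapplication_ratio(0, 1), "positive")
})

test_that("curve and mixture constructors validate their inputs", {
  expect_error(dose_response_curve("x", c(1, 1), c(10, 20)),
               "strictly increasing")
  expect_error(dose_response_curve("x", 1, 10), "at least 2")
  expect_error(mixture_spec(c(a = 0, b = 0), "zero"), "nonzero")
  expect_error(compute_tefs(list(a = gjic_curves()[[1]]), "missing"),
               "not among curves")
})
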