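test_that("identical seed and config give bit-identical tables", {
  cfg <- synthetic_config(seed = 77)
  expect_identical(simulate_dye_spread(cfg), simulate_dye_spread(cfg))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  expect_identical(simulate_hplc(cfg), simulate_hplc(cfg))
  # serialization-level identity
  expect_identical(serialize(simulate_dye_spread(cfg), NULL),
                   serialize(simulate_dye_spread(cfg), NULL))
  # a different seed changes the draw
  cfg2 <- synthetic_config(seed = 78)
  expect_false(identical(simulate_dye_spread(cfg),
                         simulate_dye_spread(cfg2)))
})

test_that("the generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_dye_spread(synthetic_config(seed = 1)))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("config validation enforces the documented invariants", {
  expect_error(synthetic_config(treatments = c("a", "b"), control = "DMSO"),
               "control")
  expect_error(synthetic_config(area_cv = -0.1), "dispersion")
  expect_error(synthetic_config(
    true_foc = c(DMSO = 99, BaP_0.3 = 85, BaP_1 = 60, BaP_3 = 45,
                 Mix_10 = 75, `BaP_1+Mix_1` = 53, `BaP_1+Mix_5` = 38,
                 `BaP_1+Mix_10` = 34)), "exactly 100")
  expect_error(synthetic_config(true_fold_change = list(BaP_1 = c(g = -1))),
               "> 0")
  expect_error(synthetic_config(calib_slope = 0), "calib_slope")
  expect_error(synthetic_config(n_experiments = 0), ">= 1")
})

test_that("dye-spread output has the full replicate structure and positive areas", {
  cfg <- synthetic_config(seed = 4, n_dishes = 3, n_cuts_per_dish = 3,
                          n_experiments = 3)
  d <- simulate_dye_spread(cfg)
  expect_equal(nrow(d), 3 * 3 * 3 * length(cfg$treatments))
  expect_true(all(d$area > 0))
  counts <- table(d$treatment, d$experiment_id)
  expect_true(all(counts == 9))
})

test_that("a no-effect, no-noise config gives FOC 100 everywhere", {
  trts <- c("DMSO", "t1", "t2")
  cfg <- synthetic_config(seed = 6, treatments = trts,
                          true_foc = c(DMSO = 100, t1 = 100, t2 = 100),
                          true_fold_change = list(),
                          true_adduct_rate = c(DMSO = 1, t1 = 1, t2 = 1),
                          area_cv = 0)
  res <- compute_foc(simulate_dye_spread(cfg))
  expect_equal(res$foc, rep(100, 3))
})

test_that("noiseless qPCR means place the target CT log2(fold) cycles from control", {
  cfg <- synthetic_config(seed = 8, ct_sd = 0,
                          true_fold_change = list(BaP_1 = c(Cox2 = 2)))
  d <- simulate_qpcr(cfg)
  ctrl <- mean(d$ct[d$treatment == "DMSO" & d$gene == "Cox2"])
  trt <- mean(d$ct[d$treatment == "BaP_1" & d$gene == "Cox2"])
  expect_equal(ctrl - trt, 1)  # 2^1 = 2
  norm <- d$ct[d$gene == "18S"]
  expect_true(all(norm == cfg$normalizer_ct))
})

test_that("HPLC records span the declared standard range and zero rates sit at blank level", {
  cfg <- synthetic_config(seed = 12, hplc_cv = 0)
  h <- simulate_hplc(cfg)
  std <- h[h$kind == "standard", ]
  expect_equal(min(std$concentration_ug_per_L), 0.0095)
  expect_equal(max(std$concentration_ug_per_L), 1.52)
  expect_true(all(c("standard", "blank", "sample") %in% h$kind))
  # zero-rate treatment: sample response equals the blank response
  zero <- h$response[h$kind == "sample" & h$treatment == "DMSO"]
  expect_equal(unname(zero),
               rep(mean(h$response[h$kind == "blank"]), length(zero)))
  expect_true(all(h$dna_mass_ug[h$kind == "sample"] > 0))
})

test_that("with default noise the combination FOC estimate stays near its truth", {
  # single-seed spot check; coverage across seeds is exercised in the
  # acceptance suite
  cfg <- synthetic_config(seed = 20171123)
  res <- compute_foc(simulate_dye_spread(cfg))
  row <- res[res$treatment == "BaP_1+Mix_10", ]
  ci <- row$foc + c(-1, 1) * stats::qt(0.975, row$n - 1) * row$sem
  expect_gte(34, ci[1])
  expect_lte(34, ci[2])
})
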