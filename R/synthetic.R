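# Seeded synthetic raw-assay data emulating the study design: 3 dishes x
# 3 cuts per treatment and 3 independent experiments, with treatments
# spanning the vehicle control, B[a]P, the 1:1 Flthn/1-MeA binary mixture,
# and B[a]P + mixture combinations.

#' Configuration for the synthetic-assay generators
#'
#' Bundles the replicate structure, treatment panel, true effect sizes and
#' noise levels used by [simulate_dye_spread()], [simulate_qpcr()] and
#' [simulate_hplc()]. The defaults encode the study conditions: triplicate
#' experiments of 3 dishes x 3 cuts, a DMSO vehicle control, B[a]P doses,
#' the 10 µM binary LMW mixture, and 1 µM B[a]P + 1/5/10 µM mixture
#' combinations, with true FOC values matching the observed GJIC responses
#' (53, 38, 34% of control for the combinations).
#'
#' Dispersion parameters may be set to 0 for noiseless simulations (every
#' estimator then recovers the configured truth exactly); negative values
#' are rejected.
#'
#' @param seed Integer RNG seed; identical seed + config gives bit-identical
#'   tables.
#' @param n_dishes,n_cuts_per_dish,n_experiments Replicate structure.
#' @param treatments Character vector of treatment labels; must include
#'   `control`.
#' @param control Vehicle-control label.
#' @param true_foc Named numeric vector, treatment -> true % of control in
#'   (0, 150]; the control must be exactly 100.
#' @param area_cv Coefficient of variation of dye-spread areas (lognormal
#'   noise; default 0.15).
#' @param control_area Median control dye-spread area, arbitrary units^2.
#' @param genes Target gene labels for qPCR simulation.
#' @param normalizer Normalizer gene label.
#' @param n_qpcr_replicates Technical replicates per (treatment, gene).
#' @param true_fold_change Named list: `treatment` -> named numeric vector
#'   `gene` -> true fold change over control (> 0). Treatments absent from
#'   the list default to fold change 1.
#' @param ct_sd Normal noise SD on the CT scale, cycles (default 0.15).
#' @param normalizer_ct,target_ct Control-anchored mean CT values.
#' @param true_adduct_rate Named numeric vector, treatment -> true adduct
#'   rate (adducts per 1e8 nucleotides, >= 0).
#' @param calib_slope,calib_intercept True calibration line (response per
#'   µg/L and baseline response); slope must be > 0.
#' @param hplc_cv Coefficient of variation of HPLC peak responses
#'   (default 0.02).
#' @param dna_mass_ug DNA mass applied per sample, µg.
#'
#' @return A validated `synthetic_config` list.
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' names(cfg$true_foc)
#' @export
synthetic_config <- function(
    seed = 20171123,
    n_dishes = 3, n_cuts_per_dish = 3, n_experiments = 3,
    treatments = NULL, control = "DMSO",
    true_foc = NULL, area_cv = 0.15, control_area = 10000,
    genes = c("Cyp1a1", "Cyp1b1", "Gja1", "Cox2"), normalizer = "18S",
    n_qpcr_replicates = 3, true_fold_change = NULL, ct_sd = 0.15,
    normalizer_ct = 15, target_ct = 25,
    true_adduct_rate = NULL, calib_slope = 250, calib_intercept = 50,
    hplc_cv = 0.02, dna_mass_ug = 25) {

  if (is.null(treatments)) {
    treatments <- c("DMSO", "BaP_0.3", "BaP_1", "BaP_3", "Mix_10",
                    "BaP_1+Mix_1", "BaP_1+Mix_5", "BaP_1+Mix_10")
  }
  if (is.null(true_foc)) {
    # control-relative GJIC: combinations at the observed 53/38/34% FOC,
    # 1 uM B[a]P at the ~40% inhibition anchor, dose-dependent otherwise
    true_foc <- c("DMSO" = 100, "BaP_0.3" = 85, "BaP_1" = 60, "BaP_3" = 45,
                  "Mix_10" = 75, "BaP_1+Mix_1" = 53, "BaP_1+Mix_5" = 38,
                  "BaP_1+Mix_10" = 34)
    true_foc <- true_foc[names(true_foc) %in% treatments]
  }
  if (is.null(true_fold_change)) {
    true_fold_change <- list(
      "BaP_1"        = c(Cyp1a1 = 8, Cyp1b1 = 3, Gja1 = 0.7, Cox2 = 1.5),
      "Mix_10"       = c(Cyp1a1 = 1, Cyp1b1 = 1, Gja1 = 0.8, Cox2 = 1.8),
      "BaP_1+Mix_10" = c(Cyp1a1 = 6, Cyp1b1 = 3, Gja1 = 0.5, Cox2 = 2.5))
    true_fold_change <-
      true_fold_change[names(true_fold_change) %in% treatments]
  }
  if (is.null(true_adduct_rate)) {
    # dose-dependent anti-BPDE adduct formation; 0.3 -> 3 uM spans the
    # > 16-fold increase. Magnitudes are chosen so that sample tetrol
    # concentrations (at the default DNA mass) fall inside the standards'
    # calibration range; the vehicle control sits at blank level.
    true_adduct_rate <- c("DMSO" = 0, "BaP_0.3" = 60, "BaP_1" = 240,
                          "BaP_3" = 990, "BaP_1+Mix_10" = 420)
    true_adduct_rate <-
      true_adduct_rate[names(true_adduct_rate) %in% treatments]
  }

  cfg <- list(seed = as.integer(seed), n_dishes = as.integer(n_dishes),
              n_cuts_per_dish = as.integer(n_cuts_per_dish),
              n_experiments = as.integer(n_experiments),
              treatments = treatments, control = control,
              true_foc = true_foc, area_cv = area_cv,
              control_area = control_area, genes = genes,
              normalizer = normalizer,
              n_qpcr_replicates = as.integer(n_qpcr_replicates),
              true_fold_change = true_fold_change, ct_sd = ct_sd,
              normalizer_ct = normalizer_ct, target_ct = target_ct,
              true_adduct_rate = true_adduct_rate,
              calib_slope = calib_slope, calib_intercept = calib_intercept,
              hplc_cv = hplc_cv, dna_mass_ug = dna_mass_ug)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (!cfg$control %in% cfg$treatments) {
    stop(sprintf("control treatment '%s' missing from `treatments`",
                 cfg$control), call. = FALSE)
  }
  if (any(c(cfg$n_dishes, cfg$n_cuts_per_dish, cfg$n_experiments,
            cfg$n_qpcr_replicates) < 1L)) {
    stop("replicate counts must be >= 1", call. = FALSE)
  }
  if (any(c(cfg$area_cv, cfg$ct_sd, cfg$hplc_cv) < 0)) {
    stop("dispersion parameters must be >= 0", call. = FALSE)
  }
  missing_foc <- setdiff(cfg$treatments, names(cfg$true_foc))
  if (length(missing_foc) > 0L) {
    stop(sprintf("`true_foc` missing treatment(s): %s",
                 paste(missing_foc, collapse = ", ")), call. = FALSE)
  }
  if (any(cfg$true_foc <= 0) || any(cfg$true_foc > 150)) {
    stop("`true_foc` values must lie in (0, 150]", call. = FALSE)
  }
  if (cfg$true_foc[[cfg$control]] != 100) {
    stop("the control's `true_foc` must be exactly 100", call. = FALSE)
  }
  fc <- unlist(cfg$true_fold_change)
  if (length(fc) > 0L && any(fc <= 0)) {
    stop("`true_fold_change` values must be > 0", call. = FALSE)
  }
  if (length(cfg$true_adduct_rate) > 0L && any(cfg$true_adduct_rate < 0)) {
    stop("`true_adduct_rate` values must be >= 0", call. = FALSE)
  }
  if (cfg$calib_slope <= 0) stop("`calib_slope` must be > 0", call. = FALSE)
  if (cfg$dna_mass_ug <= 0) stop("`dna_mass_ug` must be > 0", call. = FALSE)
  invisible(cfg)
}

# positive noise with a given CV; lognormal, median preserved in the
# cv -> 0 limit (the lognormal mean carries the same exp(sigma^2/2) factor
# for every treatment, so control-relative ratios are unbiased)
rlnorm_cv <- function(n, median, cv) {
  sdlog <- sqrt(log1p(cv^2))
  median * stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' Simulate scalpel-loaded dye-transfer areas
#'
#' One record per (experiment, treatment, dish, cut). Areas are lognormal
#' with median `control_area * true_foc / 100` and coefficient of variation
#' `area_cv`; all areas are strictly positive.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with columns `experiment_id`, `treatment`, `dish_id`,
#'   `cut_id`, `area`.
#' @examples
#' head(simulate_dye_spread(synthetic_config(seed = 1)))
#' @export
simulate_dye_spread <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(offset_seed(config$seed, 1L), {
    grid <- tidyr::expand_grid(
      experiment_id = sprintf("exp%d", seq_len(config$n_experiments)),
      treatment = config$treatments,
      dish_id = sprintf("dish%d", seq_len(config$n_dishes)),
      cut_id = sprintf("cut%d", seq_len(config$n_cuts_per_dish)))
    med <- config$control_area * config$true_foc[grid$treatment] / 100
    grid$area <- rlnorm_cv(nrow(grid), unname(med), config$area_cv)
    grid
  })
}

#' Simulate qPCR threshold cycles
#'
#' CT values are normal on the CT scale around means chosen so that the
#' comparative-CT estimator recovers the configured fold changes: the
#' normalizer CT is treatment-independent, and each target's mean CT is the
#' control target CT minus `log2(true fold change)`.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with columns `experiment_id`, `treatment`, `gene`,
#'   `replicate`, `ct`.
#' @examples
#' head(simulate_qpcr(synthetic_config(seed = 1)))
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(offset_seed(config$seed, 2L), {
    grid <- tidyr::expand_grid(
      experiment_id = sprintf("exp%d", seq_len(config$n_experiments)),
      treatment = config$treatments,
      gene = c(config$genes, config$normalizer),
      replicate = sprintf("r%d", seq_len(config$n_qpcr_replicates)))
    fc <- mapply(function(trt, gene) {
      v <- config$true_fold_change[[trt]]
      if (!is.null(v) && gene %in% names(v)) v[[gene]] else 1
    }, grid$treatment, grid$gene)
    mean_ct <- ifelse(grid$gene == config$normalizer,
                      config$normalizer_ct,
                      config$target_ct - log2(fc))
    grid$ct <- stats::rnorm(nrow(grid), mean = mean_ct, sd = config$ct_sd)
    grid
  })
}

#' Simulate HPLC-FLD tetrol records
#'
#' Produces standards spanning the 0.0095--1.52 µg/L calibration range,
#' blank injections, and per-experiment sample records whose peak responses
#' encode the configured true adduct rates inverted through the calibration
#' line (`response = intercept + slope * concentration`, multiplicative
#' noise with CV `hplc_cv`). Sample tetrol concentration follows from the
#' adduct rate, the DNA mass and the 600 µL injection volume.
#'
#' @param config A [synthetic_config()].
#' @param n_standards Number of standard concentrations (default 8,
#'   geometric ladder across the range).
#' @param n_blanks Number of blank injections (default 3).
#' @param injection_volume_uL Injected volume, µL.
#' @return Tibble with columns `kind`, `concentration_ug_per_L`, `response`,
#'   `treatment`, `dna_mass_ug`, `experiment_id`.
#' @examples
#' head(simulate_hplc(synthetic_config(seed = 1)))
#' @export
simulate_hplc <- function(config, n_standards = 8, n_blanks = 3,
                          injection_volume_uL = 600) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(config$true_adduct_rate) == 0L) {
    stop("config carries no `true_adduct_rate`", call. = FALSE)
  }
  withr::with_seed(offset_seed(config$seed, 3L), {
    conc_std <- 10^seq(log10(0.0095), log10(1.52), length.out = n_standards)
    noisy <- function(mu) {
      if (config$hplc_cv == 0) mu
      else mu * stats::rlnorm(length(mu), 0, sqrt(log1p(config$hplc_cv^2)))
    }
    std <- tibble::tibble(
      kind = "standard", concentration_ug_per_L = conc_std,
      response = noisy(config$calib_intercept +
                         config$calib_slope * conc_std),
      treatment = NA_character_, dna_mass_ug = NA_real_,
      experiment_id = NA_character_)
    blk <- tibble::tibble(
      kind = "blank", concentration_ug_per_L = NA_real_,
      response = noisy(rep(config$calib_intercept, n_blanks)),
      treatment = NA_character_, dna_mass_ug = NA_real_,
      experiment_id = NA_character_)
    smp <- tidyr::expand_grid(
      experiment_id = sprintf("exp%d", seq_len(config$n_experiments)),
      treatment = names(config$true_adduct_rate))
    rate <- config$true_adduct_rate[smp$treatment]
    # invert the rate formula: pg tetrol released from the applied DNA,
    # then concentration in the injected volume (1 pg / 1 uL = 1 ug/L)
    tetrol_pg <- rate / 1e8 * (config$dna_mass_ug * 1e-6 / MW_NUCLEOTIDE) *
      MW_TETROL * 1e12
    conc <- tetrol_pg / injection_volume_uL
    smp <- tibble::tibble(
      kind = "sample", concentration_ug_per_L = NA_real_,
      response = noisy(config$calib_intercept + config$calib_slope * conc),
      treatment = smp$treatment, dna_mass_ug = config$dna_mass_ug,
      experiment_id = smp$experiment_id)
    dplyr::bind_rows(std, blk, smp)
  })
}

# distinct, bounded sub-streams per generator
offset_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * k) %% .Machine$integer.max
}
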