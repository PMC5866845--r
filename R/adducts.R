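# Anti-BPDE-DNA adduct quantification from HPLC-FLD tetrol peak responses.
#
# The adduct surrogate analyte is B[a]P-tetrol I-1 released by acidic DNA
# hydrolysis; its fluorescence peak response is converted to a concentration
# through a linear calibration curve, to a mass in the injected volume, and
# finally to an adduct rate per 1e8 nucleotides.

MW_TETROL <- 320.34   # B[a]P-tetrol I-1 (C20H16O4), g/mol
MW_NUCLEOTIDE <- 330  # mean DNA nucleotide, g/mol (standard convention)

#' Fit a tetrol calibration curve
#'
#' Ordinary unweighted least squares of blank-corrected peak response on
#' standard concentration. The mean blank response is subtracted from every
#' standard response before fitting (and, via the stored `blank_response`,
#' from sample responses before quantification).
#'
#' @param standards Data frame of standard records with columns
#'   `concentration_ug_per_L` and `response` (>= 3 distinct concentrations).
#' @param blanks Optional data frame of blank records with a `response`
#'   column; if `NULL` or empty, no blank correction is applied.
#'
#' @return A `calibration_curve` list: `slope` (response per µg/L),
#'   `intercept`, `r_squared`, `valid_range` (µg/L), `blank_response`,
#'   `n_standards`.
#' @examples
#' std <- data.frame(concentration_ug_per_L = c(0.0095, 0.76, 1.52),
#'                   response = 100 * c(0.0095, 0.76, 1.52))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, blanks = NULL) {
  if (!all(c("concentration_ug_per_L", "response") %in% names(standards))) {
    stop("standards need `concentration_ug_per_L` and `response` columns",
         call. = FALSE)
  }
  conc <- standards$concentration_ug_per_L
  if (length(unique(conc)) < 3L) {
    stop("calibration needs >= 3 distinct standard concentrations",
         call. = FALSE)
  }
  blank_response <- 0
  if (!is.null(blanks) && nrow(as.data.frame(blanks)) > 0L) {
    if (!"response" %in% names(blanks)) {
      stop("blanks need a `response` column", call. = FALSE)
    }
    blank_response <- mean(blanks$response)
  }
  resp <- standards$response - blank_response
  fit <- stats::lm(resp ~ conc)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration failure: non-positive slope", call. = FALSE)
  }
  ss_tot <- sum((resp - mean(resp))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 valid_range = range(conc), blank_response = blank_response,
                 n_standards = length(conc)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> response = %.4g + %.4g * conc (r2 = %.4f)\n  valid range: %.4g-%.4g ug/L; blank = %.4g (%d standards)\n",
    x$intercept, x$slope, x$r_squared, x$valid_range[1], x$valid_range[2],
    x$blank_response, x$n_standards))
  invisible(x)
}

#' Quantify tetrol mass in an injected sample
#'
#' Inverts the calibration line: the sample response is blank-corrected,
#' converted to a concentration `(response - blank - intercept) / slope`
#' (µg/L), and multiplied by the injection volume (µL) to give picograms of
#' tetrol in the injected volume (1 µg/L x 1 µL = 1 pg). Concentrations
#' outside the calibration range are flagged with a warning.
#'
#' @param response Numeric vector of raw fluorescence peak responses.
#' @param curve A [fit_calibration()] result.
#' @param injection_volume_uL Injected volume in µL (default 600).
#' @return Numeric vector of tetrol masses in pg.
#' @examples
#' std <- data.frame(concentration_ug_per_L = c(0.01, 0.5, 1.5),
#'                   response = 100 * c(0.01, 0.5, 1.5))
#' quantify_tetrol(50, fit_calibration(std))  # 0.5 ug/L * 600 uL = 300 pg
#' @export
quantify_tetrol <- function(response, curve, injection_volume_uL = 600) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(response))
  if (any(!is.finite(response))) {
    stop("peak responses must be finite", call. = FALSE)
  }
  conc <- (response - curve$blank_response - curve$intercept) / curve$slope
  out_of_range <- conc < curve$valid_range[1] - 1e-12 |
    conc > curve$valid_range[2] + 1e-12
  if (any(out_of_range)) {
    warning(sprintf(
      "%d response(s) fall outside the calibration range (%.4g-%.4g ug/L)",
      sum(out_of_range), curve$valid_range[1], curve$valid_range[2]),
      call. = FALSE)
  }
  conc * injection_volume_uL
}

#' DNA adduct rate per 1e8 nucleotides
#'
#' Converts a tetrol mass and the DNA mass it was released from to an adduct
#' rate, assuming one tetrol per adduct (complete hydrolysis):
#' `rate = (moles tetrol / moles nucleotides) * 1e8` with molecular weights
#' 320.34 g/mol (B\[a\]P-tetrol I-1) and 330 g/mol (mean nucleotide).
#' Negative tetrol estimates (blank-corrected responses below zero) are
#' truncated to 0 with a warning.
#'
#' @param tetrol_pg Tetrol mass in pg (vectorised).
#' @param dna_ug DNA mass applied, in µg (> 0).
#' @param mw_tetrol,mw_nucleotide Molecular weights, g/mol.
#' @return Adducts per 1e8 nucleotides.
#' @examples
#' adduct_rate(1000, 25) # ~4120 adducts per 1e8 nt
#' @export
adduct_rate <- function(tetrol_pg, dna_ug, mw_tetrol = MW_TETROL,
                        mw_nucleotide = MW_NUCLEOTIDE) {
  stopifnot(is.numeric(tetrol_pg), is.numeric(dna_ug))
  if (any(dna_ug <= 0)) stop("DNA mass must be > 0", call. = FALSE)
  if (any(tetrol_pg < 0)) {
    warning(sprintf("%d negative tetrol estimate(s) truncated to 0",
                    sum(tetrol_pg < 0)), call. = FALSE)
    tetrol_pg <- pmax(tetrol_pg, 0)
  }
  mol_tetrol <- tetrol_pg * 1e-12 / mw_tetrol
  mol_nt <- dna_ug * 1e-6 / mw_nucleotide
  mol_tetrol / mol_nt * 1e8
}

#' Quantify adduct rates for an HPLC dataset
#'
#' Runs the full adduct pipeline on a long-format HPLC table: fits the
#' calibration curve from `standard` and `blank` records (unless a curve is
#' supplied), quantifies each `sample` record, converts to adduct rates, and
#' summarises per treatment (mean, SEM, n across records).
#'
#' @param data Data frame with columns `kind` (one of `standard`, `blank`,
#'   `sample`), `concentration_ug_per_L` (standards), `response`,
#'   `treatment` (samples), `dna_mass_ug` (samples).
#' @param curve Optional pre-fitted [fit_calibration()] curve.
#' @param injection_volume_uL Injected volume, µL.
#' @return Tibble with one row per treatment: `treatment`, `adduct_rate`
#'   (adducts per 1e8 nucleotides), `sem`, `n`, `truncated` (any negative
#'   estimate truncated), with the curve attached as attribute
#'   `"calibration"`.
#' @export
quantify_adducts <- function(data, curve = NULL, injection_volume_uL = 600) {
  required <- c("kind", "response")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("HPLC data is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  bad_kind <- setdiff(unique(data$kind), c("standard", "blank", "sample"))
  if (length(bad_kind) > 0L) {
    stop(sprintf("unknown record kind(s): %s",
                 paste(bad_kind, collapse = ", ")), call. = FALSE)
  }
  if (is.null(curve)) {
    curve <- fit_calibration(data[data$kind == "standard", ],
                             data[data$kind == "blank", ])
  }
  samples <- data[data$kind == "sample", ]
  if (nrow(samples) == 0L) stop("no sample records", call. = FALSE)
  if (!all(c("treatment", "dna_mass_ug") %in% names(samples))) {
    stop("sample records need `treatment` and `dna_mass_ug`", call. = FALSE)
  }
  if (any(is.na(samples$dna_mass_ug)) || any(samples$dna_mass_ug <= 0)) {
    stop("sample DNA mass must be > 0", call. = FALSE)
  }
  tetrol_pg <- quantify_tetrol(samples$response, curve, injection_volume_uL)
  truncated <- tetrol_pg < 0
  rate <- suppressWarnings(adduct_rate(tetrol_pg, samples$dna_mass_ug))
  if (any(truncated)) {
    warning(sprintf("%d sample(s) below blank; rate truncated to 0",
                    sum(truncated)), call. = FALSE)
  }
  out <- tibble::tibble(treatment = samples$treatment, rate = rate,
                        truncated = truncated) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n = dplyr::n(),
      sem = if (dplyr::n() > 1L)
        stats::sd(.data$rate) / sqrt(dplyr::n()) else 0,
      adduct_rate = mean(.data$rate),
      truncated = any(.data$truncated),
      .groups = "drop"
    ) |>
    dplyr::select("treatment", "adduct_rate", "sem", "n", "truncated")
  attr(out, "calibration") <- curve
  out
}

#' Fold change in adduct rate between two doses
#'
#' Ratio of mean adduct rates, `high / low`.
#'
#' @param results Tibble of per-treatment adduct rates (as from
#'   [quantify_adducts()], columns `treatment` and `adduct_rate`).
#' @param low,high Treatment labels of the low and high dose.
#' @return The fold ratio (dimensionless).
#' @examples
#' res <- tibble::tibble(treatment = c("lo", "hi"), adduct_rate = c(2, 34))
#' dose_fold_change(res, "lo", "hi") # 17
#' @export
dose_fold_change <- function(results, low, high) {
  stopifnot(is.data.frame(results),
            all(c("treatment", "adduct_rate") %in% names(results)))
  for (lab in c(low, high)) {
    if (!lab %in% results$treatment) {
      stop(sprintf("treatment '%s' not present in results", lab),
           call. = FALSE)
    }
  }
  lo <- results$adduct_rate[results$treatment == low]
  hi <- results$adduct_rate[results$treatment == high]
  lo <- mean(lo); hi <- mean(hi)
  if (lo <= 0) {
    stop("low-dose adduct rate is zero; fold ratio undefined", call. = FALSE)
  }
  hi / lo
}
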