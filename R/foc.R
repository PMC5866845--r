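# Fraction-of-control quantification of gap junctional intercellular
# communication (GJIC) from scalpel-loaded dye-transfer (SL/DT) areas.

#' Fraction of control (FOC) from dye-spread areas
#'
#' Quantifies GJIC from SL/DT dye-spread areas. Areas are aggregated
#' hierarchically -- cuts are averaged within each dish, dish means within
#' each experiment -- and the fraction of control is formed *within* each
#' experiment as `100 * mean(treatment) / mean(control)`. The reported FOC is
#' the mean of the per-experiment FOCs, with SEM and n taken across
#' experiments (matching figure legends that report experiment-level
#' `mean +/- SEM, n = 3`).
#'
#' FOC may exceed 100 (enhanced communication) and is not clipped;
#' inhibition (`100 - FOC`) may then be negative.
#'
#' @param data Tibble/data frame of dye-spread records with columns
#'   `experiment_id`, `treatment`, `dish_id`, `cut_id`, `area` (areas > 0).
#' @param control Label of the vehicle-control treatment (default `"DMSO"`).
#'
#' @return A tibble with one row per treatment: `treatment`, `foc` (% of
#'   control), `inhibition` (% = 100 - foc), `sem`, `n` (number of
#'   experiments contributing).
#' @examples
#' d <- expand.grid(experiment_id = "e1", treatment = c("DMSO", "BaP"),
#'                  dish_id = 1:3, cut_id = 1:3, stringsAsFactors = FALSE)
#' d$area <- ifelse(d$treatment == "DMSO", 100, 50)
#' compute_foc(d, control = "DMSO")
#' @export
compute_foc <- function(data, control = "DMSO") {
  data <- validate_dye_spread(data)
  per_exp <- foc_by_experiment(data, control)

  n_exp <- dplyr::n_distinct(data$experiment_id)
  partial <- per_exp |>
    dplyr::count(.data$treatment) |>
    dplyr::filter(.data$n < n_exp)
  if (nrow(partial) > 0L) {
    warning(sprintf(
      "treatment(s) %s present in only some experiments; FOC computed over available experiments",
      paste(sQuote(partial$treatment, q = FALSE), collapse = ", ")),
      call. = FALSE)
  }

  per_exp |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n = dplyr::n(),
      sem = if (dplyr::n() > 1L) stats::sd(.data$foc) / sqrt(dplyr::n()) else 0,
      foc = mean(.data$foc),
      .groups = "drop"
    ) |>
    dplyr::mutate(inhibition = 100 - .data$foc) |>
    dplyr::select("treatment", "foc", "inhibition", "sem", "n")
}

#' Per-experiment FOC values
#'
#' Same aggregation as [compute_foc()] but stopping at the per-experiment
#' level; useful as the response for ANOVA / post-hoc testing.
#'
#' @inheritParams compute_foc
#' @return Tibble with columns `experiment_id`, `treatment`, `foc`.
#' @export
foc_by_experiment <- function(data, control = "DMSO") {
  data <- validate_dye_spread(data)
  if (!control %in% data$treatment) {
    stop(sprintf("control treatment '%s' not present in the data", control),
         call. = FALSE)
  }
  per_exp <- data |>
    dplyr::group_by(.data$experiment_id, .data$treatment, .data$dish_id) |>
    dplyr::summarise(dish_mean = mean(.data$area), .groups = "drop") |>
    dplyr::group_by(.data$experiment_id, .data$treatment) |>
    dplyr::summarise(exp_mean = mean(.data$dish_mean), .groups = "drop")
  ctrl <- per_exp |>
    dplyr::filter(.data$treatment == control) |>
    dplyr::select("experiment_id", ctrl_mean = "exp_mean")
  per_exp |>
    dplyr::inner_join(ctrl, by = "experiment_id") |>
    dplyr::mutate(foc = 100 * .data$exp_mean / .data$ctrl_mean) |>
    dplyr::select("experiment_id", "treatment", "foc")
}

validate_dye_spread <- function(data) {
  required <- c("experiment_id", "treatment", "dish_id", "cut_id", "area")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("dye-spread data is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(data$area) || anyNA(data$area)) {
    stop("`area` must be numeric and non-missing", call. = FALSE)
  }
  if (any(data$area <= 0)) {
    stop("dye-spread areas must be strictly positive", call. = FALSE)
  }
  key <- paste(data$experiment_id, data$treatment, data$dish_id, data$cut_id,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (experiment, treatment, dish, cut) records", call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Convert between fraction of control and percent inhibition
#'
#' `inhibition = 100 - foc`; the two conversions are exact inverses.
#'
#' @param foc Fraction of control, percent.
#' @param inhibition Percent inhibition.
#' @return The converted percentage (vectorised).
#' @examples
#' inhibition_from_foc(53) # 47
#' foc_from_inhibition(70) # 30
#' @export
inhibition_from_foc <- function(foc) {
  stopifnot(is.numeric(foc))
  100 - foc
}

#' @rdname inhibition_from_foc
#' @export
foc_from_inhibition <- function(inhibition) {
  stopifnot(is.numeric(inhibition))
  100 - inhibition
}
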