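# Comparative-CT (delta-delta-CT) relative gene-expression quantification.

#' Fold change over control by the comparative-CT method
#'
#' For each (experiment, treatment, gene), technical-replicate CT values are
#' averaged on the CT scale, then `dCT = CT(target) - CT(normalizer)` within
#' the same experiment and treatment, `ddCT = dCT(treatment) - dCT(control)`,
#' and the per-experiment fold change is `2^(-ddCT)` (amplification
#' efficiency fixed at perfect doubling). The reported fold change per
#' (treatment, gene) is the mean across experiments with SEM and n.
#'
#' CT values flagged as non-detects (`NA`) are dropped with a warning; they
#' are never treated as numeric cycles.
#'
#' @param data Tibble/data frame of qPCR records with columns
#'   `experiment_id`, `treatment`, `gene`, `replicate`, `ct`.
#' @param control Vehicle-control treatment label (default `"DMSO"`).
#' @param normalizer Normalizer gene label (default `"18S"`), which must be
#'   measured in every (experiment, treatment).
#'
#' @return Tibble with one row per (treatment, gene): `treatment`, `gene`,
#'   `fold_change`, `sem`, `n`. The control's own fold change is 1 by
#'   construction. The normalizer gene is not reported.
#' @examples
#' d <- expand.grid(experiment_id = "e1", treatment = c("DMSO", "BaP"),
#'                  gene = c("Cox2", "18S"), replicate = 1:2,
#'                  stringsAsFactors = FALSE)
#' d$ct <- ifelse(d$gene == "18S", 15, ifelse(d$treatment == "DMSO", 25, 24))
#' fold_change(d, control = "DMSO", normalizer = "18S")
#' @export
fold_change <- function(data, control = "DMSO", normalizer = "18S") {
  required <- c("experiment_id", "treatment", "gene", "replicate", "ct")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("qPCR data is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!is.numeric(data$ct)) stop("`ct` must be numeric", call. = FALSE)
  if (anyNA(data$ct)) {
    warning(sprintf("%d non-detect CT value(s) dropped", sum(is.na(data$ct))),
            call. = FALSE)
    data <- data[!is.na(data$ct), ]
  }
  if (any(is.infinite(data$ct))) {
    stop("CT values must be finite; flag non-detects as NA", call. = FALSE)
  }
  if (!control %in% data$treatment) {
    stop(sprintf("control treatment '%s' not present in the data", control),
         call. = FALSE)
  }
  if (!normalizer %in% data$gene) {
    stop(sprintf("normalizer gene '%s' not present in the data", normalizer),
         call. = FALSE)
  }

  mean_ct <- data |>
    dplyr::group_by(.data$experiment_id, .data$treatment, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  norm_ct <- mean_ct |>
    dplyr::filter(.data$gene == normalizer) |>
    dplyr::select("experiment_id", "treatment", norm_ct = "ct")

  dct <- mean_ct |>
    dplyr::filter(.data$gene != normalizer) |>
    dplyr::left_join(norm_ct, by = c("experiment_id", "treatment"))
  if (anyNA(dct$norm_ct)) {
    bad <- dct[is.na(dct$norm_ct), c("experiment_id", "treatment")]
    stop(sprintf("normalizer gene '%s' missing for %s",
                 normalizer,
                 paste(unique(paste0("(", bad$experiment_id, ", ",
                                     bad$treatment, ")")), collapse = ", ")),
         call. = FALSE)
  }
  dct$dct <- dct$ct - dct$norm_ct

  ctrl_dct <- dct |>
    dplyr::filter(.data$treatment == control) |>
    dplyr::select("experiment_id", "gene", ctrl_dct = "dct")

  dct |>
    dplyr::inner_join(ctrl_dct, by = c("experiment_id", "gene")) |>
    dplyr::mutate(fc = 2^(-(.data$dct - .data$ctrl_dct))) |>
    dplyr::group_by(.data$treatment, .data$gene) |>
    dplyr::summarise(
      n = dplyr::n(),
      sem = if (dplyr::n() > 1L) stats::sd(.data$fc) / sqrt(dplyr::n()) else 0,
      fold_change = mean(.data$fc),
      .groups = "drop"
    ) |>
    dplyr::select("treatment", "gene", "fold_change", "sem", "n")
}
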