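# CSV schemas, mixture YAML, and the pipeline orchestrator.
#
# All files are comma-separated UTF-8 with a mandatory header row and "."
# as the decimal separator. Units are embedded in column names (dose_uM,
# concentration_ug_per_L, dna_mass_ug).

assay_schemas <- list(
  dye_spread = list(
    columns = c("experiment_id", "treatment", "dish_id", "cut_id", "area"),
    numeric = "area",
    key = c("experiment_id", "treatment", "dish_id", "cut_id")),
  qpcr = list(
    columns = c("experiment_id", "treatment", "gene", "replicate", "ct"),
    numeric = "ct",
    key = c("experiment_id", "treatment", "gene", "replicate")),
  hplc = list(
    columns = c("kind", "concentration_ug_per_L", "response", "treatment",
                "dna_mass_ug"),
    numeric = c("concentration_ug_per_L", "response", "dna_mass_ug"),
    key = NULL),
  dose_response = list(
    columns = c("compound", "timepoint_h", "dose_uM", "inhibition_pct"),
    numeric = c("timepoint_h", "dose_uM", "inhibition_pct"),
    key = c("compound", "timepoint_h", "dose_uM"))
)

#' Read an assay table from CSV
#'
#' Reads and validates one of the four assay schemas. Validation errors name
#' the offending column and data row.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema One of `"dye_spread"`, `"qpcr"`, `"hplc"`,
#'   `"dose_response"`.
#' @return A validated tibble (columns in schema order; extra columns are
#'   preserved after them).
#' @export
read_assay_table <- function(path, schema) {
  schema <- match.arg(schema, names(assay_schemas))
  sc <- assay_schemas[[schema]]
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(sc$columns, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in sc$numeric) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad) > 0L) {
        stop(sprintf("%s: non-numeric value in column '%s', row %d ('%s')",
                     path, col, bad[1L], v[bad[1L]]), call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  if (!is.null(sc$key)) {
    key <- do.call(paste, c(df[sc$key], sep = "\r"))
    dup <- which(duplicated(key))
    if (length(dup) > 0L) {
      stop(sprintf("%s: duplicate key (%s) at row %d", path,
                   paste(sc$key, collapse = ", "), dup[1L]), call. = FALSE)
    }
  }
  tibble::as_tibble(df[, c(sc$columns, setdiff(names(df), sc$columns))])
}

#' Write an assay table to CSV
#'
#' @param data Tibble/data frame matching one of the assay schemas.
#' @param path Output CSV path.
#' @param schema Schema name (checked against the data's columns).
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(data, path, schema) {
  schema <- match.arg(schema, names(assay_schemas))
  sc <- assay_schemas[[schema]]
  missing <- setdiff(sc$columns, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("data is missing schema column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read mixture definitions from YAML
#'
#' The file holds a list of entries `{label, components: {compound:
#' dose_uM}, observed_inhibition_pct (optional)}`.
#'
#' @param path Path to the mixtures YAML file.
#' @return A list of [mixture_spec()] objects.
#' @export
read_mixtures <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  lapply(raw, function(m) {
    if (is.null(m$label) || is.null(m$components)) {
      stop("each mixture needs `label` and `components`", call. = FALSE)
    }
    mixture_spec(unlist(m$components), m$label,
                 observed_inhibition_pct =
                   m$observed_inhibition_pct %||% NA_real_)
  })
}

#' Run the full co-carcinogenicity analysis pipeline
#'
#' Orchestrates the quantification stages (FOC, fold change, adducts) for
#' whichever inputs are configured, runs ANOVA + SNK on the per-experiment
#' FOC values, derives TEFs from dose-response curves, and predicts mixture
#' effects under the additive model, comparing them with observations when
#' available. Writes a JSON report (plus per-stage CSVs) embedding the full
#' effective configuration so results are audit-reproducible.
#'
#' @param config A named list (or path to a YAML file) with optional
#'   entries: `dye_spread`, `qpcr`, `hplc`, `dose_response` (CSV paths or
#'   data frames), `mixtures` (YAML path or list of [mixture_spec()]),
#'   `control` (default `"DMSO"`), `normalizer` (default `"18S"`),
#'   `reference` (default `"B[a]P"`), `effect_level` (default 40), `alpha`
#'   (default 0.05), `output_dir` (optional; when set, report files are
#'   written there).
#' @return The report, a named list, invisibly classed `pahteq_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  control <- config$control %||% "DMSO"
  normalizer <- config$normalizer %||% "18S"
  reference <- config$reference %||% "B[a]P"
  effect_level <- config$effect_level %||% 40
  alpha <- config$alpha %||% 0.05

  get_table <- function(x, schema) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) read_assay_table(x, schema)
    else tibble::as_tibble(x)
  }

  report <- list(
    parameters = list(
      control = control, normalizer = normalizer, reference = reference,
      effect_level = effect_level, alpha = alpha,
      mw_tetrol = MW_TETROL, mw_nucleotide = MW_NUCLEOTIDE,
      interpolation = "log10-dose linear, isotonic cleanup",
      amplification_efficiency = 2.0))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  dye <- get_table(config$dye_spread, "dye_spread")
  if (!is.null(dye)) {
    report$foc <- run_stage("foc", compute_foc(dye, control = control))
    foc_exp <- run_stage("foc", foc_by_experiment(dye, control = control))
    report$anova <- run_stage("stats", {
      fit <- one_way_anova(foc_exp, value = "foc", group = "treatment")
      list(f = fit$f, df_between = fit$df_between,
           df_within = fit$df_within, p = fit$p)
    })
    report$snk <- run_stage("stats",
      snk_posthoc(foc_exp, value = "foc", group = "treatment",
                  alpha = alpha))
  }

  qpcr <- get_table(config$qpcr, "qpcr")
  if (!is.null(qpcr)) {
    report$fold_change <- run_stage("ddct",
      fold_change(qpcr, control = control, normalizer = normalizer))
  }

  hplc <- get_table(config$hplc, "hplc")
  if (!is.null(hplc)) {
    adducts <- run_stage("adducts", quantify_adducts(hplc))
    curve <- attr(adducts, "calibration")
    report$adducts <- adducts
    report$calibration <- list(
      slope = curve$slope, intercept = curve$intercept,
      r_squared = curve$r_squared, valid_range = curve$valid_range)
  }

  dr <- get_table(config$dose_response, "dose_response")
  if (!is.null(dr)) {
    curves <- run_stage("teq", {
      split(dr, dr$compound) |>
        lapply(function(d) {
          d <- d[order(d$dose_uM), ]
          dose_response_curve(d$compound[1L], d$dose_uM, d$inhibition_pct,
                              timepoint_h = d$timepoint_h[1L])
        })
    })
    tefs <- run_stage("teq",
      compute_tefs(curves, reference = reference,
                   effect_level = effect_level))
    report$tefs <- tefs

    mixtures <- config$mixtures
    if (is.character(mixtures)) mixtures <- read_mixtures(mixtures)
    if (!is.null(mixtures)) {
      preds <- run_stage("teq",
        dplyr::bind_rows(lapply(mixtures, predict_additive, tefs = tefs)))
      if (!anyNA(preds$observed_inhibition)) {
        preds <- compare_predictions(preds)
      }
      report$predictions <- preds
    }
  }

  class(report) <- "pahteq_report"
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
  }
  invisible(report)
}

#' Write a pipeline report to disk
#'
#' @param report A `pahteq_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pahteq_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- lapply(unclass(report), function(x) {
    if (inherits(x, "tef_table")) {
      list(table = as.data.frame(x), reference = attr(x, "reference"),
           endpoint = attr(x, "endpoint"), ref_dose = attr(x, "ref_dose"),
           effect_level = attr(x, "effect_level"))
    } else x
  })
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  for (nm in c("foc", "fold_change", "adducts", "snk", "predictions")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(as.data.frame(report[[nm]]),
                       file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(report$tefs)) {
    utils::write.csv(as.data.frame(report$tefs),
                     file.path(dir, "tefs.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.pahteq_report <- function(x, ...) {
  cat("<pahteq_report> stages:",
      paste(setdiff(names(x), "parameters"), collapse = ", "), "\n")
  invisible(x)
}
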