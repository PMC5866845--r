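# Endpoint-specific toxic equivalency: equi-effective doses, TEFs, TEQ doses,
# and the additive mixture-effect model for GJIC inhibition.

#' Construct a dose-response curve
#'
#' A dose-response curve records percent effect (by default % inhibition of
#' gap junctional intercellular communication) at increasing doses of a single
#' compound and a fixed exposure time. It is the substrate for equi-effective
#' dose estimation and TEF derivation.
#'
#' @param compound Compound label, e.g. `"B[a]P"`.
#' @param dose_uM Numeric vector of doses in µM, strictly increasing, all >= 0.
#' @param inhibition_pct Numeric vector of percent effect at each dose.
#' @param timepoint_h Exposure duration in hours (metadata; default 24).
#'
#' @return A `dose_response_curve`: a tibble with columns `dose_uM` and
#'   `inhibition_pct`, carrying `compound` and `timepoint_h` attributes.
#' @examples
#' dose_response_curve("B[a]P", c(0.3, 1, 3), c(15, 40, 65))
#' @export
dose_response_curve <- function(compound, dose_uM, inhibition_pct,
                                timepoint_h = 24) {
  stopifnot(is.character(compound), length(compound) == 1L)
  dose_uM <- as.numeric(dose_uM)
  inhibition_pct <- as.numeric(inhibition_pct)
  if (length(dose_uM) != length(inhibition_pct)) {
    stop("`dose_uM` and `inhibition_pct` must have equal length", call. = FALSE)
  }
  if (length(dose_uM) < 2L) {
    stop("a dose-response curve needs at least 2 points", call. = FALSE)
  }
  if (anyNA(dose_uM) || anyNA(inhibition_pct)) {
    stop("doses and effects must be non-missing", call. = FALSE)
  }
  if (any(dose_uM < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(diff(dose_uM) <= 0)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(dose_uM = dose_uM, inhibition_pct = inhibition_pct)
  attr(out, "compound") <- compound
  attr(out, "timepoint_h") <- timepoint_h
  class(out) <- c("dose_response_curve", class(out))
  out
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> %s, %g h\n",
              attr(x, "compound"), attr(x, "timepoint_h")))
  NextMethod()
}

# Pool-adjacent-violators cleanup: effects are assumed monotone
# non-decreasing in dose; measurement noise can violate this.
isotonic_effects <- function(curve) {
  eff <- curve$inhibition_pct
  if (!is.unsorted(eff)) return(eff)
  stats::isoreg(seq_along(eff), eff)$yf
}

#' Equi-effective dose from a dose-response curve
#'
#' Finds the dose at which the (isotonically regressed) curve reaches a given
#' effect level, interpolating linearly on log10(dose) between the bracketing
#' observed points. A dose whose observed effect equals the level exactly is
#' returned directly. No extrapolation above the observed maximum is
#' performed.
#'
#' @param curve A [dose_response_curve()].
#' @param effect_level Target percent effect, within the observed range.
#'
#' @return The interpolated dose in µM.
#' @examples
#' equieffective_dose(dose_response_curve("x", c(1, 10), c(40, 80)), 40) # 1
#' equieffective_dose(dose_response_curve("x", c(1, 100), c(20, 60)), 40) # 10
#' @export
equieffective_dose <- function(curve, effect_level) {
  stopifnot(inherits(curve, "dose_response_curve"),
            is.numeric(effect_level), length(effect_level) == 1L)
  eff <- isotonic_effects(curve)
  dose <- curve$dose_uM

  if (effect_level == 0 && all(eff > 0)) return(0)

  # exact observed match wins (smallest such dose)
  hit <- which(abs(eff - effect_level) < 1e-12)
  if (length(hit) > 0L) return(dose[hit[1L]])

  if (effect_level > max(eff)) {
    stop(sprintf(
      "effect level %g%% exceeds the maximum observed effect (%g%%) for %s; not extrapolating",
      effect_level, max(eff), attr(curve, "compound")), call. = FALSE)
  }
  if (effect_level < min(eff)) {
    stop(sprintf(
      "effect level %g%% is below the lowest observed effect (%g%%) for %s; not extrapolating",
      effect_level, min(eff), attr(curve, "compound")), call. = FALSE)
  }

  i <- max(which(eff < effect_level))      # lower bracket
  j <- i + 1L                              # eff[j] > effect_level here
  if (dose[i] <= 0) {
    # cannot log-interpolate from a zero dose; fall back to linear in dose
    frac <- (effect_level - eff[i]) / (eff[j] - eff[i])
    return(dose[i] + frac * (dose[j] - dose[i]))
  }
  frac <- (effect_level - eff[i]) / (eff[j] - eff[i])
  10^(log10(dose[i]) + frac * (log10(dose[j]) - log10(dose[i])))
}

#' Derive endpoint-specific toxic equivalency factors
#'
#' Computes TEFs as ratios of equi-effective doses at a common effect level:
#' `TEF_i = ED(reference) / ED(compound_i)`. The reference compound has
#' TEF = 1 exactly. TEFs are endpoint-specific; the endpoint label travels
#' with the table.
#'
#' @param curves Named list of [dose_response_curve()] objects, one per
#'   compound; names are the compound labels.
#' @param reference Label of the reference compound (must be in `curves`).
#' @param effect_level Common percent effect at which equi-effective doses
#'   are read off (default 40, the GJIC-inhibition anchor).
#' @param endpoint Endpoint label stored with the table.
#'
#' @return A `tef_table`: a tibble with columns `compound`, `ed_uM`
#'   (equi-effective dose) and `tef`, with attributes `reference`,
#'   `endpoint`, `ref_dose` and `effect_level`.
#' @examples
#' curves <- list(
#'   "B[a]P"  = dose_response_curve("B[a]P",  c(0.3, 1, 3),  c(15, 40, 65)),
#'   "Flthn"  = dose_response_curve("Flthn",  c(1, 10, 20),  c(10, 40, 55)),
#'   "1-MeA"  = dose_response_curve("1-MeA",  c(2, 20, 40),  c(10, 40, 55)))
#' compute_tefs(curves, reference = "B[a]P", effect_level = 40)
#' @export
compute_tefs <- function(curves, reference, effect_level = 40,
                         endpoint = "GJIC inhibition, 24 h") {
  stopifnot(is.list(curves), length(curves) >= 1L)
  if (is.null(names(curves)) || any(names(curves) == "")) {
    stop("`curves` must be a named list (compound labels)", call. = FALSE)
  }
  if (!reference %in% names(curves)) {
    stop(sprintf("reference compound '%s' not among curves", reference),
         call. = FALSE)
  }
  ed <- vapply(names(curves), function(cmp) {
    tryCatch(equieffective_dose(curves[[cmp]], effect_level),
             error = function(e) {
               stop(sprintf("equi-effective dose failed for '%s': %s",
                            cmp, conditionMessage(e)), call. = FALSE)
             })
  }, numeric(1))
  ref_dose <- ed[[reference]]
  tef <- ref_dose / ed
  tef[[reference]] <- 1.0   # exact by definition
  out <- tibble::tibble(compound = names(curves), ed_uM = unname(ed),
                        tef = unname(tef))
  attr(out, "reference") <- reference
  attr(out, "endpoint") <- endpoint
  attr(out, "ref_dose") <- ref_dose
  attr(out, "effect_level") <- effect_level
  class(out) <- c("tef_table", class(out))
  out
}

#' Build a TEF table from known equi-effective doses
#'
#' Convenience constructor used when equi-effective doses are already known
#' (e.g. read directly off prior published dose-response data) rather than
#' interpolated from curves.
#'
#' @param ed_uM Named numeric vector of equi-effective doses (µM), names are
#'   compound labels.
#' @inheritParams compute_tefs
#' @return A `tef_table` (see [compute_tefs()]).
#' @examples
#' tef_table(c("B[a]P" = 1, "Flthn" = 10, "1-MeA" = 20), reference = "B[a]P")
#' @export
tef_table <- function(ed_uM, reference, effect_level = 40,
                      endpoint = "GJIC inhibition, 24 h") {
  stopifnot(is.numeric(ed_uM), !is.null(names(ed_uM)))
  if (!reference %in% names(ed_uM)) {
    stop(sprintf("reference compound '%s' not among doses", reference),
         call. = FALSE)
  }
  if (any(ed_uM <= 0)) stop("equi-effective doses must be > 0", call. = FALSE)
  tef <- ed_uM[[reference]] / ed_uM
  tef[[reference]] <- 1.0
  out <- tibble::tibble(compound = names(ed_uM), ed_uM = unname(ed_uM),
                        tef = unname(tef))
  attr(out, "reference") <- reference
  attr(out, "endpoint") <- endpoint
  attr(out, "ref_dose") <- ed_uM[[reference]]
  attr(out, "effect_level") <- effect_level
  class(out) <- c("tef_table", class(out))
  out
}

#' @export
print.tef_table <- function(x, ...) {
  cat(sprintf("<tef_table> endpoint: %s | reference: %s (ED = %g uM at %g%% effect)\n",
              attr(x, "endpoint"), attr(x, "reference"),
              attr(x, "ref_dose"), attr(x, "effect_level")))
  NextMethod()
}

#' Define an exposure mixture
#'
#' @param components Named numeric vector of doses in µM (compound -> dose);
#'   at least one dose must be nonzero.
#' @param label Mixture label used in reports.
#' @param observed_inhibition_pct Optional observed percent inhibition for
#'   later comparison with the additive-model prediction.
#'
#' @return A `mixture_spec` list.
#' @examples
#' mixture_spec(c("B[a]P" = 1, "Flthn" = 0.5, "1-MeA" = 0.5), "BaP + 1 uM mix")
#' @export
mixture_spec <- function(components, label,
                         observed_inhibition_pct = NA_real_) {
  stopifnot(is.numeric(components), !is.null(names(components)))
  if (any(components < 0)) stop("component doses must be >= 0", call. = FALSE)
  if (all(components == 0)) {
    stop("a mixture needs at least one nonzero dose", call. = FALSE)
  }
  structure(list(components = components, label = label,
                 observed_inhibition_pct = observed_inhibition_pct),
            class = "mixture_spec")
}

#' Toxic equivalent (TEQ) dose of a mixture
#'
#' The TEF-weighted dose sum `TEQ = sum_i TEF_i * dose_i`, in µM
#' reference-compound equivalents.
#'
#' @param mixture A [mixture_spec()].
#' @param tefs A `tef_table` covering every mixture component.
#' @return TEQ dose in µM reference equivalents.
#' @examples
#' tt <- tef_table(c("B[a]P" = 1, "Flthn" = 10, "1-MeA" = 20), "B[a]P")
#' teq_dose(mixture_spec(c("B[a]P" = 1, "Flthn" = 5, "1-MeA" = 5), "m"), tt)
#' @export
teq_dose <- function(mixture, tefs) {
  stopifnot(inherits(mixture, "mixture_spec"), inherits(tefs, "tef_table"))
  comps <- mixture$components
  unknown <- setdiff(names(comps), tefs$compound)
  if (length(unknown) > 0L) {
    stop(sprintf("no TEF available for compound(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  tef <- tefs$tef[match(names(comps), tefs$compound)]
  sum(tef * comps)
}

#' Predict a mixture effect under the additive TEQ model
#'
#' The additive (effect-additivity) model is linear in TEQ dose and anchored
#' at the reference compound: a TEQ of `ref_dose` µM produces `effect_level`
#' percent inhibition, so
#' `predicted_inhibition = effect_level * TEQ / ref_dose`, capped at 100.
#' Under this model the mixture prediction equals the sum of the
#' single-compound predictions.
#'
#' @param mixture A [mixture_spec()].
#' @param tefs A `tef_table` (carries the anchor `ref_dose`/`effect_level`).
#' @return One-row tibble: `mixture`, `teq_dose`, `predicted_inhibition`,
#'   `predicted_foc`, `capped`, plus the observed inhibition if present.
#' @examples
#' tt <- tef_table(c("B[a]P" = 1, "Flthn" = 10, "1-MeA" = 20), "B[a]P")
#' predict_additive(
#'   mixture_spec(c("B[a]P" = 1, "Flthn" = 5, "1-MeA" = 5), "BaP+10uM mix"), tt)
#' @export
predict_additive <- function(mixture, tefs) {
  stopifnot(inherits(mixture, "mixture_spec"), inherits(tefs, "tef_table"))
  ref_dose <- attr(tefs, "ref_dose")
  effect_level <- attr(tefs, "effect_level")
  if (is.null(ref_dose) || is.null(effect_level)) {
    stop("TEF table carries no anchor (ref_dose / effect_level)", call. = FALSE)
  }
  teq <- teq_dose(mixture, tefs)
  pred <- effect_level * teq / ref_dose
  capped <- pred > 100
  pred <- min(pred, 100)
  label <- mixture$label
  observed <- mixture$observed_inhibition_pct
  tibble::tibble(
    mixture = label,
    teq_dose = teq,
    predicted_inhibition = pred,
    predicted_foc = 100 - pred,
    capped = capped,
    observed_inhibition = observed
  )
}

#' Compare additive-model predictions with observed inhibition
#'
#' @param predictions A tibble of predictions, typically row-bound output of
#'   [predict_additive()].
#' @param observed Named numeric vector, mixture label -> observed percent
#'   inhibition. Defaults to the `observed_inhibition` column of
#'   `predictions` when omitted.
#' @return The predictions tibble with `observed_inhibition` and
#'   `deviation` (observed - predicted, percentage points) columns, carrying
#'   a `mean_abs_deviation` attribute.
#' @examples
#' tt <- tef_table(c("B[a]P" = 1, "Flthn" = 10, "1-MeA" = 20), "B[a]P")
#' preds <- predict_additive(
#'   mixture_spec(c("B[a]P" = 1, "Flthn" = 5, "1-MeA" = 5), "m10"), tt)
#' compare_predictions(preds, c(m10 = 66))
#' @export
compare_predictions <- function(predictions, observed = NULL) {
  stopifnot(is.data.frame(predictions))
  if (is.null(observed)) {
    if (!"observed_inhibition" %in% names(predictions) ||
        anyNA(predictions$observed_inhibition)) {
      stop("no observed inhibition values supplied", call. = FALSE)
    }
    obs <- predictions$observed_inhibition
  } else {
    unmatched <- setdiff(predictions$mixture, names(observed))
    if (length(unmatched) > 0L) {
      stop(sprintf("no observed value for mixture(s): %s",
                   paste(unmatched, collapse = ", ")), call. = FALSE)
    }
    obs <- unname(observed[predictions$mixture])
  }
  out <- predictions
  out$observed_inhibition <- obs
  out$deviation <- obs - out$predicted_inhibition
  attr(out, "mean_abs_deviation") <- mean(abs(out$deviation))
  out
}

#' Fold factor by which TEFs from one endpoint misstate another
#'
#' TEFs are endpoint-specific: applying, say, carcinogenicity TEFs to a
#' co-carcinogenic endpoint under- or over-states potency by the ratio of
#' the two endpoint-specific TEFs.
#'
#' @param tef_endpoint_a TEF for the endpoint of interest (> 0).
#' @param tef_endpoint_b TEF taken from the other endpoint (> 0).
#' @return The fold factor `tef_endpoint_a / tef_endpoint_b`.
#' @examples
#' tef_misapplication_ratio(0.1, 0.001) # 100-fold underestimate
#' @export
tef_misapplication_ratio <- function(tef_endpoint_a, tef_endpoint_b) {
  if (!is.numeric(tef_endpoint_a) || !is.numeric(tef_endpoint_b) ||
      any(tef_endpoint_a <= 0) || any(tef_endpoint_b <= 0)) {
    stop("TEFs must be positive numbers", call. = FALSE)
  }
  tef_endpoint_a / tef_endpoint_b
}
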