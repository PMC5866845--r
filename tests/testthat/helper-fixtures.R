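# Shared fixtures built in code.

# dye-spread table with constant areas per treatment
flat_dye <- function(areas, n_exp = 1, n_dish = 3, n_cut = 3) {
  grid <- expand.grid(
    experiment_id = sprintf("e%d", seq_len(n_exp)),
    treatment = names(areas),
    dish_id = sprintf("d%d", seq_len(n_dish)),
    cut_id = sprintf("c%d", seq_len(n_cut)),
    stringsAsFactors = FALSE)
  grid$area <- unname(unlist(areas)[grid$treatment])
  grid
}

# qPCR table with fixed mean CTs, no noise
flat_qpcr <- function(cts, genes, n_exp = 1, n_rep = 2) {
  grid <- expand.grid(
    experiment_id = sprintf("e%d", seq_len(n_exp)),
    treatment = names(cts),
    gene = genes,
    replicate = sprintf("r%d", seq_len(n_rep)),
    stringsAsFactors = FALSE)
  grid$ct <- mapply(function(trt, g) cts[[trt]][[g]],
                    grid$treatment, grid$gene)
  grid
}

# the paper-condition dose-response curves: equi-effective doses
# 1 / 10 / 20 uM at the 40% GJIC-inhibition level
gjic_curves <- function() {
  list(
    "B[a]P" = dose_response_curve("B[a]P", c(0.3, 1, 3), c(15, 40, 65)),
    "Flthn" = dose_response_curve("Flthn", c(1, 10, 20), c(10, 40, 55)),
    "1-MeA" = dose_response_curve("1-MeA", c(2, 20, 40), c(10, 40, 55)))
}

# the three tested B[a]P + 1:1 LMW-mixture combinations with their
# observed GJIC inhibition
gjic_mixtures <- function() {
  list(
    mixture_spec(c("B[a]P" = 1, "Flthn" = 0.5, "1-MeA" = 0.5),
                 "B[a]P + 1 uM mix", observed_inhibition_pct = 47),
    mixture_spec(c("B[a]P" = 1, "Flthn" = 2.5, "1-MeA" = 2.5),
                 "B[a]P + 5 uM mix", observed_inhibition_pct = 62),
    mixture_spec(c("B[a]P" = 1, "Flthn" = 5, "1-MeA" = 5),
                 "B[a]P + 10 uM mix", observed_inhibition_pct = 66))
}
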