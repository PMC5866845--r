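Package: pahteq
Title: Endpoint-Specific Toxic Equivalency Analysis for PAH Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies co-carcinogenic endpoints of polycyclic aromatic
    hydrocarbon (PAH) exposure in lung epithelial cells and models mixture
    effects. Provides fraction-of-control quantification of gap junctional
    intercellular communication from scalpel-loaded dye-transfer assays,
    comparative-CT (delta-delta-CT) qPCR fold changes, DNA-adduct rates from
    HPLC fluorescence calibration curves, endpoint-specific toxic equivalency
    factors (TEFs) derived from equi-effective doses, an additive
    TEQ-based mixture-effect model with prediction-versus-observation
    comparison, one-way ANOVA with Student-Newman-Keuls post-hoc testing,
    and a seeded synthetic-data generator emulating the study design for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
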