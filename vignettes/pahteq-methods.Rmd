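---
title: "Methods: endpoint-specific TEQ analysis of PAH mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endpoint-specific TEQ analysis of PAH mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahteq)
```

`pahteq` quantifies co-carcinogenic endpoints of PAH exposure in lung
epithelial cells and asks whether mixture effects are additive once each
compound is weighted by an endpoint-specific potency. This vignette is the
package's account of the underlying models, its tunable parameters, the
synthetic-data generator, and the numerical and design choices made.

## The additive TEQ model

The toxic equivalency framework ranks compounds by potency relative to a
reference. `pahteq` makes that ranking *endpoint-specific*: potencies are
derived for one measured endpoint (by default, inhibition of gap junctional
intercellular communication, GJIC, after 24 h) and must not be transferred
to another.

Given per-compound dose–response curves (percent inhibition at increasing
µM doses), the **equi-effective dose** ED$_i$ is the dose at which compound
$i$ reaches a common effect level $E$ (default 40% inhibition). Then

$$\mathrm{TEF}_i = \frac{\mathrm{ED}_\mathrm{ref}}{\mathrm{ED}_i}, \qquad
\mathrm{TEQ} = \sum_i \mathrm{TEF}_i \, d_i, \qquad
\widehat{\mathrm{inhibition}} = E \cdot \frac{\mathrm{TEQ}}{\mathrm{ED}_\mathrm{ref}}
\;\; (\text{capped at } 100\%).$$

The prediction is linear in TEQ and anchored at the reference point: a
mixture whose TEQ equals ED$_\mathrm{ref}$ is predicted to produce exactly
$E$% inhibition. Linearity makes the model *effect-additive*: the mixture
prediction equals the sum of single-compound predictions (tested as an
invariant), and scaling all doses by $\alpha$ scales the pre-cap prediction
by $\alpha$. With B[a]P as reference (ED$_\mathrm{ref}$ = 1 µM at 40%) and
equi-effective doses of 10 µM (fluoranthene) and 20 µM
(1-methylanthracene), the TEFs are 1.0 / 0.1 / 0.05 and the three tested
B[a]P + binary-mixture combinations give predicted inhibition of 43, 55 and
70%:

```{r teq}
curves <- list(
  "B[a]P" = dose_response_curve("B[a]P", c(0.3, 1, 3), c(15, 40, 65)),
  "Flthn" = dose_response_curve("Flthn", c(1, 10, 20), c(10, 40, 55)),
  "1-MeA" = dose_response_curve("1-MeA", c(2, 20, 40), c(10, 40, 55)))
tefs <- compute_tefs(curves, reference = "B[a]P", effect_level = 40)
tefs
predict_additive(
  mixture_spec(c("B[a]P" = 1, "Flthn" = 5, "1-MeA" = 5), "B[a]P + 10 uM mix"),
  tefs)
```

Assumptions worth stating plainly: (1) monotone pharmacology — more dose,
more inhibition — which the TEF concept requires; (2) no interaction
(synergy or antagonism) between components; (3) linearity of effect in TEQ
between zero and the cap, including below the lowest tested dose of the
weaker components (mixture doses of 0.5 µM Flthn/1-MeA sit below their
tested range, so their contribution rests on linear down-scaling). The model
deliberately excludes Hill/log-logistic parametric fits and
Loewe/Bliss interaction indices; it is the simplest model consistent with
an additive reading of the data, and agreement of its predictions with
observation (mean absolute deviation 5 percentage points over the three
mixtures) is the empirical check, not a fitting target. These
co-carcinogenicity TEFs must not be used to rank carcinogenic risk — the
misapplication factor for fluoranthene against its carcinogenicity TEF is
100-fold in the opposite direction.

### Numerical choices

* **Interpolation** is linear on $\log_{10}$(dose) between the two
  observed points bracketing the effect level; a dose whose observed effect
  matches the level exactly is returned as-is, so stated equi-effective
  doses pass through unchanged.
* **Non-monotone curves** are first cleaned by isotonic regression
  (pool-adjacent-violators, `stats::isoreg`), attributing dips to
  measurement noise.
* **No extrapolation**: effect levels above the observed maximum *or below
  the lowest observed effect* are errors. The implicit (0 dose, 0 effect)
  anchor cannot be log-interpolated, and silently reading a dose off an
  untested region would hide an extrapolation from the user.
* The effect-level anchor (40%) is an explicit parameter, not a constant:
  it derives from averaging two observed reductions (47% and 34%) for 1 µM
  of the reference, and a user may anchor elsewhere.
* Predictions are reported unrounded; integer values in summaries come from
  rounding at display time.

## Assay quantifications feeding the model

**SL/DT fraction of control.** Dye-spread areas are aggregated
hierarchically — cuts averaged within dish, dish means within experiment —
and FOC is formed *within* each experiment as
$100 \cdot \bar A_\mathrm{trt} / \bar A_\mathrm{ctrl}$, then averaged
across experiments with an experiment-level SEM ($n$ = experiments). This
nesting order is a design choice: figure-legend conventions report $n = 3$
with experiment-level SEM, and forming the ratio within experiment removes
between-experiment scale differences (staining intensity, imaging
settings). FOC is scale-invariant and is not clipped at 100; enhanced
communication shows as FOC > 100 and negative inhibition.

**Comparative CT.** Technical replicates are averaged on the CT scale;
$\Delta CT = CT_\mathrm{target} - CT_\mathrm{18S}$,
$\Delta\Delta CT$ subtracts the control's $\Delta CT$ within the same
experiment, and the per-experiment fold change is $2^{-\Delta\Delta CT}$
with amplification efficiency fixed at perfect doubling (the method's
standard assumption; no dilution-series efficiency estimation is
attempted). Plate-wide CT shifts cancel exactly. Non-detects must be
`NA` and are dropped with a warning, never coerced to a cycle number.

**DNA adducts.** The B[a]P-tetrol I-1 peak response is converted to an
adduct rate in three steps: (1) an ordinary unweighted least-squares
calibration line on blank-corrected standard responses (validity range =
the standard range, 0.0095–1.52 µg/L; a fit is rejected unless the slope is
positive, and r² ≥ 0.98 is the quality gate applied downstream); (2)
inversion of the line plus the injected volume (600 µL; 1 µg/L × 1 µL =
1 pg) gives picograms of tetrol, flagged when outside the validity range;
(3) the mole ratio

$$\mathrm{rate} = \frac{m_\mathrm{tetrol}/320.34}{m_\mathrm{DNA}/330} \times 10^8$$

gives adducts per $10^8$ nucleotides, with 320.34 g/mol for the tetrol
(C$_{20}$H$_{16}$O$_4$), 330 g/mol as the mean nucleotide weight (standard
DNA convention), and hydrolysis assumed complete (one tetrol per adduct, no
recovery correction). Blank correction subtracts the mean blank response
before both fitting and quantification; negative rate estimates are
truncated to zero and flagged. Unweighted (rather than 1/x-weighted)
regression is the simplest defensible choice for a two-decade calibration
range.

**Statistics.** Group comparisons use classical equal-variance one-way
ANOVA followed by Student–Newman–Keuls (SNK) stepwise comparisons:
$q = |\bar y_i - \bar y_j| / \sqrt{\mathrm{MSW}/n_h}$ with the harmonic
mean $n_h$ for unequal groups (a generalization; the design here is
balanced at $n = 3$), compared against studentized-range quantiles
$q(\alpha, r, \mathrm{df}_w)$ evaluated numerically via `stats::qtukey`
(no hard-coded tables). The step-down rule is enforced structurally: a pair
inside a non-significant span is never declared significant. The degenerate
zero-within-variance case reports $F = \infty$, $p = 0$ explicitly. The
ANOVA response in the pipeline default is per-experiment FOC (raw areas are
also accepted). No Welch correction, two-way designs or other adjustment
methods are provided.

## The synthetic-data generator

The generator exists so that every estimator can be exercised, end to end,
without any external data. Its defaults encode the study conditions rather
than convenient values:

* replicate structure 3 dishes × 3 cuts × 3 experiments (the statistics
  section of the study protocol states triplicate experiments; some figure
  legends say duplicate — the count is configurable and defaults to 3);
* a treatment panel of DMSO vehicle, B[a]P at 0.3/1/3 µM, the 10 µM 1:1
  Flthn/1-MeA binary mixture, and 1 µM B[a]P + 1/5/10 µM mixture
  combinations;
* true FOC values matching the observed responses (100, 85, 60, 45, 75,
  53, 38, 34% respectively — the combinations at the observed 53/38/34
  triple, 1 µM B[a]P at the 40%-inhibition anchor);
* dye areas lognormal (positive, right-skewed) with CV 0.15 around a
  control median of 10,000 arbitrary units²; CT values normal with SD 0.15
  cycles around control anchors (normalizer 15, target 25) — typical
  technical precision, since only control-relative quantities are reported
  upstream;
* HPLC responses with multiplicative CV 0.02 (typical FLD peak-area
  precision) around a true line (slope 250 response units per µg/L,
  baseline 50); true adduct rates 0/60/240/990/420 per 10⁸ nucleotides,
  preserving the 16.5× low-to-high B[a]P dose ratio. The magnitudes are
  chosen so that sample tetrol concentrations fall *inside* the standards'
  calibration range at the default 25 µg DNA mass — a well-designed assay
  brackets its samples; the vehicle control sits at blank level and is
  flagged as below-range;
* default seed 20171123; identical seed and configuration give
  bit-identical tables, and the generators restore the caller's RNG state.

Setting a dispersion parameter to 0 gives the noiseless limit in which
every estimator recovers the configured truth exactly (tested); with
default noise, the configured truth falls inside the estimators' t-based
95% intervals in ≥ 90% of 200 seeded replicates (tested). What passing
these tests does *not* show: the generator draws independent,
well-behaved noise — real assays have dish-level correlation, plate
effects, chromatographic drift and occasional outliers, none of which are
emulated. Parameter recovery here validates the arithmetic of the
estimators, not their robustness to structured artefacts.

## Problem sizes and runtime

The simulation-based property checks use 200 seeded replicates per assay
for interval coverage and 5,000 null simulations (3 groups, $n = 3$) for
the SNK familywise error rate, sizes at which the binomial uncertainty of
the estimated rates is well below the margins being asserted. The whole
suite runs in well under five minutes on a single core.

## Known limitations

* TEFs are derived from interpolated equi-effective doses at a single
  effect level; compounds with non-parallel curves would yield different
  TEFs at other levels. The anchor is exposed as a parameter for exactly
  this reason.
* The additive model has no interaction terms by construction; systematic
  deviations between prediction and observation are the signal it is
  designed to expose, not something it can absorb.
* Adduct quantification assumes complete hydrolysis and full recovery;
  absolute rates are therefore lower bounds in real use, though ratios
  (fold changes between doses) are unaffected.
* The SNK procedure controls the familywise error at the complete null but,
  like all stepwise range procedures, is not a confidence-interval method;
  the package reports q statistics and decisions, not adjusted p-values.
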