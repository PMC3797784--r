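---
title: "Methods behind the hemorrhage-adjusted iron requirement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the hemorrhage-adjusted iron requirement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairmetric)
```

## The model

National reference intakes for dietary iron are set for people whose only
recurrent blood loss is menstruation. Anyone with additional hemorrhagic
losses — most visibly people with recurrent nosebleeds, but equally blood
donors or patients recovering from surgery — loses iron that those
allowances do not cover. The hemorrhage-adjusted iron requirement (HAIR)
makes that deficit explicit:

$$
\mathrm{HAIR} \;=\; \mathrm{base\ allowance}
\;+\; \frac{\bar{V}}{V_\mathrm{ref}} \times \Delta
$$

where $\bar V$ is the mean monthly blood loss over a three-month window
(mL/month), $V_\mathrm{ref}$ is the reference menstrual volume the scheme's
premenopausal increment was calibrated against (80 mL/month by default), and
$\Delta$ is the scheme's daily iron increment for that volume — by default
the difference between the premenopausal and default base allowances.

Key assumptions baked into the formula:

* **Linearity in volume.** Iron need scales proportionally with blood lost.
  Absorption adaptation, stores, and losses by other routes are out of scope.
* **Three-month averaging.** A single hemorrhage is amortized over three
  months (`loss_window_single()`); a steady monthly loss fills all three
  window months (`loss_window_recurring()`). The window length mirrors the
  lifetime of iron committed to erythropoiesis and the typical interval for
  repeat blood donation.
* **Scheme-relative bases.** The base allowance depends on the subject:
  pregnant women use `base_pregnant`, premenopausal women
  `base_premenopausal`, everyone else `base_default` (`resolve_base()`).

`log_hair` is the natural logarithm of HAIR; all regression operations in
the package use that convention.

## Reference-intake schemes

Three presets ship with the package (`default_schemes()` and
`inst/extdata/intake_schemes.yaml`):

| scheme | base_default | base_premenopausal | increment used |
|---|---|---|---|
| `us_rda` | 8 | 18 | 10 |
| `uk_rni` | 8.7 | 14.8 | 6.1 |
| `study_hybrid` | 8 | 18 | 6.1 (override) |

`study_hybrid` is deliberately inconsistent: it pairs the US bases with the
UK-derived increment via the `increment_override` field. Analyses are
sometimes run on exactly that hybrid — US allowances with the more
conservative UK increment — and the package supports it as a first-class
preset (for example, a steady 276.7 mL/month loss gives an extra
requirement of 21.1 mg/day and a HAIR of 29.1 mg/day for a male subject).
Users building new analyses should normally prefer one of the internally
consistent schemes.

## Epistaxis quantification

Nosebleed volumes are recovered from the three tick-box answers of an
epistaxis severity questionnaire: typical frequency, typical duration, and
whether bleeding is "gushing or pouring". Category midpoints are mapped to
numbers (`category_maps()`):

* frequency (bleeds/month): 0, 1, 3.5, 17.7, 30, 70 for the six boxes from
  "less than monthly" to "several per day";
* duration (min): 0.5, 2.5, 10, 23, 30 for "<1" through ">30";
* intensity (mL/min): 7.9 for gushing, 2.3 otherwise.

Monthly volume is the product of the three. The worst-case answers give
70 × 23 × 7.9 = 12,719 mL/month.

Two mappings deserve comment:

* **"Weekly" → 3.5/month.** The package maps the weekly box to 3.5
  bleeds/month rather than 52/12 ≈ 4.33. Both are defensible readings of
  "weekly"; 3.5 is the shipped default, and the maps are fully overridable
  through `category_maps()` if you prefer the calendar convention.
* **Intensity rates** come from calibration against timed-bleed records
  (below), taking the median rate of gushing reporters and of non-gushing
  reporters respectively.

## Rate calibration from timed-bleed records

`rate_percentiles()` turns self-timed bleed records (duration plus caught
volume in any supported unit) into mL/min percentiles. Numerical choices:

* **Unit conversions** (`unit_to_ml_factor`): imperial cup 284.131 mL, US
  cup 236.59 mL, and hemoglobin-drop reports at **750 mL per g/dl** — the
  convention for converting a whole survey-reported hemoglobin fall in an
  otherwise healthy adult.
* **Exclusion rule**: a record is excluded only if it is *uncorroborated*
  **and** implausible (rate above 50 mL/min or volume above 5,000 mL).
  Corroborated records are never excluded.
* **Percentiles** use `stats::quantile(type = 7)`: linear interpolation
  between order statistics, the R default. The test suite checks this
  against an independently coded interpolation oracle.

Note the deliberate coexistence of **two hemoglobin-fall conventions**:
750 mL/g/dl in the survey unit conversion above, and 470 mL/g/dl (one
transfusion unit per g/dl) in `hb_fall_to_volume()` and the
clinical-settings table. They model different situations — a survey
respondent's total loss versus a per-unit clinical equivalence — and the
package keeps them as separate, documented constants rather than
reconciling them.

## The clinical-settings table

`clinical_settings_table()` regenerates HAIR for typical scenarios (blood
donation every three months, hemoglobin falls of 1–4 g/dl, femoral fracture
at 611 mL) under the US and UK schemes, for default and premenopausal
bases. Presentation rounding is **half away from zero** to one decimal
(`round_half_up()`), not banker's rounding. The packaged golden CSV pins
every cell; where two arithmetically identical cells could round-display as
37.5 or 37.6, the table standardizes on 37.6 (the unrounded value is
37.583…, so half-up gives 37.6).

## Cohort analyses

* **Natural-breaks quintiles** (`natural_breaks_quintiles()`): the k−1 cut
  points are placed at the k−1 widest gaps between consecutive sorted
  values, with ties broken toward the lowest-position gaps. Tests verify
  equivalence with a brute-force search over all partitions into k
  contiguous groups (maximizing the sorted gap vector lexicographically) for
  n ≤ 15.
* **Quadratic HAIR regressions** (`quadratic_hair_regression()`):
  `lm(f(y) ~ hair + hair² + covariates)`, reporting the linear HAIR term
  with its 95% CI. `transform_select()` chooses identity versus natural log
  by normal QQ-plot correlation, forcing identity when any value is
  non-positive.
* **Nonparametric comparisons** (`nonparametric_compare()`): Mann–Whitney
  rank-sum and Spearman rank correlation via `stats::wilcox.test()` /
  `stats::cor.test()`, validated against an exhaustive permutation
  enumeration for small samples.
* **Stepwise logistic models** (`stepwise_logistic_anemia()`): backward
  elimination of the largest Wald p-value until all retained terms have
  p ≤ 0.10; perfectly separating predictors are detected and dropped with a
  warning rather than reported with runaway coefficients.

## Hepcidin–ferritin model

`fit_hepcidin_ferritin()` fits `ln(hepcidin) ~ ferritin + ferritin²`. The
quadratic term lets the fitted curve rise and then flatten/fall over the
observed ferritin range, matching the saturating behavior of the
iron-regulatory axis. `ratio_geometric_mean()` summarizes hepcidin:ferritin
ratios as `exp(mean ± 1.96·se)` of the log ratios. `add_covariate_probe()`
adds one candidate covariate to the fitted model and reports its Wald
p-value, flagging exact collinearity instead of reporting an `NA`
coefficient silently.

## The synthetic generator: what it emulates, and what it does not

`generate_cohort()`, `generate_timed_bleeds()`,
`generate_hepcidin_panels()`, and `generate_anemia_survey()` exist for one
purpose: *parameter-recovery testing* of the statistical machinery at
realistic problem sizes. They are calibrated so marginal summaries land in
clinically plausible ranges, but they make no claim to joint realism —
subjects' questionnaire answers are drawn independently of their
demographics, and hematinic indices depend on iron status only through the
generative HAIR terms.

Default calibration (all overridable through `generator_config()`):

* demographics 56% male / 34% postmenopausal / 10% premenopausal; dietary
  intake lognormal with median 11.3 mg/day;
* questionnaire category probabilities chosen so the implied frequency and
  duration medians under the default maps are 17.7 bleeds/month and 2.5
  min, with 34% gushing;
* supplement use probability 0.18, elemental doses in {20…65} × {1,2}
  mg/day, and an attenuation factor of 0.5 on the HAIR–hematinic slopes for
  supplement users (supplemented subjects partially compensate their
  deficit);
* hematinic slopes per unit HAIR: hemoglobin −0.0038 g/dl, plus analogous
  small coefficients for hematocrit, MCV, MCH, MCHC, log RDW, serum iron,
  transferrin saturation, and log ferritin;
* hepcidin: `ln(hepcidin) = 1.5 + 0.04·f − 0.00015·f² + ε`,
  ε ~ N(0, 0.53²), ferritin lognormal (median 54, sdlog 0.727) truncated to
  [6, 203]. The noise level was fixed once, before any test was written, so
  that the quadratic explains roughly 60% of ln-hepcidin variance.

Two generator-specific numerical choices:

* **Truncated-lognormal bleed rates.** `generate_timed_bleeds()` draws
  rates from a lognormal truncated above at the plausibility cap
  (50 mL/min), with the location parameter solved numerically
  (`stats::uniroot()`) so the *truncated* median equals the configured
  median exactly. Naive draw-and-reject sampling would bias the delivered
  median below the configured one; this construction keeps the generator's
  contract ("the configured median is the median you get") exact.
* **Seed hygiene.** Every generator runs under an internal `with_seed()`
  that saves and restores the caller's RNG state, so generation is
  deterministic given `seed` and never perturbs surrounding code.

## Problem sizes used in validation

The shipped tests exercise the machinery at the scales it is meant for:
cohorts of 50 (coverage checks, 200 replicates), hepcidin panels of 21,
anemia surveys of 424, timed-bleed sets up to 5,000, calibration cohorts of
10,000, and exhaustive-oracle comparisons at n ≤ 15 (natural breaks) and
group sizes ≤ 4 (rank-sum enumeration).

## Worked example

```{r example}
scheme <- default_schemes()$us_rda
donor <- subject_profile(age = 45, sex = "male")
compute_hair(donor, loss_window_single(470), scheme)
```
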