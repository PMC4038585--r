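---
title: "Methods: MoM-based first-trimester screening statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MoM-based first-trimester screening statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(momscreen)
library(dplyr)
```

## The problem

First-trimester screening for preeclampsia asks whether serum markers
measured at 8+0–13+6 weeks of gestation, combined with maternal
characteristics and mean arterial pressure (MAP), can flag the pregnancies
that will later develop early-onset (EO-PE, delivery before 34 weeks) or
late-onset (LO-PE, delivery at or after 34 weeks) disease. The statistical
machinery is the classic serum-screening toolkit: marker levels are
expressed as multiples of the gestation-specific normal median (MoM),
log-transformed, compared between cases and controls with multiplicity
control, folded into logistic risk models, and judged by the detection rate
(DR) achievable at a fixed false-positive rate (FPR), conventionally 10%.

`momscreen` implements that pipeline end to end, together with a synthetic
cohort generator that emulates the statistical structure such a study
assumes, so every stage is testable without access to any patient data.

## The cohort generator

The generator is the package's model of the data, not a fixture: its
defaults *are* the study conditions everything downstream is evaluated
under.

* **Design.** 500 controls, 68 EO-PE and 99 LO-PE cases, sampled uniformly
  over gestational days 56–97.
* **Marker model.** For analyte $a$ with control median $m_a(g)$ at
  gestational age $g$ days, a control's concentration is
  $m_a(g)\,10^{\varepsilon}$ with $\varepsilon \sim N(0, \sigma_a^2)$ on the
  log10 scale; $\log_{10} m_a(g)$ is linear in $g$. A case's concentration
  is additionally multiplied by the configured MoM ratio (MoMR) of its
  outcome group. The discriminative defaults are the published effect
  sizes: taurine 0.79 and asparagine 0.84 in EO-PE, glycylglycine 0.72 in
  LO-PE, MAP 1.10 (EO) and 1.07 (LO).
* **Dispersion.** The study prints no MoM dispersions, so the package fixes
  typical serum-screening values once: log10 MoM SD 0.10 for amines, 0.15
  for oxylipins and 0.04 for MAP. These were chosen as field-plausible
  defaults and are not tuned; the absolute DR levels the pipeline reaches
  depend on them, which is why reproducing published DR percentages is not
  a goal of the test suite — directional and effect-size properties are.
* **Censoring.** An analyte with `lod_quantile` $q > 0$ has its limit of
  detection placed at the empirical $q$-quantile of the control draw;
  values below it are masked. The default panel (58 amines, 46 oxylipins)
  censors two oxylipins at 25% and 30% so the detection filter has work to
  do, and one amine at 10% to exercise imputation.
* **Covariates.** Maternal weight, smoking, nulliparity and history of
  hypertensive disorders are drawn per group from the study's baseline
  table (e.g. nulliparity 46.6% / 80.9% / 72.7%); two null amines carry a
  weight effect of −0.002 log10 MoM per kg so the adjustment gate is
  non-trivial. Delivery timing respects the group definitions (EO < 34
  weeks, LO ≥ 34, controls ≥ 37); birthweight centiles are Beta-shaped to
  match the reported group medians approximately.
* **Blood pressures.** MAP is generated on the MoM scale and decomposed
  into systolic/diastolic pairs by drawing a pulse pressure of
  $N(40, 5^2)$ mmHg and inverting $\mathrm{MAP} = DBP + (SBP - DBP)/3$;
  only MAP is used downstream, so the decomposition merely needs to be
  consistent with that identity.
* **Independence.** Markers are generated independently given gestation and
  weight. Real metabolite panels are correlated (taurine and asparagine
  plausibly so); an optional correlation structure was considered and left
  out because no published value constrains it. Power and FDR behaviour on
  real data will differ to the extent such correlation matters.

What passing tests on these cohorts shows is that the *statistics* are
implemented correctly and recover what was put in; they do not show that
the published real-cohort detection rates are reproducible, since those
depend on unpublished dispersions and correlations.

## Preprocessing

Only analytes detected in **more than 80%** of samples are analysed; the
inequality is strict, so exactly 80% is dropped. Detection is counted over
all subjects pooled by default (the filter acts on metabolites, not on
groups); counting within chosen groups is available as an option. Remaining
below-LOD cells are imputed as **half the lowest detected value** of that
analyte — the conventional compromise between substituting zero and
truncating at the LOD. Imputation is idempotent and never touches detected
values. MAP is computed from the pressure pair before any MoM step and then
treated exactly like a marker.

## Study design

Subjects are assigned 40/30/30 to training/test/validation within each
outcome group. The rounding convention is round-half-up on the training and
test counts with validation as the remainder — the only simple rule that
reproduces all nine published counts (500 → 200/150/150, 68 → 27/20/21,
99 → 40/30/29) — and is documented as an inference, since the study does
not state its convention.

```{r}
split_sizes(68)
```

## MoM normalization

For each analyte, the median concentration and the number of women tested
are computed per completed gestational week (week 8 = days 56–62) among
**training-set controls only**, and $\log_{10}(\text{median})$ is regressed
on the week-midpoint day by least squares weighted by the per-week counts.
Regressing on the log scale guarantees positive predicted medians; the
original analysis states the regression of weekly medians without giving a
functional form, so the log-linear choice is the package's own, aligned
with the generator and with common screening practice. A subject's MoM is the measured value over the
predicted median at their gestational day; MoMs are log10-transformed.

Covariate adjustment follows Cuckle–Wald practice: among training controls,
each candidate covariate (weight, smoking, ethnicity by default) is tested
against each marker's log10-MoM (slope t-test for continuous covariates,
two-group t-test or one-way ANOVA for categorical ones); covariates
significant at two-sided $p < 0.05$ are fitted jointly and their effect is
subtracted on the log10-MoM scale, centred so an average-covariate control
is unchanged. Gestation is *not* re-adjusted — the median curve already
removes it, and adjusting again would double-correct. The 0.05 gate is a
package choice: the source procedure requires significance without
stating a level.

```{r}
cohort <- generate_cohort(cohort_config(
  n_controls = 400, n_eo = 60, n_lo = 0,
  analytes = analyte_spec("taurine", momr_eo = 0.79), seed = 7))
meas <- dplyr::bind_rows(cohort$measurements, map_as_marker(cohort$subjects))
splits <- assign_splits(cohort$subjects, seed = 7)
train_ids <- splits$subject_id[splits$set == "train"]
curves <- fit_median_curves(meas, cohort$subjects, train_ids)
moms <- compute_mom(meas, curves, cohort$subjects)
grp <- cohort$subjects$group[match(moms$subject_id, cohort$subjects$subject_id)]
mom_ratio(moms$mom[grp == "eo_pe" & moms$marker == "taurine"],
          moms$mom[grp == "control" & moms$marker == "taurine"])
```

The MoMR here is the ratio of group **medians**; whether the published
effect sizes are median or geometric-mean ratios is not stated, so the
geometric variant is available via `mom_ratio(type = "geometric")` (the two
coincide under the log-Gaussian model).

## Marker pre-selection

Per outcome, every retained marker plus MAP is compared between cases and
controls of the training set with a pooled-variance Student's t-test on
log10-MoMs (Welch available as an option), and p-values are corrected by
Benjamini–Hochberg across that whole family. Markers with FDR $q$ strictly
below 15% are selected. Whether the original analysis pooled amines and
oxylipins into one FDR family is unstated; this package pools all tested
markers per outcome, which matches an effect-size table that lists MAP and
amines under one FDR column.

## Risk models

The prior risk is a maximum-likelihood logistic model of case status on
maternal characteristics alone (nulliparity, weight, history, smoking by
default), refit on the training set — external published prior-risk
coefficients are deliberately not copied. Combined models are plain
logistic fits (no regularization, tolerance $10^{-8}$, at most 100
iterations) of the outcome on the prior together with subsets of
{MAP} ∪ selected markers; all $2^k$ subsets are enumerated.

How the prior enters is genuinely under-specified in the source: the
printed prediction rules show only MAP and taurine terms although the
models are labelled "prior risk + …". The package therefore supports both
readings — prior log-odds as a free covariate (default) and as a fixed
offset — and asserts neither as the original. A related inconsistency
(the printed late-onset rule contains a taurine term although
glycylglycine was the late-onset-selected marker) is left as found; the
package reports its own selections.

Markers enter models as log10-MoM values. In coefficient-recovery
simulations the covariates are drawn zero-mean — with a control MoM of 1
the printed EO intercept and MAP slope would otherwise put essentially
every subject at risk ≈ 1, so the printed rules can only be centred-scale.
Those simulations use $n = 200{,}000$ with covariate variances 0.04 (MAP)
and 0.10 (taurine), sizes at which every coefficient's sampling error is
comfortably below 3%.

## Evaluation

The risk threshold is the empirical $(1-\mathrm{FPR})$ quantile of the
control scores using the inverse empirical CDF (quantile type 1), and
subjects are called positive by strict `>`. This convention is exactly
reproducible and checkable against brute-force threshold enumeration,
which the tests do exhaustively on small score sets; the source does not
state its convention. At FPR = 1 the threshold sits below all controls.
Detection-rate confidence intervals are Wilson score intervals — a package
choice, since the study prints 95% CIs without naming a method. AUC is the
Mann–Whitney probability with ties counted one half.

Model selection takes the candidate with the highest test-set DR; ties
(exact equality by default, an epsilon is configurable) go to the model
with fewest terms, mirroring the rejection of a larger model that adds a
marker without improving detection. The winner alone is validated on the
held-out set, and re-examined within the growth-restricted
(birthweight < 10th centile) and AGA case subgroups; an empty subgroup
yields an explicit empty-result row rather than an error.

## Numerical and degenerate-input choices

* Round-half-up (`floor(x + 0.5)`) for split sizes, not banker's rounding.
* Curve fitting requires at least two represented weeks; zero or negative
  concentrations are errors rather than silently logged.
* An analyte with no detected values cannot be imputed and errors.
* Constant covariates (in adjustment) and constant characteristics (in the
  prior fit) are dropped with a warning — at 27 training cases a 1–6%
  prevalence characteristic is regularly all-FALSE.
* Collinear model designs and non-convergent or separated logistic fits
  are errors with diagnostics, not silent NA coefficients.
* All randomness flows through explicit integer seeds
  (`withr::with_seed`), so identical configs are bit-identical and the
  caller's RNG state is never disturbed.

## Problem sizes used in the tests

Effect-size recovery uses 5000 subjects per group (median-ratio
Monte-Carlo error ≈ 0.004, against a ±0.02 band); weekly-median invariants
use ~500 training controls per week; the null-FDR property uses 500
replicates of a 40-marker panel; the end-to-end directional property uses
100 study-scale replicates. These sizes were picked so each check's
Monte-Carlo noise is several times smaller than the property's tolerance.

## Known limitations

* Markers are conditionally independent in the generator; real panels are
  not.
* Median curves are log-linear only; spline curves are out of scope.
* The single fixed train/test/validation partition of the original design
  is replicated as-is; no cross-validation.
* Absolute DR levels on synthetic cohorts are functions of the assumed
  dispersions and should not be read as predictions for real serum data.
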