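---
title: "Scoring, pipeline and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, pipeline and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msofa)
```

This vignette documents the modelling and numerical decisions behind the
package: how the modified SOFA (mSOFA) score is computed, how the cohort
pipeline turns raw observations into the per-patient score family, what the
statistical layer assumes, and what the synthetic-cohort generator does and
does not emulate.

## The score and its boundary conventions

The mSOFA score sums six organ components, each an integer 0–4, to a total
of 0–24. The single substantive modification relative to the classic SOFA
score is respiratory: the SpO₂/FiO₂ ratio (pulse-oximetry saturation in
percent over the inspired-oxygen fraction) replaces PaO₂/FiO₂, with bands
>301 / 221–301 / 142–220 / 67–141 / <67 mapping to 0–4 points. This keeps
the respiratory component computable when no blood gas is available, at a
known cost: saturation is insensitive above ~97 %, so the SpO₂ form tends to
understate the severity of the sickest lungs (a patient at SpO₂ 90 % on
FiO₂ 1.0 scores 3; the same patient would typically have a PaO₂ near
60 mmHg and score 4 under the original bands).

Published score cards state bands with open edges ("<150" next to ">150"),
leaving exact boundary values unassigned. A scoring function cannot have
gaps, so the package fixes one convention, stored declaratively in
`msofa_bands` so tests enumerate it:

* Every band is a half-open interval, closed at its lower edge, except that
  respiratory band 1 keeps its printed closed upper edge (221–301 and
  300–400 inclusive), since the adjacent band is printed strictly as ">301"
  (">400").
* Consequently platelets exactly 150 score 0, bilirubin exactly 12 scores 4,
  creatinine exactly 5.0 scores 4, an SpO₂/FiO₂ ratio of exactly 67 scores
  3, and GCS 15 alone scores 0.

These are conventions, not clinical claims; they give a total order with no
unscorable values, and the band-partition property (every admissible input
falls in exactly one band) is under test.

Further scoring decisions:

* **FiO₂ estimation.** On nasal cannula, FiO₂ = 0.21 + 0.03 × flow (L/min).
  The linear rule is unbounded, so the estimate is clipped to the physical
  range [0.21, 1.0]. Room air is 0.21 by definition; masks and ventilators
  require a recorded FiO₂.
* **Vasopressors.** Each running agent is scored by its own dose band
  (dopamine ≤5 → 2, >5 → 3, >15 → 4; dobutamine any dose → 2;
  norepinephrine ≤0.1 → 3, >0.1 → 4) and the maximum is taken across
  agents and the MAP band — the same worst-value philosophy used in the
  time dimension. Dobutamine alone never scores above 2. Agents outside
  this set (e.g. epinephrine) are rejected rather than guessed at.
* **SpO₂ = 100 % readings** are scored as-is; no ceiling correction is
  applied.

## Cohort pipeline

**Eligibility.** Analysis covers patients older than 12 years who stayed in
the ICU beyond 24 h: records are excluded (one primary reason each, in this
precedence) for age ≤ 12, low-risk-monitoring admission (an explicit flag in
the input — it cannot be derived from physiology), death or discharge within
24 h (`icu_los_days ≤ 1`), or a missing outcome. The report tallies each
reason and satisfies `analyzed = enrolled − excluded` by construction.

**Windows.** T0 is the admission window `[0, 24)` h and T48 the window
`[24, 48]` h, half-open at the seam so no observation is counted twice. The
worst value of each parameter within the window is used: the minimum for
oxygenation ratio, platelets, MAP, GCS and urine output; the maximum for
bilirubin, creatinine and vasopressor doses. The respiratory component uses
the per-observation ratio (each SpO₂ paired with its concurrent FiO₂) and
takes the minimum ratio, rather than pairing the worst SpO₂ with a
non-concurrent FiO₂.

**Imputation.** A single missing value flanked by measurements is replaced
by the arithmetic mean of its two neighbors; leading/trailing gaps and runs
of two or more stay missing. Imputation runs on the per-parameter
time-ordered observation series *before* window extraction: with only two
scoring windows, a per-window series has no interior positions, so
neighbor-mean imputation can only ever operate at the observation level.
The operation is idempotent and never alters observed values (both under
test).

**Missing components.** An organ with no usable data in a window even after
imputation is scored 0 and counted in per-patient completeness flags
(`t0_n_missing`, `t48_n_missing`), mirroring common SOFA practice where
absent measurements are read as "not deranged enough to measure" — but the
choice is visible, and a strict mode drops such patients instead. A window
with no observations at all makes the patient unscorable; they are removed
with a logged reason rather than scored.

**Derived family.** Per patient: initial = T0 total; 48-h = T48 total;
mean = (T0 + T48)/2; highest = max; delta = T48 − T0 (so improving
survivors have negative delta); total = T0 + T48. The identities
`delta = at48 − initial`, `total_sum = 2 × mean_score` and
`highest = max(initial, at48)` hold exactly and are asserted on every
simulated cohort.

## Statistical layer

* **AUROC** is the Mann–Whitney concordance: the probability a random
  non-survivor outscores a random survivor, ties counting ½. It is computed
  via midranks, which is algebraically the all-pairs average; the test suite
  checks exact agreement with explicit pair enumeration, and invariance
  under strictly increasing score transforms.
* **Confidence intervals** use the DeLong structural-components
  (placement-value) variance with a normal approximation, clipped to
  [0, 1]; the paired test for two score variants on the same patients uses
  the placement-value covariance. The interval method is a choice — the
  published tables this design follows print CIs without naming one — so a
  stratified bootstrap (2000 replicates, seeded) is available as an
  alternative. Degenerate inputs (fewer than 2 per class) are refused with
  a pointer to the bootstrap at larger n.
* **Group comparisons** default to Welch's t-test (group variances in
  severity-score data are routinely unequal); the pooled form is a flag.
  `method = "auto"` applies a Shapiro–Wilk pre-check at the 0.05 level in
  each group and falls back to the Mann–Whitney test, recording both the
  choice and the normality p-values. Fully degenerate inputs (two constant
  groups) return p = 1 when equal and p = 0 when not, instead of erroring.
* **Logistic regression** is the maximum-likelihood fit by iteratively
  reweighted least squares, with Wald CIs exponentiated to the odds-ratio
  scale. Constant and collinear covariates are rejected by name; complete
  separation (every event ranked above every non-event with a boundary
  likelihood) suppresses the meaningless Wald intervals and raises a flag.
  The default adjustment set — score variant plus age, sex, mechanical
  ventilation and vasopressor use — is a package choice, fully
  configurable, and every output is labelled with the covariates used.
* **No multiple-testing correction** is applied; the analysis object
  reports how many tests it ran so readers can judge.

## Synthetic cohort generator

No patient-level data accompany the study design this package implements, so
the generator is the package's own minimal model, built so that (a) every
scoring band is reachable, (b) the score–mortality association is one
tunable knob, and (c) the exact null is obtainable.

Each patient carries a latent severity `z0 ~ N(0, 1)` and a latent drift
`d ~ N(0, 1)`. ICU death is Bernoulli with
`logit p = α + β·z0 + γ·d`, where β (`severity_effect`, default 0.8) and γ
(`delta_effect`, default 0.5) are log-odds per latent unit and α is
calibrated by root-finding so the expected mortality equals the target
(default 0.466). The 48-h severity is `z48 = z0 + d + δ(outcome)` with
outcome-conditional divergence δ = −0.8 for survivors and +0.5 for
non-survivors, which at the roughly 2-points-per-latent-unit slope of the
links yields the characteristic pattern of scores falling by about 1.7
points in survivors and rising by about 1 point in non-survivors.

Physiology at observation times 4, 16, 28 and 44 h is generated from the
prevailing latent severity (plus N(0, 0.25) observation noise) through
clipped linear/log-linear Gaussian links, centered so a typical patient
(z = 0) lands near the admission subscore profile of a severe ICU cohort:

| Parameter | Link (then clipped) |
|---|---|
| SpO₂ (%) | 94 − 5z + N(0, 4), clip [40, 100] |
| FiO₂ target | 0.45 + 0.18z + N(0, 0.06), clip [0.21, 1]; device/flow derived |
| PaO₂ (mmHg) | 30 + 1.8(SpO₂ − 30) + N(0, 10), clip [30, 500] |
| MAP (mmHg) | 82 − 7z + N(0, 8), clip [30, 180] |
| GCS | round(10 − 3z + N(0, 2)), clip [3, 15] |
| Platelets (10³/mm³) | 230 − 60z + N(0, 40), clip [5, 900] |
| Bilirubin (mg/dL) | exp(−0.5 + 0.5z + N(0, 0.4)), clip [0.1, 60] |
| Creatinine (mg/dL) | exp(0.2 + 0.4z + N(0, 0.35)), clip [0.2, 25] |
| Urine output (mL/d) | 1500 − 320z + N(0, 300), clip [0, 5000] |
| Vasopressor dose | drug-specific scale × exp(0.5z + N(0, 0.3)), if running |

Vasopressor use and mechanical ventilation are Bernoulli in z0; PaO₂ is
blanked with probability 0.9 by default (the modification exists precisely
because PaO₂ is mostly missing), urine output with 0.1, vitals with 0.02.
Eligibility decoys — low-risk-monitoring admissions (shifted milder by 1.5
latent units), early deaths/discharges, missing outcomes, optionally
children — are injected at configurable fractions; the defaults (42/170,
9/170, 1/170 of 170 enrolled) make the default cohort filter down to about
118 analyzed patients. Demographics are simple draws (age ~ N(37, 17)
floored at 13; 58 % male).

The same configuration and seed give byte-identical output files; the
ground truth (`z0`, `z48`, `d`, `p_death`) is written to a separate file and
never enters the cohort schema.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: organ-system coupling and pharmacokinetics
(links are independent given z), informative missingness (blanking is
uniform at random, while real PaO₂ absence correlates with care intensity),
measurement error structure of oximetry at low saturation, admission-source
case mix beyond marginal frequencies, and length-of-stay dynamics beyond
the 24-h exclusion rule. Agreement between scored totals and latent
severity is built in by the monotone links; it validates the plumbing, not
the clinical score.

## Numerical choices and problem sizes

Root-finding for the mortality intercept uses `uniroot` on [−30, 30] and
refuses targets of exactly 0 or 1. Paired DeLong tests with zero variance
(identical scores) return p = 1 rather than 0/0. AUC intervals are clipped
to [0, 1] after the normal approximation. All random draws in tests and
scripts are seeded.

The test suite exercises: 10⁴ randomized inputs for the subscore
range/monotonicity/partition properties; 500 random cohorts (n ≤ 200) for
exact AUROC–concordance agreement; 1000 replicates at n = 118 (55 deaths)
for DeLong CI coverage at true AUC 0.75 and for the two type-I-error nulls,
judged within three binomial standard errors of nominal; and n = 10⁴ for
logistic parameter recovery within ±10 %. These sizes make the Monte-Carlo
error small relative to the tolerances while keeping the default suite
under a minute per file.

## Known limitations

* The boundary conventions above are one defensible reading of ambiguous
  printed bands; a cohort scored under a different convention can differ by
  a point at exact boundaries.
* The SpO₂ respiratory criterion saturates: its worst band (<67) is nearly
  unreachable while oxygen delivery is accurate, and unreliable oxygen
  sources bias FiO₂ — both inherited properties of the modification itself.
* Scoring is restricted to the two study timepoints 48 h apart; no
  interpolation to other horizons is attempted.
* The logistic layer reports the model it fits; with ~118 patients and five
  covariates, non-significant adjusted odds ratios are the expected
  behaviour, not evidence of no association.
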