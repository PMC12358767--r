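---
title: "Dose-specific screening of adverse three-drug combinations"
author: "triplerx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-specific screening of adverse three-drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplerx)
```

## The problem

Adverse drug events (ADEs) such as acute kidney injury, gastrointestinal
bleeding or hypoglycemia are often precipitated by *combinations* of drugs,
and for many of them risk is strongly dose-dependent. Claims databases
record enough — diagnoses at emergency-department (ED) visits, enrollment
spans, and pharmacy fills with dose, quantity and days of supply — to
screen thousands of three-drug combinations for dose-specific risk.
`triplerx` implements that screen end to end: cohort construction, dose
coding, a per-triplet interaction model, multiplicity control, signal
selection, and dose-reduction profiling, plus a synthetic claims generator
that makes every inferential property of the pipeline testable.

## Cohort construction

A **case** is a person's earliest ED visit that (i) falls in the study
window (default 2008–2021), (ii) is preceded by more than 365 days of
continuous enrollment, (iii) has no other ED visit in the prior 180 days,
and (iv) carries an outcome diagnosis code in position 1 or 2. Persons with
any outcome diagnosis before that visit are excluded; so are control
candidates with a prior outcome diagnosis. Controls are matched 1:1 without
replacement on gender, race and the binary risk-factor vector (exact), age
within ±2 years, and the calendar year-month of the ED visit within ±2
months.

Design choices a reader should know about:

* **Matching algorithm.** Greedy nearest-match without replacement: cases
  in ascending index-date order (ties by person id), each taking the
  candidate minimising |age difference| then |month difference| then
  person id. Greedy matching is the standard claims-study default, is
  deterministic, and makes the unmatched-case report exact. Optimal
  (maximum-cardinality) matching is out of scope.
* **Age** is computed from birth year only — `floor((index − Jan 1 of
  birth year)/365.25)` — because claims tables carry no birth date; the ±2
  year caliper applies to these integer ages.
* **"Year-month ± 2 months"** is read literally as a calendar-month index
  difference of at most 2, ignoring the day of month.
* **Risk factors** are assessed over all history before the index date; no
  lookback bound is imposed.
* The same global study window applies to cases and controls; a control's
  qualifying visit is not constrained to its case's window beyond the ±2
  month caliper. A person may contribute several qualifying visits to the
  candidate pool but is used at most once.

## Dose coding

For each drug ingredient-unit combination (an ingredient dispensed in two
units, e.g. milligrams and percent, forms two columns) the **average daily
dose** over fills dated in `[index − 30 d, index)` is

$$\mathrm{ADS} = \frac{\sum_f \text{dose per unit}_f \times \text{quantity}_f}
                      {\sum_f \text{days of supply}_f}.$$

The single-fill version of this formula is the field's standard; the
pooled form above is our multi-fill extension — it reduces to the
single-fill formula for one fill and is robust to overlapping fills. Fills
are included if their *fill date* is in the window; days of supply are not
prorated at the boundary. In-window fills with non-positive days of supply
are data errors: rejected with a logged warning rather than silently kept
or fatal.

Doses are coded ternary against per-drug thresholds: 0 (no exposure),
1 (0 < ADS ≤ threshold), 2 (ADS > threshold). The threshold is the **median
ADS among exposed cases** (ADS > 0), with the even-count median taken as
the mean of the two middle order statistics so thresholds are
bit-reproducible. Two deliberate readings:

* *Exposed cases only.* A median over all cases including the unexposed
  would collapse to zero whenever fewer than half the cases are exposed,
  leaving the low-dose class empty; the exposed-only support is the only
  reading under which "0 < ADS ≤ median" defines a non-degenerate class.
* *Cases only.* Control exposures never influence thresholds — a property
  the test suite enforces by perturbing control fills and asserting
  thresholds are unchanged.

The top-`k` (default 200) drug-units by exposed-case count are retained,
ties broken lexicographically.

## The per-triplet model

For a triplet with dose codes $X_1, X_2, X_3 \in \{0,1,2\}$:

$$\operatorname{logit} P(\text{case}) = \alpha + \beta_1 X_1 + \beta_2 X_2 +
\beta_3 X_3 + \beta_4 X_1X_2 + \beta_5 X_1X_3 + \beta_6 X_2X_3 +
\beta_7 X_1X_2X_3.$$

The stratum effect $\alpha$ is handled by **conditioning**: for 1:1 pairs
the conditional likelihood contribution of a pair with case/control
regressor rows $z_c, z_0$ is $\exp(\beta'z_c)/(\exp(\beta'z_c) +
\exp(\beta'z_0))$, which is free of $\alpha$. We state this explicitly
because a genuine random-intercept (mixed-model) fit would integrate over
$\alpha$ and give different estimates; the conditional likelihood is the
standard and exact treatment for matched sets and is what `fit_clrm()`
maximises. Concordant pairs contribute a constant $\log\tfrac12$ and carry
no information about $\beta$.

### Numerical choices

* **Optimizer.** Newton–Raphson on the within-pair difference
  representation, started at $\beta = 0$, with step-halving (the objective
  is concave, so a short enough Newton step always ascends), a gradient
  max-norm tolerance of `1e-8`, and a 100-iteration cap. A fixed
  deterministic optimizer keeps estimates bit-stable across runs.
* **Covariance** is the inverse observed information at the maximum;
  contrasts use the delta-method quadratic form.
* **Degenerate inputs.** All-concordant designs raise a "no information"
  error; rank-deficient designs raise an error naming the aliased columns
  (e.g. a triplet in which only one drug's dose ever varies).
* **Separation.** If any coefficient escapes ±15 on the log-odds scale
  while the score has not vanished the fit is flagged as separated,
  reported in a quarantine list, and excluded from testing and FDR pooling
  — never silently dropped, never "rescued" by penalisation (noted as an
  extension point).

### Testing battery and contrasts

Each tested triplet yields eight one-sided Wald p-values: $\beta_j \le 0$
for $j = 1..7$, and the highest-dose composite
$2\beta_1+2\beta_2+2\beta_3+4\beta_4+4\beta_5+4\beta_6+8\beta_7 \le 0$ —
the log-OR of configuration (2,2,2) versus no exposure, since the contrast
vector is exactly `design_row(2,2,2)`. All contrasts in the package are
generated from `design_row()` differences rather than hand-entered
coefficient tables; the ten dose-reduction/discontinuation contrasts
(label = the reduced configuration, e.g. "221" for reducing drug 3 to low
dose, "022" for discontinuing drug 1) are regenerated this way and frozen
in the tests. One-sided p-values use the upper normal tail, matching the
direction "no increased risk / no risk reduction".

## Multiplicity and signal selection

All eight p-values of all tested triplets enter **one pooled
Benjamini–Hochberg family** (`stats::p.adjust`); a per-test-type family is
available behind `pool_by_test_type` but off by default, since the pooled
family is the screen's defining choice. Triplets are tested only when at
least `min_case_count` (default 500) cases are co-exposed to all three
drugs and the triplet contains at least one outcome-related drug
(`required_drug_set`, deliberately mandatory — an empty set is a
configuration error, not "no filter").

A tested triplet is a **signal** when

1. the composite highest-dose q-value is below `fdr_level` (default 0.05),
2. the OR at (2,2,2) is at least `or_min` (default 1.3), and
3. each of the three drugs is individually risky: a positive main-effect
   estimate, or membership in an interaction term whose q-value passes the
   FDR level.

Criterion 3 formalises "three risky individual effects and/or significant
interactions", which admits more than one reading; ours is the literal
conjunction, it is config-toggleable, and every non-signal records
`reason_codes` naming the failed criteria so alternative readings can be
audited from the output alone. Whether criterion 2 should apply to every
exposed configuration rather than only (2,2,2) is similarly ambiguous; the
default applies it to (2,2,2), with `strict_or_all_configs` available.

## Dose profiling

For each signal the full 27-configuration OR grid (with 95% Wald CIs
relative to (0,0,0)) is computed — the complete grid makes figure-style
outputs and audits trivial even though only a subset is typically reported
— along with the ten reduction tests and the percent OR decrement
$100(1 - \mathrm{OR}_{\text{low}}/\mathrm{OR}_{222})$, flagged significant
at p < 0.05. Median-OR summaries pool ORs **across signals within
stratum** (highest dose; one drug reduced — three ORs per signal; two
drugs reduced; all three reduced), since the distribution being summarised
is over signal-configuration pairs; per-signal aggregation first is
available behind `per_profile`.

## The synthetic claims generator

Two levels, both seeded through one master seed with deterministic
per-stage substreams (so partial re-runs reproduce):

* `generate_matched_pairs()` draws pair-member dose triples from a
  configurable per-drug level distribution and assigns the case label from
  the *exact* conditional probability
  $\exp(\eta_a)/(\exp(\eta_a)+\exp(\eta_b))$. This is the estimator's
  native model: it is what CI-coverage, type-I-error and FDR calibration
  studies simulate from.
* `generate_population()` emits persons/diagnoses/claims tables with
  referential integrity: lognormal per-drug ADS (right-skewed, as real
  daily doses are) decomposed into fills with days of supply in {7, 14,
  30}; risk-factor histories; deliberate fractions of short enrollment
  (~5%), recent prior ED visits (~5%), prior outcome diagnoses (~3%) and
  out-of-window fills (~20%) so every exclusion rule is exercised; and an
  outcome drawn from a person-level logistic model with planted triplet
  effects on the latent dose codes plus a normal random intercept
  (sd 0.3 by default) shared within a matching cell — the stratum effect
  that matching later absorbs.

What the generator does **not** emulate: realistic ICD/NDC vocabularies,
longitudinal disease progression, confounding by indication, time-varying
exposure, or dose measurement error beyond the threshold recoding. Passing
tests therefore demonstrate that the pipeline's logic and inference are
correct under its stated model — not that real claims data satisfy that
model.

The bundled demonstration (`demo_pipeline_config()`) plants one triplet
among five drugs with high-dose main effects of 0.5 log-odds per drug and
a small three-way interaction, in 6000 persons with 8% baseline outcome
prevalence — strong enough that detection is expected in essentially every
seeded run, which is what an end-to-end smoke screen should be.

## Calibration studies and problem sizes

The package ships its own evaluation harness (`coverage_study()`,
`type1_error_study()`, `fdr_calibration_study()`,
`demo_detection_study()`), used by both the test suite and
`scripts/acceptance.R`. The shipped sizes — 1000 replicates of 5000 pairs
for CI coverage, 3000 replicates for the composite test's type-I error,
500 null screens of 50 triplets for the false-signal rate, 20 seeded
demonstration runs — were chosen so each study's Monte-Carlo standard
error is small relative to the property being checked (e.g. coverage
within ±2 binomial SEs of 95%) while the whole battery completes in a few
minutes on one CPU.

## Known limitations

* 1:1 strata only; m:n matching and exact conditional inference are out of
  scope.
* Separation is flagged and quarantined, not penalised (no Firth-type
  fallback yet).
* Thresholds are data-driven medians, not clinically vetted cutoffs.
* Greedy matching does not maximise the number of matched pairs.
* The screen is marginal per triplet: overlapping triplets sharing a
  genuinely risky drug will co-signal, as the demonstration shows.
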