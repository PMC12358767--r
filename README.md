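# triplerx

High-throughput, dose-specific screening of **adverse three-drug
combinations** in claims-style data.

Polypharmacy is common — a fifth of US adults and two thirds of older
adults take three or more drugs concurrently — and drug dose is a major
determinant of adverse drug event (ADE) risk. `triplerx` implements a
matched case-control screening pipeline that asks, for every candidate
triplet of drugs, not just *whether* the combination is associated with an
ADE but *at which dose levels*, and how much risk would change if one drug
were reduced or discontinued.

## The model

For an ADE outcome, cases (first ED visit carrying the outcome diagnosis in
position 1–2, with enrollment and washout rules) are 1:1 matched to
controls on gender, race and risk factors (exact) plus age (±2 years) and
ED-visit year-month (±2 months). Exposure in the 30 days before the index
date is summarised per drug ingredient-unit as the **average daily dose**

    ADS = Σ(dose per unit × quantity) / Σ(days of supply)

and coded ternary against the median ADS among exposed cases:
`X = 0` (none), `1` (0 < ADS ≤ median), `2` (ADS > median).

Each drug triplet is fit with the **conditional logistic regression**

    logit P(case) = α + β₁X₁ + β₂X₂ + β₃X₃ + β₄X₁X₂ + β₅X₁X₃ + β₆X₂X₃ + β₇X₁X₂X₃

where the pair effect α is eliminated by conditioning on one case per pair.
Eight one-sided Wald tests per triplet (each βⱼ ≤ 0, plus the highest-dose
composite 2β₁+2β₂+2β₃+4β₄+4β₅+4β₆+8β₇ ≤ 0) are pooled across all tested
triplets into a single Benjamini–Hochberg family. A triplet is flagged a
**signal** when the composite test passes FDR, the odds ratio at dose
(2,2,2) clears a minimum (default 1.3), and each drug shows a risky effect
pattern. For signals, the full 27-point dose grid is profiled and ten
dose-reduction / discontinuation contrasts (e.g. (2,2,2) vs (2,2,1):
β₃+2β₅+2β₆+4β₇) are tested.

A seeded synthetic claims generator — both raw relational tables and
matched pairs drawn from the exact conditional model — ships with the
package for end-to-end testing and calibration studies.

## Worked example

```r
library(triplerx)

cfg <- demo_pipeline_config(seed = 7)   # 6000 persons, one planted triplet
run <- run_pipeline(cfg)

str(run$manifest$counts)
#> $ persons             : int 6000
#> $ cases               : int 1403
#> $ pairs_matched       : int 1370
#> $ triplets_tested     : int 6
#> $ signals             : int 5

run$screen$results[1, c("drug1", "drug2", "drug3", "or_222", "q_or222", "signal")]
#>        drug1      drug2      drug3   or_222      q_or222 signal
#> 1 drug_01|mg drug_02|mg drug_03|mg 45.05962 2.587959e-32   TRUE

run$medians
#>                       stratum median_or  n
#> 1                highest dose 12.179558  5
#> 2     lower dose for one drug  7.078802 15
#> 3   lower doses for two drugs  5.855291 15
#> 4 lower doses for three drugs  3.391214  5
```

The planted triplet (drugs 1–3, strong positive dose effects) is recovered
as a signal; its OR at the highest dose level (45, against a generating
conditional OR of ~30 plus matched-sampling noise) dwarfs the reduced-dose
configurations, and the median OR across signals falls monotonically as
more drugs move from high to low dose — the dose-response pattern the
screen is designed to surface. Overlapping triplets that share the planted
drugs also reach significance, as expected under marginal screening.

Per-run artifacts (`pairs.csv`, `thresholds.csv`, `dose_matrix.csv`,
`screening_results.csv`, `profiles.csv`, `medians.csv`, `signals.json`,
`manifest.json`, `report.md`) land in `cfg$outdir`.

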