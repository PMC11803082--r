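---
title: "Methods: age- and sex-disaggregated antibiotic prescribing metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age- and sex-disaggregated antibiotic prescribing metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxdemog)
library(data.table)
```

This vignette is the package's own account of the methods it implements:
the data model, each metric and its assumptions, the parameters that matter,
the numerical choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish about real data.

## Data model and exclusion handling

The unit of analysis is the *disaggregated cell*: items dispensed in one
month for one drug, one of 23 age bands, one gender, one region. Cells with
fewer than five items arrive redacted; a redacted cell's true count is an
integer in 1–4. The canonical in-memory form keeps redacted counts as `NA`
until `impute_redacted()` substitutes a value — 1 in the main analysis, with
the 1–4 envelope explored by `sensitivity_scan()`.

Three exclusion rules are applied by `apply_exclusions()`, in this order:
unknown age or gender, Indeterminate gender, then drugs averaging fewer than
10 items per complete calendar year (2016–2023; the first and last data
years are partial and are never used for annual averages). The order matters
only for the rare-drug rule, whose averages are computed after the
demographic exclusions; since unknown-demographic records are about 3% of
items, the rule is insensitive to the ordering except for drugs sitting
almost exactly at the threshold.

Two band-edge conventions deserve a note because the published band scheme
does not align with round ages:

* "children only" in the imputation scopes means under-20s, i.e. bands
  `0–1` through `16–20` (the band containing age 19);
* the UCM child-substitute rule ("children up to 16") also runs through
  `16–20`, the band containing age 16. Both are arguments, not constants.

The label `105+` is read as *older than 105*: band `101–105` already
contains age 105, and the bands must partition the ages. Parsing accepts
hyphen, en-dash and whitespace variants of the labels; anything else is a
hard error, while malformed *rows* (bad period, zero or non-integer counts)
are quarantined into a rejects table with reasons rather than dropped —
FOI-style extracts should stay auditable.

## Rates

`compute_rates()` divides summed items by mid-year population, scaled per
100,000. The matching rule is by calendar year: every month of a year uses
that year's mid-year estimate. When a stratum collapses over years the
denominators add, so time-free strata are items per 100,000 person-years;
when a demographic dimension is collapsed, the *whole* population of the
spanned years and regions forms the denominator (a drug prescribed only to
the elderly still has a national rate). Zero-population cells yield `NA`
rates, never division errors.

The female:male contrast uses the natural log of the rate ratio. The base
affects display only; orderings and majority calls are base-free. Because
redaction makes true zeros and suppressed small counts distinguishable only
through the imputation policy, the degenerate cases are explicit: one-sided
zero rates give `±Inf` log ratios with the majority set by the nonzero side,
and both-zero rows carry a flag and are excluded from majority summaries.

## Seasonality rule

A drug is classed seasonal when at least `min_months = 2` calendar months
have mean items at least `threshold_factor = 1.2` times the overall mean,
computed on pre-COVID data (April 2015 – February 2020 by default; the COVID
window March 2020 – June 2022 never contributes). Decisions taken where the
rule is ambiguous:

* the overall mean is the mean of the 12 month-means, not of raw months, so
  incomplete years do not overweight the months they do cover (the
  alternative is available via the `overall` argument);
* the threshold is inclusive (a month at exactly 1.2× counts). The boundary
  is not academic: a two-peak drug with amplitude 0.25 sits *exactly* at
  1.2× its overall mean in expectation, and sampling noise then decides the
  verdict. The classifier is only sharp when the amplitude is comfortably
  away from 0.2, which is why the recovery tests use amplitude 0.5 vs 0;
* classification operates on national totals summed over ages and sexes; a
  profile needs all 12 calendar months observed or it is an error, not a
  guess.

The verdict is invariant under uniform scaling (counts vs rates give the
same answer), and raising the threshold can only remove peaks
(monotonicity); both are property-tested.

## UCM weights and regional ranking

The Updated Comparison Metric generalises STAR-PU weighting to the full
23-band resolution. Weights are per-capita prescribing rates relative to
females 66–70 (a subset of the classic STAR-PU 65–74 female baseline) in a
reference year (2023), computed on pooled national data and then applied to
regional populations — mirroring STAR-PU practice; a per-region weighting
mode is deliberately absent, since it would remove exactly the variation the
metric is meant to expose. Family-specific weights use one BNF family's
items. Numerical guards:

* weights are clamped to `[0.01, 100]`. The bounds are inert for any
  well-populated cell; they exist for sparse family weightings. Both overall
  and family weights are clamped — the bounds never bind on the overall
  weighting in practice, so this costs nothing and keeps one rule;
* child bands with zero items take the substitute 0.01 (in sparse families
  children are the only empty cells); a zero count in any other band is an
  error unless clamping is explicitly requested, because it almost always
  indicates a data problem rather than a true zero;
* a zero baseline cell is an error: the metric is undefined, and silently
  shifting baselines would make regions incomparable across runs.

Regions are ranked by items per weighted person, descending, with ties
broken by region code so output is deterministic. With 42 regions the
published grouping 1–10/11–20/21–30/31–42 applies; other counts use
proportional cuts at `ceiling(n·(10,20,30)/42)`.

## AWaRe targets

Drug names resolve to Access/Watch/Reserve by exact case- and
whitespace-insensitive match, then through a manual-match override table
(salt suffixes and spelling variants), else explicitly `Unclassified`.
Unclassified drugs stay in the denominator by default: the 60/70/80% targets
are fractions of *total* consumption, and dropping unmatched drugs would
inflate the Access share; the alternative is a switch. The packaged
reference map is a curated table covering the common English primary-care
antibiotics, shipped with an editable overrides file; users with the full
WHO reference table can point `read_aware_map()` at it directly.

## Influenza-season analysis

Respiratory-tract-infection prescribing is proxied by the penicillins and
cephalosporins/other β-lactams families, excluding amoxicillin (volume and
indication breadth would mask any vaccine effect). The season is 1 October –
30 March; at monthly resolution the whole of March is included, the 31 March
boundary being unobservable in monthly data. October–December belong to the
season starting that year, January–March to the previous one, April–
September to none. Analysis age groups are built from whole canonical bands
("5–10" maps to band `6–10`, "15–50" to `16–20`…`46–50`), so no age is
double-counted even though the quoted group edges overlap the band scheme.
Per-capita season rates use the population of the year containing October;
relative rates divide by the 15–50 group, whose own relative rate is exactly
1 by construction. The season-on-season proportional change is computed
within group against the *previous season* (not the previous calendar year),
and is undefined for a group's first season. Vaccination introductions are
annotations from a schedule table; the package deliberately fits no causal
model — the analysis is descriptive.

## Sensitivity scan

For each imputation value and scope the scan recomputes per-drug, per-band
female majorities (strict rate comparison) and reports the fraction of drugs
female-majority in at least 50/75/90% of their bands. Bands with zero items
in both sexes leave the denominator — counting undefined comparisons would
bias against female majority. The baseline (value 1, everyone) row is always
included, and the drug set is the post-exclusion set.

## The synthetic generator

`generate_prescriptions()` draws each cell count from a Poisson (optionally
negative-binomial, `dispersion`) distribution whose mean is a product of
configured factors: base monthly rate per 100,000 × age-profile multiplier ×
sex factor × seasonal multiplier × regional prescribing multiplier × COVID
dip × optional intervention multiplier × population/100,000. The female and
male factors are `2r/(1+r)` and `2/(1+r)` for configured female:male ratio
`r`, so they average to 1. The default panel is 20 drugs loosely modelled on
the most-prescribed English antibiotics: realistic relative volumes,
winter-seasonal β-lactams and macrolides (December/January peaks), strongly
female-skewed urinary-tract drugs, an acne tetracycline concentrated in
young adults, a small male-skewed tail, an Access-dominant (~84%) category
mix, a 0.7 COVID dip over March 2020 – June 2022, and suppression of counts
below 5. Population is an England-like pyramid, equal across sexes and
constant over years, so every female:male contrast in generated data comes
from the configured ratios and denominator drift cannot masquerade as a
prescribing effect.

What the generator does **not** emulate: correlation between months beyond
the seasonal mean structure (no epidemics, no amoxicillin-shortage spike),
comorbidity or deprivation structure, regional age-composition differences
(regions differ only in scale and a uniform prescribing multiplier),
reporting-completeness drift, or the real dataset's marginals. Passing
recovery tests therefore establishes that the pipeline's estimators are
consistent for the quantities the generator controls — not that any
particular real-world figure is correct.

Ground truth (per-cell expected counts plus the config) is retained and
queried with `truth_expected_totals()`; recovery tests compare pipeline
output against truth, never against themselves.

## Problem sizes and tolerances in the test suite

The suite and the acceptance script size their simulations for sharp
verdicts at desk scale: 100 drugs × 48 months nationally for the seasonality
error rates (≈11,000 mean monthly items per drug, where the amplitude-0.5
vs 0 contrast is decided at ≫10 standard errors); ≥10⁵ expected items per
age-sex cell for UCM weight recovery (observed error ≈0.5%, asserted <2%);
two half-size twin regions for the ranking property; the default 20-drug
panel for the Access-share and redaction-bracket properties. The injected
influenza drop (−10% in one group) is asserted to ±1 percentage point,
about three standard errors at the configured volumes. All randomness flows
from a single integer seed; a rerun under the same config is asserted to be
byte-identical.

## Known limitations

* The rare-drug exclusion counts redacted cells at the imputation value, so
  a drug consisting mostly of suppressed cells has an averaged count known
  only to within a factor of four; near-threshold drugs can enter or leave
  the set across sensitivity settings.
* `mean_annual` rounds half-to-even, matching how the published summary
  tables print these values; `"half_away"` is available where other
  conventions are needed.
* The UCM inherits STAR-PU's known blind spots: no comorbidity adjustment,
  and a single reference year. It answers "who prescribes more than their
  demography predicts", not "who prescribes inappropriately".
* AWaRe classification is name-based; route of administration is ignored
  (the oral-use 80% aspiration is evaluated against all items).
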