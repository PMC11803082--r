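# abxdemog

Age- and sex-disaggregated analysis of primary-care antibiotic prescribing.

## The problem

English primary-care prescription counts can be obtained from the NHS
Business Services Authority disaggregated by month, drug (with its BNF
section 5.1 family), 23 age bands ("0–1", "2–5", then 5-year bands to
"105+"), gender and region (the 42 Integrated Care Boards, ICBs). Working
with these extracts raises a set of recurring methodological problems that
this package solves as reusable, tested components:

- **Suppression.** Counts below 5 are redacted ("\*"); the true value is in
  1–4. Analyses must impute them (default 1) and show robustness across the
  1–4 envelope and across scopes (everyone / males only / under-20s only).
- **Exclusions.** Records with unknown age or gender, Indeterminate gender,
  and drugs averaging fewer than 10 items per year are removed, with an
  auditable report.
- **Rates.** Items per 100,000 against ONS-style mid-year denominators, at
  any stratification, with female:male log-ratio contrasts.
- **Seasonality.** A drug is seasonal when at least 2 calendar months sit at
  least 20% above its pre-COVID average monthly level (the COVID window,
  March 2020 – June 2022, is excluded).
- **Fair regional comparison.** The Updated Comparison Metric (UCM) is a
  STAR-PU-style weighting at full 23-band resolution: the weight of cell
  (age band *a*, sex *s*) in the reference year is

  w(a,s) = rate(a,s) / rate(66–70, Female),

  with rate = items per capita, weights clamped to [0.01, 100] and empty
  child cells set to 0.01. A region's metric is items per weighted person,
  Σ items / Σ w(a,s)·pop(a,s); regions are ranked descending (groups
  1–10 / 11–20 / 21–30 / 31–42 for the 42 ICBs). Family-specific weights
  ("UCM-family") use one BNF family's items only.
- **AWaRe targets.** Drug → Access/Watch/Reserve mapping with manual-match
  overrides, item-weighted category shares per stratum, and the 60/70/80%
  Access thresholds.
- **Influenza linkage.** Respiratory-tract-infection antibiotics
  (penicillins + cephalosporins/other β-lactams, amoxicillin excluded),
  assembled into October–March seasons, as rates relative to ages 15–50 and
  season-on-season proportional changes, annotated with vaccination
  introductions.

Because the source extracts come from Freedom of Information requests and
have no public accession, the package includes a synthetic-data generator
(`synthetic_config()`, `generate_population()`, `generate_prescriptions()`,
`apply_suppression()`) that reproduces the assumed statistical structure —
hockey-stick age profiles, female excess, winter seasonality, a COVID dip,
small-number suppression — with retained ground truth, so the whole pipeline
is testable end to end.

## Worked example

```r
library(abxdemog)

cfg <- synthetic_config(seed = 42)          # 20 drugs, England-like, 2015-2023
pop <- generate_population(cfg)
gen <- generate_prescriptions(cfg, pop)
raw <- apply_suppression(gen$records)       # counts < 5 redacted, as at source
rec <- impute_redacted(raw, value = 1)      # main-analysis imputation

sm <- summarize_drugs(rec, top_n = 5, population = pop)
sm[, 1:5]
#>                     drug total_items mean_annual pct_female top_month
#> 1:           Amoxicillin    63348994     7918624   58.33462        12
#> 2:        Nitrofurantoin    21991147     2748893   81.82439         8
#> 3: Flucloxacillin sodium    21142906     2642863   54.55154         8
#> 4:   Doxycycline hyclate    19718738     2464842   60.00712        12
#> 5:          Penicillin V    18657148     2332144   59.18439        12

classify_seasonal(monthly_profile(rec, "Amoxicillin"))
#> Amoxicillin -> seasonal (peaks: Jan, Dec)

summary(compute_ucm_weights(rec, pop, year = 2023))
#> UCM weight summary (overall)
#>   range: 0.176 to 2.19
#>   highest: Female 91–95 (2.19), Female 96–100 (2.13), Female 86–90 (2.11)
```

`total_items` sums the complete years 2016–2023, `mean_annual` is that total
over 8 years, `pct_female` the item share prescribed to females, `top_month`
the calendar month with most items (12 = December). The UCM summary reads:
the average woman aged 91–95 receives 2.19 times the antibiotics of the
baseline group (women 66–70).

A reference transcription of the published top-20 summary ships with the
package (`load_table1()`), and `headline_counts()` derives the whole-cohort
statements from it (drugs decreasing 2016→2023, female-majority counts,
top-month distribution).

There is also a config-driven runner,
`run_pipeline("simulate" | "ingest" | "rates" | "seasonality" | "ucm" |
"aware" | "flu" | "sensitivity" | "summary", config)`, with a shell wrapper
in `inst/cli/abxdemog.R`.

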