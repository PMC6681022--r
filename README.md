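# chipseek

Identifying microchip implantation events in the free-text examination
fields of veterinary electronic patient records (EPRs).

## The problem

Microchipping is compulsory for dogs and cats in most Australian
jurisdictions (before 3 months of age in most states, 6 in others), and
the chip number is the only permanent identifier that links one animal's
records across clinics. But the *date* an animal was chipped lives in
free-text consultation notes, not in structured fields. Epidemiologists
working with practice-management databases therefore need to

1. validate the structured microchip field (a valid Australian chip number
   is exactly 15 decimal digits),
2. search the examination text for chip-related terms — a case-insensitive
   substring search, so a stem like `microc` finds "microchip",
   "microchipped" and misspellings, but also "microcytic" and other
   confounders,
3. classify a random sample of hits by the reason the term appears (an
   actual implantation, a blank templated form, a pre-existing chip
   confirmed, a future plan, a stray scanned, ... — 17 categories), and
   estimate the search's **positive predictive value** (PPV),
4. compare cohorts (valid vs invalid chip fields) with Yates-corrected
   chi-squared tests, summarise **age at implantation** (median/IQR,
   log-scale *t*-test of dogs vs cats, compliance with the 12-week
   deadline), and
5. find chip numbers shared by several patient IDs and class each group's
   demographic concordance (same animal at multiple clinics vs data-entry
   error).

chipseek implements all five stages as a tested R pipeline, plus a seeded
synthetic EPR generator with ground-truth labels so the whole pipeline can
be validated end to end without access to clinical data.

Key statistical pieces, in the field's standard notation:

* PPV = TP / (TP + FP) over a reviewed random sample of search hits.
* 2×2 cohort tests: Pearson χ² with 1 df and the Yates correction,
  χ² = Σ (|O − E| − ½)² / E.
* Two-proportion sample size with the Fleiss continuity correction:
  n = (z₍α/2₎√(2p̄q̄) + z_β√(p₁q₁ + p₂q₂))² / (p₁ − p₂)²  +  2/|p₁ − p₂|.
* Age model for simulation: log-normal with meanlog = log(median) and
  sdlog = asinh(IQR / (2·median)) / z₀.₇₅.

## Worked example

```r
library(chipseek)

sim    <- generate_corpus(generator_config(n_patients = 10000, seed = 1))
report <- run_analysis(sim$corpus, sample_size = 1000, seed = 1)
report
#> Implantation-event analysis
#>   corpus: 30204 rows, 10068 patients (7695 dogs, 2373 cats), 7282 unique chips
#>   primary search term: 'microc' (7315 records in valid cohort)
#>   PPV: valid 0.243 (n=1000), invalid 0.155 (n=1000)
#>   PPV difference: X2 = 23.742, p = 1.1e-06 (Yates)
#>   dog age at implantation: median 79.0 d (IQR 108.00, n=257)
#>   cat age at implantation: median 128.5 d (IQR 142.50, n=80)
#>   dog vs cat log-age t-test: t = -3.816, p = 0.000191
#>   duplicated chips: 68 groups
```

Reading this: of 1000 randomly sampled `microc` hits in the valid-chip
cohort, 24.3% were actual implantation events performed that day (the
rest are blank forms, confirmations of existing chips, plans, strays, …);
the invalid-chip cohort's PPV of 15.5% is significantly lower. Individual
dogs are chipped around a median of 79 days — about half inside the
84-day statutory deadline (`report$compliance_dogs` is 0.52) — while cats
are chipped significantly later. The 68 duplicated chip numbers are
patient IDs sharing a chip, classed by whether species, breed and sex
agree across the records.

Term ranking and the broad-vs-narrow comparison:

```r
report$ranking
#>      term n_records n_patients n_patients_shared_with_reference
#> 1  microc      7315       7290                               NA
#> 2 implant       636        636                              576
#> 3   mchip        20         20                                0
#> ...

head(differential_words(split_cohorts(sim$corpus)$valid, "microc", "microch"), 3)
#> tokens found by 'microc' but not 'microch': misspellings ("microcip")
#> and clinical confounders ("microcardia", "microcytic", ...)
```

`export_tables(report, "results/")` writes one CSV per table plus a
self-auditing `report.json` carrying every statistic with its inputs,
seeds and convention flags. A thin command-line wrapper with `generate`,
`search` and `analyze` subcommands is installed at
`inst/cli/chipseek.R`.

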