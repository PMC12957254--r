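# faerscreen

Comparative pharmacovigilance screening for FAERS-style spontaneous-report
data, built around the two interleukin-23 inhibitors risankizumab and
guselkumab but configurable for any pair of target drugs.

## The problem

The FDA Adverse Event Reporting System (FAERS) publishes quarterly
"$"-delimited ASCII extracts of spontaneous safety reports: demographics
(DEMO), drugs with role codes (DRUG), MedDRA-coded reactions (REAC),
outcomes (OUTC), report sources (RPSR), therapy dates (THER), and
indications (INDI). Turning those extracts into defensible drug-event
signals requires a chain of decisions — cross-quarter case deduplication,
free-text drug-name standardization, a primary-suspect filter,
disproportionality statistics against a database background, and
time-to-onset modelling — each of which this package implements as a
tested, composable stage.

## The statistics

For a drug *D* and preferred term *P*, records (one row per deduplicated
report × drug × PT) are cross-classified into the 2×2 table
*a, b, c, d* (*a* = reports of *D* with *P*; background = all other
drugs). The package computes:

- **ROR** = *ad/bc* with Woolf 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`
- **PRR** = `[a/(a+b)] / [c/(c+d)]` with its analogous CI, and the
  uncorrected Pearson **χ²**
- **BCPNN IC** = `log2(aN / ((a+b)(a+c)))` with
  `IC025 = IC − 3.3a^(−1/2) − 2a^(−3/2)`

A pair is a signal when any rule fires (all configurable): ROR CI lower
bound > 1 with N ≥ 3; PRR ≥ 2 with χ² ≥ 4 and N ≥ 3; IC025 > 0.

Time-to-onset (event date minus earliest therapy start) is modelled with
an uncensored two-parameter Weibull MLE — shape β < 1 indicates an
early-failure hazard — plus Kaplan–Meier cumulative incidence, the
log-rank test, and a univariate Cox hazard ratio between the two drugs.
Age-stratified screens (<18, 18–65, ≥65) recompute all statistics within
each stratum with Benjamini–Hochberg-adjusted χ² p-values for volcano
plots.

A synthetic-data generator emits whole FAERS-dialect quarters with known
ground truth (injected relative risks, true Weibull onset parameters,
planted duplicate cases) so every stage is testable without database
access.

## Worked example

```r
library(faerscreen)

cfg <- synth_config(
  n_risankizumab = 2000L, n_guselkumab = 1000L, n_background = 10000L,
  injected_signals = data.table::data.table(
    drug = "risankizumab", pt = "pt_30", rr = 10),
  seed = 42L)

gen <- synth_generate(cfg)
ds  <- dedup_dataset(gen$dataset)        # latest report per caseid
rec <- build_records(ds)                 # (report, drug, PT) records, PS only

screen_all_pts(rec, "risankizumab", signals_only = TRUE)
#>       pt   n   ror ror_lo ror_hi   prr chisq    ic ic025
#> 1: pt_30 470 9.448  8.112     11 8.624  1197 1.929 1.777
```

The injected pair (true relative risk 10) is the only positive signal:
470 records, ROR 9.45 (95% CI 8.11–11.0), all three rules firing. The
onset stage recovers the generating Weibull parameters and the earlier
guselkumab onset:

```r
tto_r <- extract_tto(ds, "risankizumab")
tto_g <- extract_tto(ds, "guselkumab")
onset_summary_table(list(risankizumab = tto_r$tto_days,
                         guselkumab   = tto_g$tto_days))
#>            drug   n median alpha  beta beta_lo beta_hi       pattern
#> 1: risankizumab 501    172 280.2 0.737  0.6882  0.7891 early-failure
#> 2:   guselkumab 233     43 108.2 0.474  0.4305  0.5214 early-failure

cox_hazard_ratio(c(tto_r$tto_days, tto_g$tto_days),
                 rep(c("risankizumab", "guselkumab"),
                     c(nrow(tto_r), nrow(tto_g))))
#> Cox HR = 1.456 (95% CI 1.242-1.707); log-rank chisq = 21.51, p = 3.51e-06
```

HR > 1 (reference: risankizumab) means guselkumab events arrive earlier —
here by construction, since the arms were generated with shapes 0.69 vs
0.44. `run_pipeline(pipeline_config(...))` chains all stages and writes
CSV artifacts plus a run log; `exec/faerscreen` exposes `simulate` and
`run-all` subcommands.

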