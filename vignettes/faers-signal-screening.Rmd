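---
title: "Disproportionality screening and time-to-onset modelling for spontaneous-report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening and time-to-onset modelling for spontaneous-report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerscreen)
```

## Scope and model

`faerscreen` implements a comparative pharmacovigilance workflow for
FAERS-style quarterly extracts: ingestion of the seven "$"-delimited
tables, case-level cleaning, record-level disproportionality screening of
two target drugs (risankizumab and guselkumab by default) against the
full-database background, system-organ-class profiling, age-stratified
screening, and time-to-onset modelling. Spontaneous-report databases
contain no denominators, so all inference is *disproportionality*: a
drug–event pair is compared with the rest of the database via a 2×2
table, and "signal" means statistical over-reporting, never causation.

### Counting unit

The unit entering every 2×2 table is the drug–event **record**: one row
per (deduplicated report, drug, preferred term). A report listing three
PTs contributes three records to its drug's margin `a + b`. This makes
the per-drug AE-record totals — not report totals — the contingency
margins, which is the convention that published signal tables of this
kind imply (AE totals of order 2–3× report totals). Within a report a
duplicated PT counts once.

### Cleaning assumptions

* **Deduplication** keeps, for each `caseid`, the row with the largest
  `fda_dt`; ties keep the largest `primaryid` (the latest submission
  sequence). The choice of `fda_dt` as the "date" is ours; sources of
  this kind do not state which date field they used. Dedup is idempotent
  and order-independent.
* **Drug standardization** is case- and punctuation-insensitive substring
  matching of a synonym table (generic name, brand name, development
  code) against `drugname` and `prod_ai`. FAERS free text carries dose
  and formulation suffixes, so exact matching would under-capture; full
  NLP normalization (Medex-style) is out of scope.
* **Primary-suspect filter**: only role `PS` rows generate records — for
  the target drugs *and* for background drugs. The alternative (keeping
  concomitant background rows) contaminates the background event rates
  with target-arm reactions and biases RORs toward 1; the record
  invariant "role is PS for all records entering signal analysis" is
  enforced uniformly.
* **Ages** convert to years (decades ×10, months ÷12, weeks ÷52.14, days
  ÷365.25, hours ÷8766); converted values outside [0, 120] become
  missing rather than truncated, treating them as recording errors.
* **Partial dates** (`YYYYMM`, `YYYY`) are retained with a precision flag
  and never imputed; each downstream stage decides usability (the onset
  stage excludes them, descriptive stages ignore precision).
* **Serious outcome** means any of death, life-threatening,
  hospitalization, disability; "other serious" (OT) is tabulated but
  deliberately outside the severe flag.

### Disproportionality statistics

For cells *a, b, c, d* (N = total records):

* ROR = *ad/bc*, Woolf CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
* PRR = `[a/(a+b)]/[c/(c+d)]`, CI with
  `√(1/a − 1/(a+b) + 1/c − 1/(c+d))`;
* Pearson χ² **without** Yates continuity correction — the uncorrected
  form is what reproduces published χ² values in the acceptance
  reconstructions, and the PRR rule's χ² ≥ 4 uses the same statistic;
* IC = `log2(aN/((a+b)(a+c)))` with
  `IC025 = IC − 3.3·a^(−1/2) − 2·a^(−3/2)`.

The IC025 expression is the standard shrinkage-style approximation. It
is accurate for large *a* but known to overshoot downward at very small
counts (*a* ≈ 3); published small-count IC025 values are not exactly
reproducible by any common closed form, so the package documents the
formula it uses rather than claiming agreement there. Zero cells yield
flagged `NA` statistics, never infinities; an optional Haldane–Anscombe
0.5 correction is available but off by default. Default signal criteria
(all configurable): ROR CI lower bound > 1, N ≥ 3; PRR ≥ 2 ∧ χ² ≥ 4 ∧
N ≥ 3; IC025 > 0; combined with OR, with N ≥ 3 enforced globally.
Ranking is by ROR, ties broken by larger N then PT.

The comparator is the **full database background** (all other drugs'
records). Published analyses of this design rarely state the comparator
explicitly; the full-database convention is the one consistent with the
χ² magnitudes those tables print, which is how the acceptance
reconstruction cross-checks it (solving the background total from the
printed χ² yields a database of ~3×10⁷ records, the right order for
FAERS).

### Time-to-onset

Onset is `event_dt − earliest start_dt` of the target drug's therapy
rows. Exclusions (each counted in the extraction log): missing or
partial dates, negative onset, events post-dating the report's receipt
date. Same-day onsets are recoded to 0.5 days rather than excluded —
published IQR lower bounds of 1 day show near-zero onsets belong in the
data, and the Weibull likelihood needs *t* > 0.

The Weibull fit maximizes the uncensored two-parameter likelihood over
(log α, log β) with BFGS; CIs come from the observed information matrix
on the log scale. Failure patterns follow the shape CI against 1:
entirely below → early failure (decreasing hazard), containing →
random, above → wear-out. Kaplan–Meier cumulative incidence (equal to
the empirical CDF here, since every report is an event), the log-rank
test, and a univariate Cox model with Efron tie handling (onset days are
heavily tied) compare the two drugs; the Cox model is deliberately
unadjusted because the published comparison is univariate. HR is
reported with risankizumab as reference, so HR > 1 means earlier
guselkumab onset.

### Age-stratified screening

Strata are [0, 18), [18, 65), [65, ∞) on cleaned age; records with
missing age enter no stratum (they are tabulated separately in the
descriptive summary). All statistics are recomputed within the stratum
— the background is the other drugs *in the same stratum* — so
stratified RORs are internally valid; this is documented as our choice
because sources are typically silent on it. Raw p-values come from the
χ² statistic (1 df); adjustment is Benjamini–Hochberg within each
stratum × drug family (Bonferroni available) — published volcano plots
say only "adjusted p-value", and BH is the field standard for screening.
Volcano coordinates are `log2(ROR)` and `−log10(p_adj)`; a base-2 axis
is used throughout (one published figure axis reads "log_3", which we
treat as a typo for the base-2 used elsewhere).

## The synthetic-data generator

`synth_config()` states one desk-scale world; its defaults are not
tuning knobs:

* report counts 2,000 / 1,000 / 10,000 (risankizumab / guselkumab /
  background) keep the observed ~2:1 target ratio against a larger
  background while fitting in seconds;
* the PT vocabulary (60 terms) has long-tailed probabilities summing to
  2.1 expected PTs per report, matching published AE-per-report ratios
  (~2.3 and ~1.7);
* PT draws are independent Bernoulli per vocabulary term, with injected
  pairs' probabilities multiplied by the configured relative risk
  (capped at 1, error if the product exceeds 1); reports drawing zero
  PTs receive one weighted term, since FAERS reports must carry a
  reaction;
* onset times are Weibull with the published per-drug fits (scale
  241.61 / shape 0.69 and 109.71 / 0.44; background 180 / 0.8), and
  ~50% / 45% of start / event dates are missing plus 3% partial — per
  published onset-analysis attrition, only a quarter or so of reports
  have usable onset dates;
* 5% of caseids are re-reported with a later `fda_dt` and a fresh
  `primaryid`; deduplication must keep exactly the re-reports;
* demographic mixes (sex, reporter, country, outcomes, ~50% missing
  age) sit near published descriptive-table proportions.

What a green test establishes: the pipeline recovers *known generative
truth* — injected record-level RORs (whose closed form under the
generator, including the zero-draw top-up, is derived independently in
the test helpers), configured Weibull parameters, planted duplicates —
under FAERS's structural quirks. What it does not establish: behaviour
under reporting-bias dynamics (stimulated reporting, the Weber effect),
real MedDRA term correlations, or real-world name misspellings beyond
the synonym table's reach.

## Numerical choices

* Dates: 8-digit strings are parsed strictly (`%Y%m%d`, invalid
  calendar dates flagged); nothing is imputed.
* Weibull likelihood: optimizer excursions to non-finite regions return
  a large penalty rather than NaN; degenerate samples (identical times,
  n < 10) are errors, not estimates.
* The background-total solve in `reconstruct_contingency()` is a
  one-dimensional `uniroot` on the uncorrected χ², bracketed between
  the drug margin and 10¹².
* Missing fields are `NA` in memory and empty strings on disk, in both
  directions of I/O; round-trips are bit-exact for valid datasets.
* Ties: dedup (largest `primaryid`), ranking (larger N, then PT), Cox
  (Efron).

## Known limitations

* Disproportionality cannot separate true risk from reporting artefacts;
  the package reports statistics, not causal claims.
* The IC025 approximation is inaccurate at very small *a*; use the IC
  point estimate or the exact criteria flags there.
* Headline database-wide counts from any published analysis depend on
  the live FAERS snapshot and drug-name normalizer and are not
  reproducible from synthetic data; the acceptance suite therefore
  rests on internal-consistency reconstructions and stochastic
  parameter recovery instead.
* The XML FAERS dialect and network download are out of scope; only the
  "$"-delimited ASCII dialect is supported.
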