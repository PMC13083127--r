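# faersignal

Disproportionality signal detection and outcome modelling for
spontaneous adverse-event report databases in the FAERS quarterly ASCII
dialect.

Spontaneous-report databases have no exposure denominator, so drug-safety
screening asks a relative question: is a (drug, event) pair reported more
often than the independence expectation *within the database*? This
package implements that screening chain end to end for a target drug +
indication cohort (the motivating use case is PD-1 checkpoint-inhibitor
therapy in oesophageal cancer), for pharmacoepidemiologists and
drug-safety analysts who work with FAERS-style extractions:

* **Ingestion** of the seven `$`-delimited quarterly tables
  (DEMO/DRUG/REAC/OUTC/THER/INDI/RPSR), tolerant of dialect quirks,
  strict about accounting (malformed rows and orphan records are counted,
  never silently dropped).
* **Deduplication** by the FDA rule: per `caseid`, keep the report version
  with the highest `fda_dt`, ties broken by the largest `primaryid`.
* **Cohort assembly**: synonym-dictionary drug matching on
  `drugname`/`prod_ai`, primary-suspect role filter, drug-linked
  indication filter; everything else becomes the background comparator.
* **Three disproportionality algorithms** per preferred term (PT), on the
  2×2 table `a,b,c,d` of report counts:
  - reporting odds ratio `ROR = ad/bc`,
    CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; positive when `a ≥ 3`
    and the lower bound exceeds 1;
  - proportional reporting ratio `PRR = [a/(a+b)]/[c/(c+d)]` with Pearson
    `χ² = (ad−bc)²N/[(a+b)(a+c)(c+d)(b+d)]`; positive when `a ≥ 3`,
    `PRR ≥ 2`, `χ² ≥ 4`;
  - BCPNN information component `IC = log2[aN/((a+b)(a+c))]` with
    closed-form posterior moments under the standard priors
    (`αi=βj=1, α=β=2, γij=1`); positive when `a ≥ 3` and
    `IC025 = E(IC) − 2·SD > 0`.

  A headline "positive PT" passes all three. System-Organ-Class roll-ups
  (user-supplied PT→SOC map; MedDRA is licensed and not bundled) and
  sex/age/weight-stratified tables rerun the same machinery.
* **Time to onset**: whole days from earliest day-precision therapy start
  to first reported event; Kaplan–Meier median with Brookmeyer–Crowley
  log(−log) CI; log-rank subgroup comparisons.
* **Mortality**: five univariable logistic fits of the death outcome
  (`DE`) on age band, sex, weight band, distinct-PT count and
  time-to-first-event, with Wald CIs and separation flagging.
* **A synthetic FAERS generator** with planted, recoverable ground truth
  (exact expected ROR per planted pair, configurable onset distribution,
  logistic death model, duplicate report versions, field missingness) so
  the whole chain is testable offline, plus a pipeline driver that writes
  a deterministic delimited output bundle.

## Worked example

Everything below is runnable offline: we synthesize a quarter with five
planted signal pairs at ROR 5, write it in the FAERS dialect, and read it
back through the same path a real quarter would take.

```r
library(faersignal)
library(dplyr)

sim <- sim_faers(sim_config(seed = 42, n_cases = 5000))
quarter <- tempfile("quarter-")
write_faers_quarter(sim$tables, quarter)

tables <- dedup_tables(read_faers_quarter(quarter))
spec <- cohort_spec(
  drug_synonym_map("pembrolizumab", c("pembrolizumab", "keytruda", "mk-3475")),
  indication_terms = "Oesophageal cancer")
cohort <- build_cohort(tables, spec)
cohort
#> <faers_cohort> target: pembrolizumab
#>   cohort reports: 493  (distinct PTs: 204)
#>   background reports: 4507

signals <- detect_signals(cohort)
signals %>%
  filter(all_three) %>%
  arrange(desc(ror_low)) %>%
  select(pt, a, ror, ror_low, ror_high, prr, chi2, ic025)
#> # A tibble: 5 × 8
#>   pt                                a   ror ror_low ror_high   prr  chi2 ic025
#>   <chr>                         <dbl> <dbl>   <dbl>    <dbl> <dbl> <dbl> <dbl>
#> 1 Hypothyroidism                   27  7.20    4.33    12.0   6.86  78.2 1.27
#> 2 Immune-mediated myocarditis      26  5.78    3.52     9.49  5.53  60.9 1.11
#> 3 Renal impairment                 23  4.36    2.64     7.21  4.21  39.1 0.844
#> 4 Immune-mediated enterocolitis    14  3.18    1.72     5.88  3.12  15.2 0.354
#> 5 Synthetic PT 113                 11  3.09    1.55     6.16  3.05  11.4 0.197
```

Five PTs pass all three positivity criteria. Reading the first row:
`a = 27` cohort reports list hypothyroidism, 7.2 times the reporting odds
of the background (95% CI 4.3–12.0), PRR 6.9 with χ² 78, and the
shrunk Bayesian lower bound IC025 = 1.27 > 0. At this modest sample four
of the five planted pairs are recovered (the fifth sits just under the
CI threshold) and one of the 200 null terms sneaks in by chance —
exactly the behaviour the large-sample validation suite quantifies.

```r
onset <- compute_tto(cohort)
km_median(onset$tto_days)
#> # A tibble: 1 × 4
#>       n median_days ci_low ci_high
#>   <int>       <dbl>  <dbl>   <dbl>
#> 1   411          31     27      37
```

411 cohort reports have day-precision start and event dates; their median
onset is 31 days (95% CI 27–37), consistent with the generator's
configured exponential median of 35 days.

```r
mortality_report(build_mortality_table(cohort, onset)) %>%
  filter(covariate == "tto_first_days")
#> # A tibble: 1 × 10
#>   covariate  level     n n_deaths    or ci_low ci_high p_value significant note
#>   <chr>      <chr> <int>    <int> <dbl>  <dbl>   <dbl>   <dbl> <lgl>       <chr>
#> 1 tto_first… per …   411       52 0.993  0.986    1.00  0.0662 FALSE       ""
```

Each additional day of onset delay multiplies the odds of a fatal outcome
by 0.993 (i.e. earlier-onset events carry higher mortality odds), not
significant at this sample size.

`run_pipeline(pipeline_config(...))` chains all of the above —
descriptives, PT/SOC/stratified signal tables, onset summaries, mortality
table, optional two-drug ROR comparison — into a deterministic TSV bundle
with a stage log; `inst/scripts/faers-pipeline.R` wraps it for shell use.

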