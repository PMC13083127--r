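---
title: "Signal detection for spontaneous adverse-event reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection for spontaneous adverse-event reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The problem

Spontaneous-report databases such as FAERS collect adverse-event (AE)
reports for marketed drugs: each case carries demographics, the suspect and
concomitant drugs with their roles and indications, the coded event terms
(MedDRA preferred terms, PTs), therapy dates and outcomes. Because there is
no exposure denominator, safety screening works by *disproportionality*:
a (drug, event) pair is a signal when it is reported more often than the
independence expectation within the database itself. `faersignal`
implements this screening chain for a target drug + indication cohort —
for instance a PD-1 checkpoint inhibitor (pembrolizumab or nivolumab) used
in oesophageal-cancer immunotherapy, the setting whose reported conditions
the synthetic generator's defaults emulate — together with the two
standard follow-on analyses: time-to-onset survival summaries and
univariable logistic models of fatal outcome.

## Data preparation

**Parsing.** FAERS quarters are seven `$`-delimited ASCII tables (DEMO,
DRUG, REAC, OUTC, THER, INDI, RPSR). The reader is deliberately strict
about accounting and liberal about dialect: stray leading/trailing
delimiters are tolerated, column names are case-folded, rows with more
fields than the header are counted as malformed (never guessed at), and
non-DEMO rows whose `primaryid` is unknown to DEMO are counted as orphans.
Dates are kept verbatim with a precision flag (`day`, `month`, `year`,
`missing`); partial dates survive for descriptive counts but are barred
from any day-resolution arithmetic.

**Deduplication.** One case (`caseid`) may be represented by several report
versions (`primaryid`). Following the FDA-recommended rule, the version
with the highest `fda_dt` is kept, ties broken by the largest `primaryid`.
The operation is order-independent and idempotent, and the removal ledger
is part of the output so that reports in = kept + removed + quarantined is
checkable.

**Cohort.** A report enters the cohort when some drug entry matches the
target synonym set (lower-cased, trimmed, punctuation-stripped; exact match
by default, substring matching behind a flag for combination-product
strings), carries the required role code (`PS` by default), and — under the
default drug-level indication scope — is linked through
`indi_drug_seq = drug_seq` to one of the indication PTs. Case-level
indication scope is available because source databases are not always
consistent about the linkage. Reports with missing age, sex or weight are
retained here; each downstream analysis deletes per-variable only what it
cannot use. The comparator ("background") for all 2×2 tables is every
deduplicated report outside the cohort — the conventional full-database
comparator.

## Disproportionality statistics

All three algorithms consume the same 2×2 table per PT, counted in units
of unique deduplicated reports (a PT counts once per report):

|              | target PT | other PTs |
|--------------|-----------|-----------|
| cohort       | a         | b         |
| background   | c         | d         |

with $N = a+b+c+d$.

**Reporting odds ratio.** $ROR = ad/bc$, with
$95\%\,CI = \exp(\ln ROR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.
Positive when $a \ge 3$ and the lower bound exceeds 1.

**Proportional reporting ratio.** $PRR = \frac{a/(a+b)}{c/(c+d)}$ with the
Pearson chi-square
$\chi^2 = \frac{(ad-bc)^2 N}{(a+b)(a+c)(c+d)(b+d)}$ — no continuity
correction, matching the plain formula. Positive when $a \ge 3$,
$PRR \ge 2$ and $\chi^2 \ge 4$.

**BCPNN information component.** The point IC is
$\log_2 \frac{aN}{(a+b)(a+c)}$. The Bayesian estimate uses the closed-form
posterior moments of the information component under the standard priors
$\alpha_i=\beta_j=1$, $\alpha=\beta=2$, $\gamma_{ij}=1$, with the joint
prior weight rescaled per table,
$\gamma = \gamma_{ij}(N+\alpha)(N+\beta)/\big((a+b+\alpha_i)(a+c+\beta_j)\big)$,
so the prior is centred on independence. $IC_{025} = E(IC) - 2\sqrt{V(IC)}$,
and the rule is positive when $a \ge 3$ and $IC_{025} > 0$. We use the
closed-form approximation, not Monte-Carlo posterior sampling: at the
table sizes where the $a \ge 3$ gate admits a signal the two agree to far
below decision relevance, and the closed form is deterministic.

**Zero cells.** By default any statistic whose formula divides by (or logs)
zero is returned `NA` with a definedness flag, rather than silently
smoothed — the positivity criteria's $a \ge 3$ gate makes this irrelevant
for declared signals, and transparency wins for the rest. A
Haldane–Anscombe +0.5 option exists for the frequentist statistics; the
Bayesian moments never need it.

**Consensus and ranking.** A "positive PT" requires all three rules
simultaneously by default (an `any` mode is available). Tables are ordered
by frequency ($a$) and, as the strength key, by the ROR lower confidence
bound — a ranking that penalizes small noisy counts. No multiplicity
adjustment is applied, matching standard practice in hypothesis-generating
pharmacovigilance screens; the number of PTs tested is attached so users
can adjust post hoc.

**SOC roll-up and strata.** System Organ Class tables pool member PTs with
report-level counting (a report with two PTs of one SOC counts once) and
recompute all three statistics; the PT→SOC map is user-supplied because
MedDRA is licensed and cannot ship with the package. Stratified screening
(sex, the ≥65/<65 age split, weight bands) restratifies the background to
the same stratum level by default, so a stratum's comparator is not
confounded by the stratifying variable itself; a global-background mode is
available for sensitivity analysis.

## Time to onset

TTO is the whole-day difference between the earliest day-precision therapy
start of the target drug and the report's event date (the first reported
AE). Records missing either date, at partial precision, or with a negative
difference are excluded with counted reasons. Spontaneous reports are
events by construction, so no censoring mechanism exists: every record
enters as an event, the product-limit estimate coincides with the
empirical survivor function, and the KM median is the smallest time with
$S(t) \le 0.5$. Its 95% CI is the Brookmeyer–Crowley inversion with
Greenwood variance on the log(−log) scale — the dominant convention.
Subgroups (age band, sex, weight band, optionally SOC) are compared with
the standard log-rank test, aggregated counts at tied event times,
chi-square reference with (levels − 1) degrees of freedom. Medians are
reported and labelled as medians.

## Mortality model

Death is outcome code `DE` on the deduplicated report. Five univariable
logistic fits — never a multivariable model, which spontaneous-report data
cannot support — relate death to: age band (18–44 reference, 44–64, ≥65;
age 44 is assigned to "18–44" to resolve the overlapping band boundary
deterministically), sex (male reference), weight band (50–100 kg
reference, <50, >100), the distinct-PT count per report, and the
time-to-first-AE in days (both continuous covariates per unit,
untransformed). Each fit deletes only records missing its own covariate.
Estimates carry Wald 95% CIs ($e^{\beta \pm 1.96\,se}$) and Wald p-values,
matching the symmetric intervals conventionally printed; complete
separation is detected and flagged rather than raised, and reference rows
are emitted with OR = 1 and no interval.

## The synthetic generator

The generator exists so the whole chain can be validated offline against
known truth; it is first-class, tested code. Its defaults are the reported
real-world conditions of the emulated setting: ~85% male among known sex
(~80% of all reports after 5.5% sex missingness), an elderly age mixture
(~70% of known ages ≥65, under 2% aged 18–44), country and reporter
marginals dominated by Japan/US and physicians, exponential first-AE onset
with median 35 days, ~14% fatal and ~22% hospitalized outcomes, heavy
weight missingness (~80%, as in real spontaneous reports where weight is
rarely captured), a 10% duplicate-version rate, and five planted signal
pairs at ROR 5 among a ~200-term vocabulary.

Mechanics worth knowing:

* **Planted disproportionality** is exact in expectation: the exposed-arm
  event probability solves the odds identity
  $p_1 = r\,p_0 / (1 - p_0 + r\,p_0)$, so the report-level odds ratio
  against the background equals the target $r$; infeasible targets are a
  hard error. The realized $a/b/c/d$ and ROR per pair are recorded in a
  truth ledger that tests recount exhaustively from the emitted tables.
* **Onset** is drawn once per case as the first-AE time (exponential,
  Weibull or log-normal), so the configured median *is* the median of the
  realized TTO distribution — the property the recovery tests consume.
  `event_dt = start_dt + onset`, and `start ≤ event ≤ fda` holds before
  missingness.
* **Duplicates** share `caseid` with strictly increasing `fda_dt` and
  `primaryid`; earlier versions duplicate the case's child-table rows, so
  deduplication is exercised realistically.
* **Death** is Bernoulli under a logistic model on age ≥65, female sex,
  weight bands, the distinct-PT count and the onset day — the same
  covariates the mortality module fits, making coefficient recovery a
  closed loop.
* Everything is deterministic given the seed, to the byte, including the
  written quarter.

What the generator does *not* emulate: free-text drug-name noise beyond
case/whitespace perturbation, realistic country/occupation joint
structure, PT co-occurrence correlation within organ systems, secular
reporting trends, or indication miscoding. Passing recovery tests
therefore demonstrate that the estimators and plumbing are correct under
the stated sampling model — not that real FAERS extractions are free of
confounding, stimulated reporting, or coding drift.

## Numerical and design choices

* Problem sizes in the validation suite were chosen to put Monte-Carlo
  error well inside the asserted bands: 20,000-report quarters with 100
  replicates for planted-ROR recovery (cohort ≈ 2,000, planted $a$ ≈ 90);
  2,000 onset records × 100 replicates for median-CI coverage; 1,000 null
  replicates at 200/arm for log-rank size; 200 replicates at n = 5,000 for
  Wald-CI coverage of a planted OR 3.
* Logistic fits tighten the IRLS convergence tolerance to $10^{-12}$ so
  the binary-covariate fit reproduces the closed-form cross-product OR to
  $10^{-8}$.
* The IC-monotonicity property (IC increasing in $a$ at fixed $b,c,d$)
  holds only while $a$ is small against the comparator margins; it is
  asserted in that regime, which is the regime where disproportionality
  screening operates.
* Degenerate inputs have defined behaviour throughout: absent PTs give
  zero tables (not errors), empty cohorts warn and continue for
  descriptive output, point-mass onset distributions give a degenerate
  median interval, single-level subgroup variables emit rows with the
  p-value marked not applicable, and all exclusions are ledgered with
  reasons.

## Limitations

Disproportionality measures reporting association, not incidence or
causation; there is no exposure denominator. The three algorithms share
one contingency table, so their consensus is robustness against threshold
artefacts, not independent replication. The onset analysis treats every
report as an event because spontaneous data offer no censoring
information, which overstates certainty in the right tail when reporting
is delayed. The mortality model is univariable by design and inherits all
reporting biases of the source data.
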