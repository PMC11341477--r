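---
title: "Disproportionality signal mining on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersmine)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect unsolicited reports of suspected drug
reactions. Because there is no denominator of exposed patients, safety
signals are sought by *disproportionality analysis*: for a drug of
interest and each adverse-event term, the reporting frequency of the
drug–event combination is compared with the background frequency of the
event across all other drugs in the database. `faersmine` implements the
full path from raw FAERS quarterly ASCII files to per-term signal tables
for one target drug (the packaged defaults identify teprotumumab, an
IGF-1R monoclonal antibody used in thyroid eye disease, but every piece
is configurable).

The pipeline stages are fixed:

1. **Parse** the `$`-delimited DEMO/DRUG/REAC/THER tables
   (`read_faers_table()`, `read_faers_quarter()`), resolving columns by
   header name because FAERS layouts changed across years.
2. **Join** child rows to their report by `PRIMARYID`
   (`join_cases()`); orphan rows are counted, never attached.
3. **Deduplicate** report versions (`deduplicate()`): FAERS re-publishes
   a case whenever its report is amended, so per `CASEID` only the
   version with the largest `FDA_DT` survives, ties broken by the
   largest `PRIMARYID`. An absent `FDA_DT` loses to any present one.
4. **Build the cohort** (`is_target_report()`, `expand_pairs()`): a
   report belongs to the cohort when one of its drug rows matches a
   synonym exactly on the normalized `DRUGNAME` or `PROD_AI` *and* that
   row carries the primary-suspect (PS) role code. Matching is exact,
   never substring: the synonym list enumerates name variants, and
   substring matching would capture unrelated products.
5. **Analyse**: demographics (`demographics()`), annual report counts
   (`annual_counts()`), disproportionality at PT and SOC level
   (`disproportionality()`), and time-to-onset (`compute_tto()`,
   `summarize_tto()`).

`run_faers_pipeline()` executes all stages in order and writes a CSV/JSON
bundle; it also logs the case counts at every stage (raw versions,
unique cases, target cases, pairs) so real-data runs are auditable.

## The counting model

The unit of analysis is the **drug–event pair**: one record per kept
report × distinct preferred term (PT). Duplicate mentions of a PT within
one report collapse to a single pair, so a report contributes at most 1
to any term's count, which is what published 2×2 tables mean by "number
of reports". A report's pairs all inherit the report-level target flag.
At system-organ-class (SOC) level a report again contributes at most one
pair per SOC by default (`soc_counting = "report"`); summing PT pairs
within the SOC is available as an option because published tables do not
always state which convention they use.

For each term $t$ the 2×2 table is

|            | term $t$ | other terms |
|------------|---------:|------------:|
| target     | $a$      | $b$         |
| background | $c$      | $d$         |

with $N = a+b+c+d$ the total pair count of the deduplicated database.

## The four statistics

With $\mathrm{se} = \sqrt{1/a + 1/b + 1/c + 1/d}$:

* **ROR** $= ad/(bc)$, with the two-sided Wald interval
  $\exp(\ln \mathrm{ROR} \pm 1.96\,\mathrm{se})$.
* **PRR** $= a(c+d)/(c(a+b))$, paired with the Pearson $\chi^2$ of the
  table, $\chi^2 = (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d))$, without
  continuity correction.
* **IC** $= \log_2\!\big(aN/((a+c)(a+b))\big)$, the information
  component of the BCPNN: the log2 ratio of the observed to the expected
  pair count under independence. The lower credibility bound is
  $\mathrm{IC}_{025} = \mathrm{IC} - 2\sqrt{V(\mathrm{IC})}$ with the
  standard closed-form posterior variance under symmetric unit Dirichlet
  priors.
* **EBGM** $= aN/((a+c)(a+b))$, the observed/expected reporting ratio,
  with $\mathrm{EBGM}_{05} = \exp(\ln \mathrm{EBGM} - z\,\mathrm{se})$
  and $z = 1.645$ (a one-sided 5th percentile) by default.

Two deliberate design choices deserve emphasis.

**EBGM is unshrunk.** The full MGPS methodology shrinks observed/expected
ratios through an empirical-Bayes gamma-mixture prior. This package
implements the plain observed/expected ratio — which is what many
published FAERS analyses actually tabulate under the EBGM heading — and
consequently $\mathrm{IC} = \log_2(\mathrm{EBGM})$ holds as an exact
algebraic identity (it is asserted in the test suite on random tables).
If true DuMouchel shrinkage is needed, this is not the tool.

**EBGM05 uses z = 1.645.** Recomputing published signal tables from
their printed aggregates reproduces the printed EBGM05 column with
1.645 and contradicts 1.96, even where the accompanying formula sheet
prints 1.96; the lower bound of a one-sided 95% criterion is also the
field's convention. The quantile is exposed as `ebgm_z` for users who
want the two-sided variant.

**IC025 is our own.** Published IC025 columns in this literature are
frequently inconsistent with any count-dependent variance formula (a
near-constant offset of about 1.67 bits across very different counts).
The package computes the documented closed-form Bayesian bound and makes
no attempt to mimic such columns; IC025 is therefore not a
reproduction surface, while the IC point estimate is.

**Zero cells.** All four estimates are left undefined (`NA`) when a
required cell is zero; flags on undefined estimates are `FALSE`. The
Haldane +0.5 correction is available behind `continuity = TRUE` but is
off by default, matching standard practice of simply not reporting
zero-cell terms.

**Rounding.** Report output rounds half-up to 2 decimals
(`round_half_up()`), the convention of published tables; `round()`'s
half-to-even rule would disagree on exact halves.

## Signal criteria

`signal_criteria()` encodes the field-standard thresholds, each rule
individually switchable: at least `min_a = 3` reports; ROR 95% CI lower
bound > 1; PRR ≥ 2 with χ² ≥ 4; IC025 > 0; EBGM05 > 2. These are
screening thresholds, not proof of causation: a flagged term is a
candidate for clinical review.

## Reconstructing published rows

`reconstruct_cells()` inverts a printed signal-table row: given a term's
$a$ cell, the target pair total and the database grand total, it solves
$c$ from a printed PRR (or EBGM) value and returns the full table. This
is how the package validates itself against published aggregates without
redistributing FAERS: recomputing the ROR on the reconstructed
muscle-spasms table of the motivating teprotumumab analysis ($a = 44$,
687 target pairs, 6,703,410 total pairs, PRR anchor 20.42) returns
21.75 with CI (16.02–29.53), matching the printed row to the printed
precision. `scripts/acceptance.R` performs exactly this computation.

## Time to onset

TTO is the day difference between the event onset date (`EVENT_DT`,
DEMO) and the earliest therapy start date (`START_DT`, THER) among rows
linked to a matching target drug record. Both dates must have full day
precision; month- or year-truncated dates exclude the report with reason
`missing_date`, a negative difference with `event_before_start`.
Same-day onset (0 days) is included — an interval does not exclude zero.
One TTO per report is computed (the earliest qualifying start), since
published onset summaries are report-level. Quartiles use linear
interpolation between order statistics (the `quantile()` type-7
default); the convention is stated because published tables rarely state
theirs.

## The synthetic generator

Real FAERS quarters cannot ship with a package, so `generate_faers()`
draws them: DEMO/DRUG/REAC/THER tables in the exact ASCII dialect the
parser reads, plus a ground-truth ledger (unique-case count, per-PT 2×2
cells, true onset delays). The integration contract is
`parse(generate(x))`, and the per-PT cells counted by the pipeline must
equal the ledger *exactly* — any discrepancy is a bug, and the test
suite asserts it.

The reaction model includes each background PT independently per case
with its base probability; for target cases the probabilities of
injected PTs are multiplied by a configured factor (capped at 0.95).
This Bernoulli-per-PT design was chosen over a renormalized categorical
draw because it makes injected signals interpretable: with a single
injected PT, the theoretical pair-level reporting odds ratio equals the
configured multiplier exactly (`theoretical_ror()`), which turns CI
coverage into a well-posed property — the suite checks that the Wald 95%
interval covers the injected ROR in at least 90% of replicates at
injected strengths 2, 5 and 20 (200 replicates of 50,000-case quarters
each, a size chosen to give stable per-term counts while keeping the
whole study inside a coffee break). A side effect of independence is
that a case can draw zero reactions (~5% at the default spectrum);
such cases simply contribute no pairs.

Duplication emits a fraction of cases as an additional earlier version
(same `CASEID`, smaller `PRIMARYID`, earlier or tied `FDA_DT`, a subset
of the reactions), exercising the dedup rule including its tie-break.
Missing-date perturbation blanks or month-truncates therapy and event
dates, exercising the TTO exclusion reasons.

Defaults mirror the motivating cohort: 78% female, weight mass in the
50–100 kg bin, ages concentrated in 18–64.9, 98.5% US reporters,
reports spread over 2020–2023 with a declining trend, and log-normal
onset delays with median 48 days and log-sd 1.17 (chosen so the
quartile ratio matches the published IQR 19–92; a log-normal cannot
also match that IQR's asymmetry around the median, and its tail beyond
180 days is heavier than the published 3.39% — the generator emulates
the central distribution, not the tail). `paper_scale_config()` fixes
200 target cases among 10,000 and rescales the background spectrum so
the *expected* target pair count is 687 (~3.4 distinct reactions per
target case); the realized count varies binomially around it. What
passing tests on these data show is that the pipeline counts, dedups,
joins and estimates correctly — not that real FAERS data are this
clean: real quarters have free-text drug-name noise far beyond the
generator's case/punctuation perturbations, non-random missingness, and
duplicate cases that share no `CASEID`.

## Numerical and degenerate-input choices

* Dates: 8/6/4-digit strings parse to day/month/year precision;
  calendar-invalid values (e.g. day 30 in February) become absent, never
  errors. Downstream operations declare the precision they need.
* `PRIMARYID` is compared numerically when all-digits (FAERS ids are
  numeric), lexicographically otherwise, so dirty data degrade rather
  than crash the dedup rule.
* Empty string, `"NULL"` and whitespace-only fields all read as absent.
* Two report versions with identical `CASEID`, `FDA_DT` *and*
  `PRIMARYID` raise an integrity error rather than picking arbitrarily.
* An empty pair list is an error in `build_tables()`; a requested term
  absent from the data yields an $a = c = 0$ row with undefined
  estimates and `FALSE` flags.
* 50 kg / 100 kg and 65 y / 85 y fall in the inner bins ("50–100",
  "65–85"), reproducing the mutually exclusive labels of published
  demographic tables; ages convert through `AGE_COD` (DEC×10, MON÷12,
  WK÷52.143, DY÷365.25) and weights through `WT_COD`
  (LBS×0.45359237).

## Known limitations

* No probabilistic duplicate detection across distinct `CASEID`s, and
  cross-quarter deleted-case lists are not applied.
* PT→SOC mapping is a user-supplied two-column file forcing one SOC per
  PT; the licensed MedDRA hierarchy (LLT/HLT/HLGT, primary vs secondary
  SOC) is out of scope.
* No multiple-testing adjustment is applied to the signal flags.
* The XML/E2B FAERS dialect is not parsed; ASCII only.

## A worked example

```{r example, eval = FALSE}
cfg <- paper_scale_config(seed = 1)
dir <- tempfile()
generate_faers(cfg, dir = dir)
map <- file.path(dir, "ptsoc.csv")
write_pt_soc_map(cfg, map)
run <- run_faers_pipeline(dir, pt_soc_map = map)
print(run)
head(as.data.frame(run$signals_pt))
```

The printed run log shows the flowchart counts (12,000 raw versions →
10,000 unique cases → 200 target cases → pairs), and the signal table
ranks the injected ear/hearing and muscle associations at the top with
all four flags set.
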