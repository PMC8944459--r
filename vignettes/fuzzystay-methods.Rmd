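---
title: "Fuzzy discretization and k-modes profiling of ICU stays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy discretization and k-modes profiling of ICU stays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzystay)
```

## The problem

Intensive-care patients generate two streams of structured data that
clinicians summarise qualitatively at every hand-over: which antimicrobials
the patient is receiving and for how many consecutive days, and the hourly
bedside monitoring picture (vitals, blood gases, fluid balance). fuzzystay
turns both streams into small categorical vocabularies — "ultra-short" to
"ultra-long" for therapy durations, "very low" to "very high" for
monitoring parameters — and then groups whole patient-days and
patient-hours by k-modes clustering, so that a stay can be read as a
trajectory through a handful of named profiles rather than as thousands of
raw numbers.

The package implements the full chain: automatic construction of a fuzzy
domain per parameter from population statistics, fuzzification of records
into category patterns, deduplication, k-modes clustering with elbow-based
model selection, and per-stay synoptic tables and charts. A seeded
synthetic-cohort generator stands in for hospital data, which are never
distributed with analyses of this kind.

## Fuzzy domains

Each parameter's range is partitioned into five linguistic subsets F1..F5:
trapezoidal shoulders at the extremes (F1, F5) and three triangles in
between (F2, F3, F4), each adjacent pair overlapping in a band of width
`h`. A value's membership degree in a subset is piecewise linear in
`[0, 1]`; because subsets overlap only pairwise, at most two degrees are
positive at any value.

### The 95% table

Domains are anchored on the central mass of the population distribution,
not its extremes. `trim_values()` builds the "95% table": the smallest set
of observed values whose cumulative frequencies reach the coverage target
(default 0.95). Cutoffs are always observed values, never interpolated:
the trimmed bound is the smallest value at which the running cumulative
frequency reaches the tail threshold. Two sidedness modes exist because
duration-like variables and vitals differ structurally:

* `upper` — only the long upper tail is trimmed; the minimum is meaningful
  (a course of 0–1 days) and is kept. Used for therapy durations.
* `central` — 2.5% is trimmed from each tail. Used for monitoring vitals.

Observations outside the trimmed range are not discarded downstream: they
clamp to the extreme subsets ("very low"/"very high") at fuzzification
time, which is exactly the role of the shoulder trapezoids.

### Geometry

With trimmed minimum `m`, maximum `M`, trimmed median `med` and overlap
width `h`, `fuzzy_domain()` places the ten limits as

```
VLL = m - h        LL = m + h        VLH = m + 2h
NL  = med - (M-m)/6                  NH  = med + (M-m)/6
LH  = NL + h                         HL  = NH - h
VHL = M - 2h       HH = M - h        VHH = M + h
```

The medium triangle is centred on the trimmed median — the construction is
deliberately median-anchored so that the "medium" category tracks the
population's central value rather than the midpoint of the range — and all
four overlap bands have the same width `h`. The default overlap is half
the standard deviation of the trimmed sample (`h = sd_t / 2`), overridable
per parameter with a fixed width. `h` must stay below `(M - m) / 6`, or
the triangles would invert; the constructor rejects such requests.

For a markedly skewed distribution the median can sit so close to a range
edge that the medium triangle would collide with a shoulder. The strict
constructor rejects that geometry. The pipeline's safeguarded builder
instead clamps the triangle's anchor into the feasible band
`(m + (M-m)/6 + 2h, M - (M-m)/6 - 2h)` (with a 0.1% margin), shrinks an
overlap that violates the `h` bound to half its admissible maximum, and
widens a constant column's range by ±0.5 unit before construction. These
safeguards only matter for short-range per-drug duration columns; for
vitals with realistic spreads the raw statistics are always feasible.

```{r}
domain <- fuzzy_domain(0, 22, 11, 1.8, labels = therapy_labels())
round(domain$limits, 2)
```

### Fuzzification

`membership()` returns the five degrees; `fuzzify()` assigns the single
category with the highest degree. Ties — which occur only at exact
crossing points of two membership lines — go to the lower category, making
the assignment deterministic and total on the reals. Wherever some degree
exceeds 0.5 (everywhere except the measure-zero crossing points), this
argmax rule coincides with the rule "assign the subset whose membership
exceeds one half". Missing data map to code 0 ("none"); no numeric value
ever produces 0. Values at or below `VLL` are category 1, at or above
`VHH` category 5.

Internal arithmetic is kept at full precision; only reports round, to one
decimal, half away from zero.

## From raw tables to patterns

`build_therapy_records()` turns a long administrations table (patient,
drug, calendar day) into one record per treated patient-day: the overall
consecutive days of any antimicrobial therapy plus one consecutive-day
counter per vocabulary drug (0 = not given). The overall counter runs on
the union of the patient's drug days, so two overlapping courses of
different drugs accumulate a single uninterrupted overall course. A
missing calendar day resets a counter; a configurable grace of `g` days
off (default 0) can bridge charting gaps. With the default 90-drug
vocabulary each record has 91 numeric columns.

`build_monitoring_records()` buckets readings by patient, day and clock
hour (0–23). Multiple validated readings of one parameter within an hour
reduce to their median by default (`last` is available); hours with no
readings at all emit no record, because a record of pure absence carries
no information. With the default 46-parameter schema each record has 46
columns, missing values allowed.

`normalize_records()` fuzzifies every value column with its parameter's
domain. For therapy columns zeros mean "drug not given" and map to code 0;
for monitoring columns only `NA` is absent (a measured 0 — a fluid
balance, a base excess — is a value). A column with no observable value at
all (a drug never prescribed in the dataset) codes to 0 without needing a
domain; any other column without a domain is an error.

`dedup_patterns()` collapses identical category vectors. Two patterns are
identical exactly when their Euclidean distance is zero, so exact row
equality implements the zero-distance criterion provably. Unique patterns
are numbered in lexicographic code order — a deterministic labelling that
makes reruns and diffs stable — and a back-map ties every source record to
its unique pattern.

## k-modes clustering

`kmodes()` clusters the unique patterns under the matching dissimilarity
(count of differing positions). Code 0 participates as an ordinary
category: "drug absent" versus "drug on day 3" is a real difference
between patient-days, and the clustered patterns contain 0s by
construction. (An alternative that ignores 0-positions is deliberately not
the default.)

The fit is the classic alternation: assign every pattern to the nearest
mode (ties to the lowest cluster index), recompute each mode attribute-wise
as the most frequent category among members (ties to the lowest code),
stop when labels stabilise. Within one run the cost never increases. The
first start is the deterministic density-based initialization of Cao et
al. (attribute-frequency density, then greedy maximin selection); the
remaining `n_init - 1` starts (default 20) draw distinct patterns at
random under the seed, and the best run by cost wins. An emptied cluster
is re-seeded with the point farthest from its current mode. Everything is
reproducible from the seed.

`elbow_select()` fits k = 1..k_max (default 25) and picks the knee as the
maximum second difference of the cost curve. When the data run out of
distinct patterns before `k_max`, the curve is padded flat for knee
detection, since further clusters cannot reduce the cost. The automatic
choice is advisory: the pipeline accepts a fixed `k` per dataset, and 4
(therapy) and 7 (monitoring) are the presets used in practice after
inspecting elbow charts.

`assign_clusters()` propagates the unique-pattern labels to every source
record through the dedup back-map — by construction identical to
re-assigning each record to its nearest mode.

## Stay analysis

`build_stay_table()` joins the two label streams into the synoptic object:
one row per treated patient-day holding the day's therapy cluster and 24
hourly monitoring-cluster cells. Hourly cells are stored as
`monitoring cluster + 1` with 0 reserved for hours without monitoring;
storing raw ids would make "no monitoring" indistinguishable from
monitoring cluster M0. Report labels (T0.., M0..) are applied at
presentation time only.

Derived tables:

* `subset_frequencies()` — per cluster, the F1..F5 distribution over
  non-null codes, with pattern and non-null counts.
* `contingency_table()` — therapy-by-monitoring cluster frequencies over
  all monitored hours, as fractions of the grand total (the whole table
  sums to 1); absent hours are excluded because 0 is missingness, not a
  cluster.
* `chi_square()` — Pearson's test on the raw counts (not the displayed
  frequencies), no continuity correction, `(r-1)(c-1)` degrees of freedom.
  A zero marginal is an error rather than a silent drop.
* `nabtcl_summary()` — the per-stay count of distinct therapy clusters
  (Nabtcl) and the population stratified by it: stays, monitored hours,
  therapy- and monitoring-cluster distributions, and the overall-duration
  fuzzy-subset distribution per stratum. Stratum frequencies are
  conditional distributions (each stratum column sums to 1).

`stay_chart()` draws paired therapy/monitoring bars for a window of
monitored hours (default 14) and `plot_fuzzy_ribbon()` the fuzzified
parameter traces — the two bedside views.

## The synthetic cohort

`simulate_cohort()` emulates the structure of a PDMS extract, not any
real population:

* stay lengths are log-normal (median 6 days, `sdlog` 0.6, clipped to
  2–60) — a right-skewed ICU stay distribution;
* 80% of patients receive antimicrobials; a treated patient has
  `1 + Poisson(1.2)` courses; drugs are drawn from the 90-name vocabulary
  with Zipf-like weights so a few workhorse agents dominate;
* course lengths come from a two-component mixture — geometric
  (`p = 0.35`) for routine short courses plus a long tail
  (`8 + Poisson(10)` days) with weight 0.15 — chosen so that all five
  duration categories are genuinely populated rather than concentrating
  in "ultra-short";
* hourly vitals are normal per parameter with the schema's mean, SD,
  per-hour missingness and a per-patient gate (e.g. intracranial pressure
  in 10% of patients), reproducing structured missingness;
* courses are contiguous day blocks, so consecutive-day counters are
  exercised with known answers.

Vitals are i.i.d. across hours by default; an AR(1) option exists for
chart realism but stays off in tests, which assume exchangeable hours.
The generator does not model pharmacodynamics, sepsis episodes,
inter-parameter correlation or outcome, so passing tests demonstrate the
correctness of the machinery on data with the right shape and
missingness — they say nothing about clinical validity on real
populations, which requires the real extract.

`simulate_patterns()` plants K modes and perturbs each attribute with
probability ε (uniform resampling over codes 0–5, so a fraction ε·5/6
actually changes); it is the ground-truth source for cluster-recovery
tests, which require an adjusted Rand index of at least 0.9 at K = 4,
length 20, n = 500, ε = 0.05.

## Problem sizes and numerical choices in the test suite

The suite validates the clustering against an exhaustive-partition oracle
(subset dynamic programming) on instances of up to 10 unique patterns,
where the global optimum is computable; chi-square against the textbook
formula on random tables to 1e-9; and dedup against exhaustive
zero-distance matching on 1,000 random patterns. The end-to-end run uses
a 200-patient cohort with the k = 4 / k = 7 presets and 10 restarts —
about 35,000 monitoring hours, enough to populate every table while
keeping the full chain under two minutes. Elbow-based selection is
exercised separately on planted-structure data, where the knee must land
on the planted K in at least 8 of 10 replicates.

## Known limitations

* The domain geometry assumes a roughly unimodal distribution; for
  strongly multimodal parameters a median-anchored medium triangle may
  not be the clinically natural "normal" band. Expert-curated ranges
  (MEWS-style) are intentionally out of scope.
* Only fuzzification is implemented — there is no rule base or
  defuzzification; the package is not a fuzzy inference engine.
* The consecutive-day counter works on calendar days and knows nothing of
  doses, routes or drug classes.
* k-modes is the only clustering offered; k-means on fuzzy codes,
  fuzzy c-means and model-based alternatives are non-goals.
* Cost scores and cluster counts are data-dependent; on synthetic cohorts
  they characterise the machinery, not any hospital population.
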