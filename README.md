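# fuzzystay

Fuzzy-logic discretization and k-modes profiling of ICU antimicrobial
therapy and bedside monitoring data.

## What it does, and for whom

Intensivists summarise patients qualitatively — "long course of
meropenem, hemodynamics stable, lactate a bit high" — while the patient
data management system stores thousands of raw numbers per stay.
fuzzystay bridges the two. It is aimed at clinical data scientists and
antimicrobial-stewardship teams who want patient-day therapy patterns and
patient-hour monitoring patterns expressed in a small linguistic
vocabulary, grouped into a handful of recurring profiles, and laid out
per stay for discussion.

The method has three stages:

1. **Automatic fuzzy domains.** For each parameter, the population
   distribution is trimmed to the smallest observed-value set covering
   ≥ 95% of observations (m, M, median *med*, SD *s* of the trimmed
   sample). Five fuzzy subsets F1..F5 — two trapezoidal shoulders and
   three triangles, adjacent pairs overlapping by *h = s/2* — are placed
   by closed form:

   ```
   VLL = m − h     LL = m + h     VLH = m + 2h
   NL  = med − (M−m)/6            NH = med + (M−m)/6
   LH  = NL + h                   HL = NH − h
   VHL = M − 2h    HH = M − h     VHH = M + h
   ```

   A value is assigned the category with the highest membership degree
   (ties to the lower category); missing data are category 0 ("none").
   Therapy durations read as "ultra-short".."ultra-long", monitoring
   parameters as "very low".."very high".

2. **Patterns and k-modes.** Per-day therapy records (overall plus
   per-drug consecutive-day counters, 91 columns with the default
   90-drug vocabulary) and per-hour monitoring records (46 columns by
   default) are fuzzified into category vectors, deduplicated (exact
   equality ≡ zero Euclidean distance), and the unique patterns are
   clustered by k-modes under the matching dissimilarity
   d(a, b) = #{j : aⱼ ≠ bⱼ}, with Cao initialization plus seeded random
   restarts and elbow-based selection of k (maximum second difference of
   the cost curve; fixed presets k = 4 therapy / k = 7 monitoring are
   supported).

3. **Stay tables.** Labels propagate back to all records and join into
   per-stay rows (therapy cluster + 24 hourly monitoring cells),
   therapy-by-monitoring contingency tables with Pearson chi-square,
   per-cluster fuzzy-subset frequency tables, and stratification by the
   number of distinct therapy clusters per stay (Nabtcl).

A seeded synthetic-cohort generator (`simulate_cohort()`) emulates the
shape of a PDMS extract — log-normal stays, Zipf-weighted drug courses
with a long-tail duration mixture, 46 hourly vitals with structured
missingness — so the entire chain is testable without hospital data.

## Worked example

Cluster planted category patterns and check recovery:

```r
library(fuzzystay)

sim <- simulate_patterns(K = 4, length = 20, n = 500, eps = 0.05, seed = 1)
fit <- kmodes(sim$patterns, k = 4, seed = 1)
glance(fit)
#> # A tibble: 1 × 6
#>       k  cost     n n_init iterations  seed
#> 1     4   441   500     20          2     1
tidy(fit)
#> # A tibble: 4 × 3
#>   cluster  size within_cost
#> 1       0   117         104
#> 2       1   144         127
#> 3       2   112          97
#> 4       3   127         113
mclust::adjustedRandIndex(fit$labels, sim$labels)
#> [1] 1
```

The cost 441 is the total number of mismatching attribute positions
between the 500 patterns and their cluster modes; an adjusted Rand index
of 1 means the planted grouping was recovered exactly despite the 5%
attribute noise.

Run the full pipeline on a synthetic cohort:

```r
cfg <- pipeline_config(out_dir = "demo", seed = 1, n_patients = 60,
                       therapy_k = 4, monitoring_k = 7, n_init = 5)
run_pipeline("all", cfg)

readr::read_csv("demo/chi_square.csv")
#>   statistic   dof p_value table
#> 1      25.4    18   0.113 therapy_x_monitoring
readr::read_csv("demo/nabtcl_strata.csv")
#>   nabtcl n_stays n_hours
#> 1      1      20     936
#> 2      2      20    2016
#> 3      3      13    2712
#> 4      4       1     168
```

Here 20 simulated stays never change therapy profile (Nabtcl 1), one
visits four different profiles, and the contingency cells
(`demo/contingency.csv`) sum to 1 over all monitored hours. The run also
writes the fuzzy-domain chart, a paired therapy/monitoring cluster bar
chart for one stay, and the fuzzified-parameter ribbon view.

A single parameter end to end:

```r
domain <- fuzzy_domain(0, 22, 11, 1.8, labels = therapy_labels())
round(domain$limits, 1)
#>  VLL   LL  VLH   NL   LH   HL   NH  VHL   HH  VHH
#> -1.8  1.8  3.6  7.3  9.1 12.9 14.7 18.4 20.2 23.8
fuzzify(domain, c(NA, 1, 8, 11, 25))
#> [1] 0 1 2 3 5
```

A missing duration is "none", 1 day is "ultra-short", 8 days sits in the
short/medium overlap and resolves to "short", 11 days is the "medium"
peak, and 25 days clamps to "ultra-long".

A command-line wrapper for the staged pipeline ships in
`inst/scripts/fuzzystay` (`fuzzystay all --out-dir out/ --seed 1`).

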