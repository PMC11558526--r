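# immunostage

Stage-specific immuno-assessment of sepsis from serial complete blood
counts, for biostatisticians and clinical researchers working with
longitudinal CBC data.

Single leukocyte variables rarely discriminate septic outcomes at the
individual level: survivor and non-survivor value intervals overlap even
when group medians differ significantly. `immunostage` implements a
non-reductionist pipeline that

* expands the leukocyte differential into a combinatorial space of
  **dimensionless indicators** — canonical monomials
  $\prod_i x_i^{e_i}$ with $\sum_i e_i = 0$ over percentages and count
  fractions ("ratios and products of ratios"); the default grammar holds
  33,110 distinct indicators;
* quantifies **data overlap** per feature and group pair as
  $\mathrm{len}(A \cap B)/\min(\mathrm{len}\,A, \mathrm{len}\,B)$ on
  quantile intervals, with zero overlap (disjoint intervals) as the
  criterion of personalized discrimination, alongside rank-sum, chi-square
  and kurtosis statistics;
* detects **thin line-like structures** in 3D indicator space (principal-axis
  thinness $1-(\lambda_2+\lambda_3)/\sum\lambda$), orders observations along
  them, and partitions at perpendicular direction inflections into subsets
  of contrasting mortality;
* classifies every observation into one of **five inflammatory stages** —
  early inflammation, early immunocompetence, intermediary (monocyte-mediated)
  suppression, late (renal-associated) suppression, other — from cohort-quantile
  rules on $N/L$, $[N/L]/[M/N]$, $M/N$, serum urea and creatinine, with
  temporal constraints (no suppression in week 1, immunocompetence only in
  week 1);
* builds **personalized trajectories** against the population reference
  curve, including detection of persistent (immunoparalysis-like) profiles;
* ships a seeded **synthetic cohort generator** (331 patients, ~4,072
  longitudinal observations, stage-structured markers and mortality) so the
  whole pipeline is testable without external data.

The central estimator follows the classic R modelling idiom: `immunostage()`
fits the five-stage classifier to a cohort and returns an object with
`print`, `summary`, `coef`, `fitted`, `predict` and `plot` methods.

## Worked example

```r
library(immunostage)

sim    <- simulate_cohort(cohort_config(seed = 42))
cohort <- sim$cohort
cohort
#> Sepsis cohort: 331 patients, 4060 observations
#> status
#>   non_septic not_assigned       septic
#>           43            2          286

summarize_mortality(cohort, "day1_only")
#> 30-day in-hospital mortality (day-1 patients)
#>         group total deaths mortality_pct
#>        septic   286     85          29.7
#>    non_septic    43      2           4.7
#>  not_assigned     2      0           0.0

fit <- immunostage(cohort)
summary(fit)
#> Stage rules: quantile cutpoints (low = 0.10, high = 0.75) from 4060 observations
#>                low    high
#> NL          2.2518  6.3174
#> NL_over_MN  0.4009 26.5241
#> MN          0.0874  0.4118
#> urea       23.2000 41.9000
#> creatinine  0.6500  1.0700
#>
#> Stage-outcome table:
#>                     stage    n deaths mortality_pct
#>        early_inflammation  369    118          32.0
#>    early_immunocompetence  232      0           0.0
#>  intermediary_suppression  132     89          67.4
#>          late_suppression  353    264          74.8
#>                     other 2974    638          21.5
#> stage-outcome association: chi2 = 650.36, df = 4, p = 1.95e-139

mean(as.character(fitted(fit)) == sim$truth$stage)
#> [1] 0.9231527
```

Reading: day-1 septic mortality (29.7%) is about six times the non-septic
rate, the fitted stages separate outcomes strongly — no deaths among
immunocompetent observations, two-thirds-plus mortality in both suppression
stages — and the classifier recovers 92% of the generator's ground-truth
stage labels from the cohort-quantile rules alone.

The same steps are available as a file-based chain
(`run_pipeline("simulate"|"expand"|"scan"|"partition"|"stage"|"trajectory"|"report")`,
or the `inst/cli/immunostage` wrapper), writing CSV/JSON artifacts and a
run manifest per step.

## Layout

* `R/` — cohort I/O and validation, DI grammar, overlap statistics,
  pattern geometry, the stage classifier, trajectories, the generator,
  pipeline orchestration
* `tests/testthat/` — unit, property and acceptance tests (fixtures built
  in code)
* `vignettes/immunostage-methods.Rmd` — models, assumptions, parameter
  defaults, design decisions, limitations
* `scripts/acceptance.R`, `inst/cli/immunostage` — entry points
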