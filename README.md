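# epiregistry

Statistical toolkit for population-based disease registries. Registry
statisticians routinely need the same half-dozen analyses — descriptive
incidence or mortality rates, trends, projections, two-population
comparisons, and patient survival corrected for background mortality —
and `epiregistry` provides them as one tested R package with a
command-line interface, working from plain delimited files.

## What it computes

* **Rates** — crude rate `100000·X/N`; age-specific rates; the directly
  age-standardized rate `ASR = Σ wᵢrᵢ / Σ wᵢ` (Segi world standard
  embedded, file override supported); the truncated rate over ages
  35–64; the cumulative rate to age 74, `CumR = Σ 5·rᵢ`, and cumulative
  risk `1 − exp(−CumR)`.
* **Trends** — estimated annual percent change from the Gaussian
  log-linear model `log(ASR_T) = α + βT`, with
  `EAPC = (e^β − 1)·100` and a t-based transformed confidence interval;
  trends classified increasing/decreasing/stable by whether the CI
  contains 0.
* **Projections** — log-linear count models of age-specific rates with
  person-years offset, `log(C_iT/Y_iT) = αᵢ + βᵢ(T−T₀)` or the common
  slope (*age-drift*) variant, under Poisson or negative-binomial error;
  four candidates compared by AIC with a Pearson chi-square
  goodness-of-fit diagnostic; expected cases at a future year
  `Ŷ_iF·exp(α̂ᵢ + β̂(F−T₀))` plus the projected ASR.
* **SIMR** — standardized incidence/mortality ratio `D/E` with
  `E = Σ rᵢ^ref·Yᵢ^target`, exact Poisson (gamma-inversion) confidence
  interval, Byar's approximation optional.
* **Net-change decomposition** — the change in case counts between two
  periods or areas partitioned exactly into risk, population-size and
  population-structure components, on absolute, percent and crude-rate
  scales.
* **Relative survival** — Kaplan–Meier observed survival over Hakulinen
  expected survival from sex × age × calendar-year life tables, with
  log-transform confidence intervals, reported on an annual grid.
* **Synthetic registry** — a generator with known ground truth (true
  EAPC, true SIMR, true decomposition, closed-form true relative
  survival) producing the full six-file input set.

## Worked example

```r
library(epiregistry)
sim <- simulate_registry(registry_spec(seed = 20))

rate_summary(sim$aggregated)
#>  sex   disease cases person_years crude_rate   asr truncated_asr
#>    1 Synthetic  4909      5649595      86.89 33.39         54.89
#>    2 Synthetic  5141      5649595      91.00 35.11         57.90
#>  cumulative_rate_pct cumulative_risk
#>                 3.94          0.0386
#>                 4.11          0.0402

ser <- asr_series(sim$aggregated, sex = 1, disease = "Synthetic")
fit_eapc(ser$year, ser$asr)
#> EAPC = 2.28% (95% CI: 0.80, 3.79), 10 years 1995-2004: increasing trend
```

The generator's rates rise 2% a year, so the ASR of ~33 per 100,000 and
the EAPC interval covering 2 are the expected readings. Comparing the
two halves of the decade for women (sex 2):

```r
agg <- sim$aggregated
a1 <- agg[agg$year <= 1999 & agg$sex == 2, ]
a2 <- agg[agg$year >= 2000 & agg$sex == 2, ]
pool <- function(x, g) sapply(1:18, function(i) sum(x[g == i]))
simr_with_ci(sum(a2$cases),
             expected_events(pool(a1$cases, a1$age_group),
                             pool(a1$person_years, a1$age_group),
                             pool(a2$person_years, a2$age_group)))
#> SIMR = 1.13 (95% CI: 1.09, 1.18), D = 2795 observed, E = 2465.7 expected
#>   significant excess risk vs the reference

decompose_net_change(pool(a1$cases, a1$age_group),
                     pool(a1$person_years, a1$age_group),
                     pool(a2$cases, a2$age_group),
                     pool(a2$person_years, a2$age_group))
#> Net-change decomposition (net = risk + size + structure):
#>                scale     net    risk    size structure population
#>       absolute_cases 449.000 329.330 119.670         0    119.670
#>              percent  19.139  14.038   5.101         0      5.101
#>  crude_rate_per_100k  11.376  11.376   0.000         0      0.000
```

Cases rose 19.1%: 5.1 points from population growth, the remaining 14.0
from increased risk (the generator's population grows uniformly, so the
structure component is zero). Projection and survival:

```r
sub <- agg[agg$sex == 1, ]
best <- select_model(fit_count_models(sub))
best
#> Log-linear count model: poisson, drift slope (T0 = 2004)
#>   drift beta = 0.02170 (annual rate change 2.19%)
#>   AIC = 875.06; Pearson X2 = 166.45 on 161 df (p = 0.368)

m <- sim$individual[sim$individual$sex == 1, ]
relsurv_curve(m, sim$life_table, study_end_year = 2004, max_years = 5)
#> Relative survival (observed / Hakulinen expected):
#>  Risk T    RS   LCI   UCI    OS
#>  4909 0 1.000 1.000 1.000 1.000
#>  3686 1 0.866 0.855 0.877 0.841
#>  2676 2 0.742 0.727 0.756 0.700
#>  1934 3 0.644 0.627 0.661 0.591
#>  1366 4 0.547 0.529 0.566 0.489
#>   934 5 0.469 0.450 0.489 0.407
```

The 5-year relative survival of 0.469 (CI 0.450–0.489) estimates the
generator's true value `exp(−5·0.15) = 0.472`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/epiregistry.R", package = "epiregistry"))')
Rscript $CLI simulate --output-dir demo --seed 7
Rscript $CLI descriptive --input demo/aggregated.csv --output demo/rates.csv
Rscript $CLI eapc        --input demo/aggregated.csv --output demo/eapc.csv
Rscript $CLI relsurv     --input demo/individual_records.csv \
                         --life-table demo/life_table.csv \
                         --study-end-year 2004 --output demo/rs.csv
```

Subcommands: `descriptive`, `eapc`, `expected`, `simr`, `riskdiff`,
`relsurv`, `simulate`; run with no arguments for the full flag list.

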