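---
title: "Statistical methods for disease-registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for disease-registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiregistry)
```

`epiregistry` bundles the descriptive and inferential analyses a
population-based disease registry runs routinely: rates and their
standardization, trend estimation, projection of future case counts,
comparison of two populations by a standardized ratio, decomposition of a
change in case counts into demographic and risk components, and cohort
relative survival. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical and design choices made where the
methods literature leaves latitude.

## Data model

All analyses run off two substrates. *Aggregated counts* are case counts
and person-years at risk per sex × age-group × calendar-year × disease
cell; the default age-group scheme is eighteen 5-year groups 0–4 … 85+
(half-open intervals `[lower, upper)`, only the last open-ended).
*Individual records* carry one diagnosed patient each — sex, disease
group, age and date at diagnosis, vital status (1 = dead, 0 =
alive/censored), end of follow-up, follow-up time in years — and feed the
survival analysis as well as `aggregate_individuals()`. Auxiliary inputs
are the standard-population weights, a person-years distribution, and a
general-population life table of annual survival probabilities indexed by
sex, single year of age and calendar year. Files are plain delimited text
with a header; comma and semicolon are auto-detected with comma winning a
tie, and age-group indices in files are 1-based. When the stored follow-up
time and the redundant diagnosis/end date pair disagree by more than 1/12
year the stored time is taken as authoritative with a warning — a silent
choice either way would corrupt survival times.

## Rates

With $X$ cases over $N$ person-years the crude rate is $100\,000\,X/N$.
The age-standardized rate is the weighted mean of age-specific rates
$r_i$,
$$\mathrm{ASR} = \frac{\sum_i w_i r_i}{\sum_i w_i},$$
with the Segi world standard weights as the embedded default (a supplied
standard-population file overrides them). A zero-person-years group under
a positive weight is a coverage error rather than a silent zero rate. The
truncated rate restricts the same estimator to the groups tiling ages
35–64 — used where diagnosis in the elderly is considered unreliable —
and re-normalizes the weights within the range; because the estimator
divides by the weight total, re-normalizing or not changes nothing, but
the convention is stated so results can be compared against tools that
print intermediate weighted sums. The cumulative rate to age 74 is
$\mathrm{CumR} = \sum_i 5\, r_i$ over the fifteen closed 5-year groups
(widths in years, rates per person-year), and the cumulative risk is
$1 - e^{-\mathrm{CumR}}$ — the probability of developing the disease
before age 75 absent competing mortality.

## Trend: estimated annual percent change

The EAPC model assumes rates change by a constant percentage per year:
$$\log(\mathrm{ASR}_T) = \alpha + \beta T + \varepsilon,$$
fitted by ordinary least squares on the already-standardized annual ASR
series (at least 3 positive points). Then
$\mathrm{EAPC} = (e^{\beta} - 1) \cdot 100$, and the confidence interval
transforms the interval for $\beta$, by default built with the
$t_{n-2}$ quantile (a normal-quantile option exists for cross-checking
against tools that use $z$). A trend is *stable* when the interval
contains 0, *increasing*/*decreasing* otherwise. Years with a zero ASR
are a hard error naming the year — `log(0)` silently dropped is the
classic corruption bug — with `drop_zero_years = TRUE` as the explicit
escape hatch. The fit is unweighted: weighting years by case counts is a
defensible alternative, but the plain Gaussian log-linear model is the
convention this estimator is defined by.

## Projection of case counts

Future counts come from log-linear models of age-specific rates with
person-years as exposure offset:
$$\log(C_{iT}/Y_{iT}) = \alpha_i + \beta_i (T - T_0)
 \quad\text{or}\quad \alpha_i + \beta (T - T_0),$$
the second — one common slope — being the *age-drift* model. Both are fit
under Poisson and under negative-binomial error (dispersion estimated by
maximum likelihood via `MASS::glm.nb`), giving four candidates. Selection
is by minimum AIC; exact ties break toward fewer parameters (drift before
age-specific, Poisson before negative binomial). A Pearson chi-square
goodness-of-fit statistic on `cells − parameters` degrees of freedom is
reported as a diagnostic and warns when the winner fails at 0.05, but it
does not veto the AIC choice — with both criteria reported, one must
decide, and AIC decides. $T_0$ defaults to the last observed year; it
shifts the meaning of $\alpha_i$ only, never predictions. Age groups with
zero cases in every year cannot be represented on the log scale; they are
excluded and predicted as zero, with a notice. Prediction at year $F$
plugs future person-years into the fitted rate:
$\hat C_{iF} = Y_{iF}\, e^{\hat\alpha_i + \hat\beta (F - T_0)}$, with the
projected ASR computed from the predicted cells.

## Standardized incidence/mortality ratio

For a target population with $D$ observed events, the expected count
under the reference population's age-specific rates is
$E = \sum_i r^{\mathrm{ref}}_i Y^{\mathrm{tar}}_i$, and
$\mathrm{SIMR} = D/E$. $E$ is treated as a known constant (the classical
convention: the reference is usually much larger, and its sampling error
is ignored), so the interval comes from the Poisson distribution of $D$
alone. The default is the exact gamma-inversion interval — lower bound
$q_{\gamma}(\alpha/2; D)/E$ (0 when $D = 0$), upper
$q_{\gamma}(1-\alpha/2; D+1)/E$ — with Byar's approximation behind a
flag. Mismatched age schemes between target and reference are an error,
never silently re-binned. Significance is read off the interval
containing 1.

## Decomposing a change in case counts

Between a reference and a target period (or two areas), with reference
rates $r_i = C^1_i/Y^1_i$ and person-year totals $N^1, N^2$:

* net $= \sum C^2_i - \sum C^1_i$;
* size $= \sum C^1_i\,(N^2/N^1 - 1)$ — cases added by uniform population
  growth;
* structure $= \sum r_i Y^2_i - \sum C^1_i\, N^2/N^1$ — the further
  change from the shifted age pyramid at old rates;
* risk $= \sum C^2_i - \sum r_i Y^2_i$ — the residual not explained by
  demography.

Additivity `net = risk + size + structure` holds exactly by construction
on all three reported scales (absolute cases, percent of the reference
total, crude rate per 100,000 — where the size term vanishes, since a
uniform rescaling of the population leaves the crude rate unchanged).
Component values depend on the ordering of the partition; the convention
here — size first, structure second, risk as residual — is the standard
one and is fixed. Rates within each period are treated as constant, i.e.
inputs are period totals. A subtlety worth a worked example: with
reference counts $(10, 10)$ on person-years $(1000, 1000)$ and target
$(10, 30)$ on $(1000, 2000)$, the reference rates are equal across age
groups, so the structure component is exactly zero — when all
age-specific rates are equal, no re-shaping of the pyramid can change
expected cases — and the 100% net increase splits 50% size, 50% risk.
No significance measures are attached to the components; none are defined
for this partition.

## Relative survival

Cohort relative survival is $RS(T) = S_o(T)/S_E(T)$: all-cause observed
survival over the survival the cohort would have under general-population
mortality, interpreted as net survival when the disease is the only
excess cause of death. $S_o$ is the Kaplan–Meier product-limit estimator
on exact (continuous) follow-up times via the `survival` package — the
annual rows of the report are evaluation points, not actuarial intervals
(an actuarial variant would require interval-grouped estimation, which
exact-time data make unnecessary). $S_E$ uses Hakulinen's cohort
estimator: for annual interval $j$, every patient still *potentially*
under follow-up — diagnosis to study end, regardless of earlier death or
loss — contributes their life-table annual survival probability
(matched on sex, attained age, calendar year), weighted by the patient's
cumulative expected survival to the interval start; a patient whose
potential follow-up ends a fraction $f$ into the interval contributes
$p^f$ (constant hazard within the year). Keeping lost patients on the
expected side is the essence of Hakulinen's method versus Ederer II, and
removes the bias of heterogeneous potential follow-up. Attained age and
calendar year advance annually from diagnosis; ages beyond the life
table's maximum reuse its last age row with a warning, while a missing
calendar year is a hard coverage error naming the cell. The 95% interval
transforms the Greenwood standard error of $\log S_o$ with the normal
0.975 quantile, treating $S_E$ as constant; $RS$ may exceed 1 and is not
clipped (only the lower bound is clipped at 0). On a homogeneous cohort
with full potential follow-up the estimator collapses to the plain
product of annual probabilities, and with a unit life table $RS \equiv
S_o$ — both identities are tested to machine precision.

## The synthetic registry

`simulate_registry()` produces the full input file set with known ground
truth, so every estimator can be validated without access to registry
microdata. Cell counts are Poisson with mean rate × person-years;
age-specific rates change by a constant factor per year, making the true
EAPC `(annual_rate_change − 1)·100`. Patient survival follows an additive
hazard — the constant background hazard implied by the synthetic life
table plus a constant excess hazard — so true relative survival is
exactly $e^{-\lambda_{\mathrm{excess}} t}$, an analytic oracle for the
survival module. Defaults describe a modest mid-size registry: ten
diagnosis years (1995–2004), two sexes, 30,000 person-years per sex ×
age-group cell growing 1% a year, an adult-cancer-like age profile
rising from 1 to 260 per 100,000, rates rising 2% a year, a 0.15/year
excess hazard and 0.97 annual background survival — magnitudes a
registry statistician would recognize as ordinary, chosen once and not
revisited. One global seed fans out to per-stream seeds for counts and
survival, and a fixed seed reproduces files byte for byte. What the
generator does *not* emulate: realistic site-specific rate profiles,
age-dependent background mortality, sub-annual seasonality, and
registry-quality artefacts (late registration, death-certificate-only
cases). Tests passing on this generator therefore validate the
estimators' mathematics, not robustness to real-world data quality.

## Numerical choices and problem sizes

Exact identities (decomposition additivity, ASR versus a brute-force
loop, the Hakulinen product identity) are tested to 1e-10 or tighter.
Stochastic properties use fixed-seed Monte Carlo at sizes chosen so the
quantity under test is separated from its acceptance bound by several
Monte-Carlo standard errors: 2,000 replicates for EAPC and SIMR coverage,
200 replicated 18 × 10 registries for drift-slope recovery and model
selection, 500 replicated cohorts for the null-excess-hazard relative
survival check. For the exact-interval coverage check the simulation is
placed at an expected count of 50, where the interval's true coverage
(enumerated over the Poisson distribution) is 96.1% — coverage of exact
Poisson intervals oscillates with the expected count, and a configuration
sitting exactly on the nominal bound would make the empirical check a
coin flip on Monte-Carlo noise rather than a test of the implementation.

## Limitations

No confidence intervals accompany the descriptive rates, no
changepoint/joinpoint modelling backs the single-slope EAPC, projections
carry no prediction intervals, the decomposition has no inferential
wrapper, and the survival module fits no excess-hazard regression and
compares no pairs of curves. These are deliberate scope edges, not
oversights; the surrounding ecosystem (`survival`, `flexsurv`, dedicated
joinpoint software) covers them.
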