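# Descriptive rate statistics: crude, age-specific, directly standardized,
# truncated (ages 35-64) and cumulative (ages 0-74) rates, and the
# cumulative risk 1 - exp(-CumR). All rates are reported per 100,000
# person-years unless noted; the cumulative rate is the dimensionless sum
# of age-specific rates times group widths.

#' Segi world standard population
#'
#' The classical world standard population weights for the eighteen 5-year
#' age groups 0-4 through 85+ (total 100,000). Used as the default standard
#' for direct age standardization; a file-based standard supplied by the
#' user takes precedence.
#'
#' @return Numeric vector of 18 weights.
#' @export
world_standard_population <- function() {
  c(12000, 10000, 9000, 9000, 8000, 8000, 6000, 6000, 6000, 6000,
    5000, 4000, 4000, 3000, 2000, 1000, 500, 500)
}

#' Crude rate per 100,000 person-years
#'
#' @param cases Number of observed events (X).
#' @param person_years Person-years at risk (N).
#' @return The rate 100000 * X / N.
#' @export
crude_rate <- function(cases, person_years) {
  if (any(person_years <= 0)) {
    stop("person-years must be positive", call. = FALSE)
  }
  if (any(cases < 0)) stop("cases must be non-negative", call. = FALSE)
  1e5 * cases / person_years
}

#' Age-specific rates per 100,000 person-years
#'
#' @param cases Case counts per age group.
#' @param person_years Person-years per age group.
#' @return Numeric vector of rates; `NA` where person-years are zero.
#' @export
age_specific_rates <- function(cases, person_years) {
  ifelse(person_years > 0, 1e5 * cases / person_years, NA_real_)
}

#' Directly age-standardized rate
#'
#' Weighted mean of age-specific rates with standard-population weights:
#' ASR = sum(w_i * r_i) / sum(w_i), per 100,000 person-years. Invariant to
#' rescaling all weights by a constant. Groups with zero weight and zero
#' person-years are skipped; zero person-years under a positive weight is a
#' coverage error.
#'
#' @param cases Case counts per age group.
#' @param person_years Person-years per age group.
#' @param std Standard-population weights, one per age group (default the
#'   Segi world standard for 18 five-year groups).
#' @return The age-standardized rate per 100,000 person-years.
#' @export
direct_standardized_rate <- function(cases, person_years,
                                     std = world_standard_population()) {
  k <- length(std)
  if (length(cases) != k || length(person_years) != k) {
    stop("cases, person_years and std must have one entry per age group",
         call. = FALSE)
  }
  if (any(std < 0)) stop("standard weights must be non-negative",
                         call. = FALSE)
  bad <- std > 0 & (is.na(person_years) | person_years <= 0)
  if (any(bad)) {
    stop("age group(s) ", paste(which(bad), collapse = ", "),
         " carry positive standard weight but no person-years",
         call. = FALSE)
  }
  use <- std > 0
  r <- 1e5 * cases[use] / person_years[use]
  sum(std[use] * r) / sum(std[use])
}

# indices of the scheme's groups exactly tiling [lower, upper + 1)
aligned_groups <- function(scheme, lower, upper) {
  hi <- upper + 1
  idx <- which(scheme$lower >= lower & scheme$upper <= hi)
  if (length(idx) == 0L || scheme$lower[idx[1]] != lower ||
      scheme$upper[idx[length(idx)]] != hi) {
    stop("age range [", lower, ", ", hi, ") does not align with the ",
         "age-group scheme boundaries", call. = FALSE)
  }
  idx
}

#' Truncated age-standardized rate (ages 35-64)
#'
#' The directly standardized rate restricted to the age groups tiling
#' `[lower, upper + 1)`; standard weights are renormalized within the
#' truncated range. Used where age-specific rates in the elderly are
#' considered unreliable.
#'
#' @inheritParams direct_standardized_rate
#' @param scheme An [age_scheme()].
#' @param lower,upper Truncation bounds in years (inclusive ages; default
#'   35-64). Must align with group boundaries.
#' @return The truncated standardized rate per 100,000 person-years.
#' @export
truncated_rate <- function(cases, person_years, scheme = age_scheme(),
                           std = world_standard_population(),
                           lower = 35, upper = 64) {
  idx <- aligned_groups(scheme, lower, upper)
  direct_standardized_rate(cases[idx], person_years[idx], std[idx])
}

#' Cumulative rate and cumulative risk from birth to a given age
#'
#' CumR is the sum over age groups within `[0, max_age + 1)` of the
#' age-specific rate (per person-year) times the group width in years;
#' the cumulative risk is `1 - exp(-CumR)`, the probability of developing
#' the event before `max_age + 1` in the absence of competing mortality.
#'
#' @inheritParams truncated_rate
#' @param max_age Last age included (default 74, i.e. ages 0-74).
#' @return List with elements `cumulative_rate` (dimensionless) and
#'   `cumulative_risk` (probability).
#' @export
cumulative_rate_and_risk <- function(cases, person_years,
                                     scheme = age_scheme(), max_age = 74) {
  idx <- aligned_groups(scheme, 0, max_age)
  if (any(is.infinite(scheme$upper[idx]))) {
    stop("open-ended age group below age ", max_age + 1, call. = FALSE)
  }
  if (any(person_years[idx] <= 0)) {
    stop("zero person-years within ages 0-", max_age, call. = FALSE)
  }
  widths <- group_widths(scheme)[idx]
  cumr <- sum(widths * cases[idx] / person_years[idx])
  list(cumulative_rate = cumr, cumulative_risk = 1 - exp(-cumr))
}

#' Descriptive rate summary by sex and disease
#'
#' Pools an aggregated-counts table over its years and computes, for each
#' sex x disease stratum, the case total, person-years, crude rate, ASR,
#' truncated rate (35-64) and cumulative rate/risk (0-74), all rates per
#' 100,000 person-years. The cumulative rate is also reported as a percent
#' (100 * CumR).
#'
#' @param agg An `aggregated_counts` table.
#' @param scheme An [age_scheme()].
#' @param std Standard-population weights (default Segi world standard).
#' @return Data frame of class `rate_summary`, one row per sex x disease.
#' @export
rate_summary <- function(agg, scheme = age_scheme(),
                         std = world_standard_population()) {
  strata <- unique(agg[c("sex", "disease")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    s <- strata$sex[i]; d <- strata$disease[i]
    sub <- agg[agg$sex == s & agg$disease == d, ]
    cases <- vapply(seq_len(n_groups(scheme)), function(g)
      sum(sub$cases[sub$age_group == g]), numeric(1))
    py <- vapply(seq_len(n_groups(scheme)), function(g)
      sum(sub$person_years[sub$age_group == g]), numeric(1))
    cum <- cumulative_rate_and_risk(cases, py, scheme)
    data.frame(sex = s, disease = d,
               cases = sum(cases), person_years = sum(py),
               crude_rate = crude_rate(sum(cases), sum(py)),
               asr = direct_standardized_rate(cases, py, std),
               truncated_asr = truncated_rate(cases, py, scheme, std),
               cumulative_rate = cum$cumulative_rate,
               cumulative_rate_pct = 100 * cum$cumulative_rate,
               cumulative_risk = cum$cumulative_risk,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rate_summary", "data.frame")
  out
}

#' @export
print.rate_summary <- function(x, digits = 2, ...) {
  cat("Descriptive rates per 100,000 person-years",
      "(ASR: direct standardization; TR: ages 35-64; CumR/Risk: ages 0-74)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  y$cumulative_risk <- signif(x$cumulative_risk, 3)
  y$cumulative_rate <- NULL
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' Annual ASR series for one sex x disease stratum
#'
#' @param agg An `aggregated_counts` table.
#' @param sex Sex code.
#' @param disease Disease label.
#' @inheritParams rate_summary
#' @return Data frame with columns `year`, `asr`.
#' @export
asr_series <- function(agg, sex, disease, scheme = age_scheme(),
                       std = world_standard_population()) {
  sub <- agg[agg$sex == sex & agg$disease == disease, ]
  if (nrow(sub) == 0L) {
    stop("no rows for sex ", sex, ", disease '", disease, "'",
         call. = FALSE)
  }
  years <- sort(unique(sub$year))
  asr <- vapply(years, function(y) {
    yr <- sub[sub$year == y, ]
    cases <- py <- numeric(n_groups(scheme))
    cases[yr$age_group] <- yr$cases
    py[yr$age_group] <- yr$person_years
    direct_standardized_rate(cases, py, std)
  }, numeric(1))
  data.frame(year = years, asr = asr)
}
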