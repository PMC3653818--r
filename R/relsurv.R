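# Cohort relative survival: RS(T) = S_o(T) / S_E(T), the Kaplan-Meier
# observed survival of the patient cohort divided by the expected survival
# the cohort would have under general-population mortality. Expected
# survival uses Hakulinen's cohort estimator: each patient contributes the
# life-table annual conditional survival probability matched on sex,
# attained single-year age and calendar year, for as long as the patient is
# *potentially* under follow-up (diagnosis to study end), weighted by the
# patient's cumulative expected survival. Keeping patients lost earlier in
# the expected-survival denominator is what distinguishes Hakulinen's
# method from Ederer II and removes the bias of heterogeneous potential
# follow-up. Confidence intervals transform the Greenwood standard error of
# log S_o(T), treating S_E(T) as a constant.

#' Kaplan-Meier observed survival on an annual grid
#'
#' Product-limit estimate on exact (continuous) follow-up times, evaluated
#' at the requested time points. Patients with status 0 are censored at
#' their end of follow-up.
#'
#' @param follow_up Follow-up times in years (non-negative).
#' @param status Event indicator: 1 = dead, 0 = alive/censored.
#' @param grid Time points in years from diagnosis (default annual 0..max
#'   observed whole year).
#' @return Data frame with columns `time`, `n_risk`, `os` (observed
#'   survival) and `var_log_os` (Greenwood variance of log observed
#'   survival).
#' @export
km_observed <- function(follow_up, status,
                        grid = 0:floor(max(follow_up))) {
  if (length(follow_up) == 0L) stop("empty cohort", call. = FALSE)
  if (any(follow_up < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(status %in% c(0, 1))) {
    stop("status must be coded 0 (alive/censored) or 1 (dead)",
         call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(follow_up, status) ~ 1,
                           conf.type = "none")
  s <- summary(fit, times = grid, extend = TRUE)
  os <- s$surv
  # summary() reports the SE of S; convert to the variance of log S
  var_log <- ifelse(os > 0, (s$std.err / os)^2, Inf)
  data.frame(time = s$time, n_risk = s$n.risk, os = os,
             var_log_os = var_log)
}

# life-table lookup: annual survival probability for (sex, age, year)
# vectors; ages above the table's maximum reuse the last age row (warned);
# any other gap is an error naming the missing cell.
lt_lookup <- function(life_table, sex, age, year) {
  max_age <- max(life_table$age)
  over <- age > max_age
  if (any(over)) {
    warning("attained age(s) beyond the life table's maximum (", max_age,
            "); reusing the last age row", call. = FALSE)
    age[over] <- max_age
  }
  key <- paste(sex, age, year)
  hit <- match(key, paste(life_table$sex, life_table$age, life_table$year))
  if (anyNA(hit)) {
    miss <- key[is.na(hit)][1]
    stop("life table lacks cell (sex, age, year) = (",
         gsub(" ", ", ", miss), ")", call. = FALSE)
  }
  life_table$prob[hit]
}

#' Hakulinen expected survival of a cohort
#'
#' For annual interval j the cohort's conditional expected survival is the
#' weighted mean of the patients' life-table probabilities, over patients
#' still potentially under follow-up at the start of the interval, with the
#' patient's cumulative expected survival as weight; a patient whose
#' potential follow-up ends a fraction f into the interval contributes
#' p^f (constant hazard within the year). The expected survival curve is
#' the cumulative product of these conditional probabilities. Attained age
#' and calendar year advance annually from the values at diagnosis.
#'
#' @param sex,age,year Per patient: sex code, age in years and calendar
#'   year at diagnosis.
#' @param potential_follow_up Per patient: years from diagnosis to the end
#'   of study (not to loss or death).
#' @param life_table A [life_table][read_life_table] object.
#' @param grid Annual time points (must be `0:K`).
#' @return Numeric vector of expected survival at each grid point (`NA`
#'   once no patient is potentially under follow-up).
#' @export
hakulinen_expected <- function(sex, age, year, potential_follow_up,
                               life_table, grid = 0:5) {
  n <- length(sex)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  if (!all(grid == seq_along(grid) - 1)) {
    stop("grid must be the annual sequence 0, 1, ..., K", call. = FALSE)
  }
  if (any(potential_follow_up < 0)) {
    stop("negative potential follow-up", call. = FALSE)
  }
  K <- max(grid)
  es <- numeric(K + 1)
  es[1] <- 1
  cum <- rep(1, n)  # cumulative expected survival per patient
  for (j in seq_len(K)) {
    t0 <- j - 1
    at_risk <- potential_follow_up > t0
    if (!any(at_risk)) {
      es[(j + 1):(K + 1)] <- NA_real_
      break
    }
    p <- lt_lookup(life_table, sex[at_risk], age[at_risk] + t0,
                   year[at_risk] + t0)
    frac <- pmin(1, potential_follow_up[at_risk] - t0)
    w <- cum[at_risk]
    es[j + 1] <- es[j] * sum(w * p^frac) / sum(w)
    cum[at_risk] <- cum[at_risk] * p
  }
  es[grid + 1]
}

#' Relative survival with log-transform confidence interval
#'
#' RS = S_o / S_E; the CI is `exp(log S_o -/+ z * se(log S_o)) / S_E`,
#' treating the expected survival as a constant. RS may exceed 1 and is not
#' clipped; the lower bound is clipped at 0.
#'
#' @param os Observed survival per time point.
#' @param es Expected survival per time point (positive).
#' @param var_log_os Greenwood variance of log observed survival.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `rs`, `ci_low`, `ci_high`.
#' @export
relative_survival <- function(os, es, var_log_os, level = 0.95) {
  if (any(es <= 0, na.rm = TRUE)) {
    stop("expected survival must be positive at every evaluated point",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(var_log_os)
  rs <- os / es
  lo <- ifelse(os > 0, exp(log(os) - z * se) / es, 0)
  hi <- ifelse(os > 0, exp(log(os) + z * se) / es, 0)
  data.frame(rs = rs, ci_low = pmax(0, lo), ci_high = hi)
}

#' Relative-survival curve of a cohort
#'
#' Combines [km_observed()], [hakulinen_expected()] and
#' [relative_survival()] into an annual survival curve.
#'
#' @param records Data frame with per-patient columns `sex`, `age`,
#'   `diagnosis_year`, `follow_up`, `status` (1 = dead); an
#'   `individual_records` object works (its `diagnosis_month` is used for
#'   the potential follow-up when present, otherwise diagnosis is taken at
#'   mid-year).
#' @param life_table A [life_table][read_life_table] object.
#' @param study_end_year Last calendar year of follow-up; potential
#'   follow-up runs to 31 December of this year.
#' @param max_years Largest time point (default 5).
#' @param level Confidence level.
#' @return Object of class `relsurv_curve`: data frame with columns
#'   `n_risk`, `time`, `os`, `es`, `rs`, `ci_low`, `ci_high`.
#' @export
relsurv_curve <- function(records, life_table, study_end_year,
                          max_years = 5, level = 0.95) {
  need <- c("sex", "age", "diagnosis_year", "follow_up", "status")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  month <- if ("diagnosis_month" %in% names(records)) {
    records$diagnosis_month
  } else 6.5
  diag_time <- records$diagnosis_year + (month - 0.5) / 12
  potential <- (study_end_year + 1) - diag_time
  if (any(potential < 0)) {
    stop("diagnosis after the study end year", call. = FALSE)
  }
  grid <- 0:max_years
  km <- km_observed(records$follow_up, records$status, grid)
  es <- hakulinen_expected(records$sex, records$age,
                           records$diagnosis_year, potential,
                           life_table, grid)
  rs <- relative_survival(km$os, es, km$var_log_os, level)
  out <- data.frame(n_risk = km$n_risk, time = km$time, os = km$os,
                    es = es, rs = rs$rs, ci_low = rs$ci_low,
                    ci_high = rs$ci_high)
  class(out) <- c("relsurv_curve", "data.frame")
  out
}

#' @export
print.relsurv_curve <- function(x, ...) {
  cat("Relative survival (observed / Hakulinen expected):\n")
  print(report_table(x), row.names = FALSE, ...)
  invisible(x)
}

#' Annual relative-survival report table
#'
#' One row per annual time point with columns `Risk` (number at risk),
#' `T`, `RS`, `LCI`, `UCI`, `OS`, survival values rounded to 3 decimals.
#'
#' @param curve A `relsurv_curve`.
#' @param path Optional output file; when given, the table is written as
#'   delimited text.
#' @param delimiter Field delimiter for `path`.
#' @return The report data frame, invisibly when written to `path`.
#' @export
report_table <- function(curve, path = NULL, delimiter = ",") {
  out <- data.frame(Risk = curve$n_risk, T = curve$time,
                    RS = round(curve$rs, 3),
                    LCI = round(curve$ci_low, 3),
                    UCI = round(curve$ci_high, 3),
                    OS = round(curve$os, 3))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE)
    return(invisible(out))
  }
  out
}
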