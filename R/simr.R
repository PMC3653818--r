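# Standardized incidence/mortality ratio: observed events in a target
# population divided by the events expected if the reference population's
# age-specific rates applied to the target's person-years. The expected
# count is treated as a known constant (classical SIR convention), so the
# confidence interval comes from the Poisson distribution of the observed
# count alone.

#' Expected events under reference rates
#'
#' E = sum over age groups of (reference rate_i) x (target person-years_i).
#' Every target age group with positive person-years must have a reference
#' rate (reference person-years > 0).
#'
#' @param ref_cases,ref_person_years Reference case counts and person-years
#'   per age group.
#' @param target_person_years Target person-years per age group (same
#'   scheme and ordering as the reference).
#' @return The expected number of events E.
#' @export
expected_events <- function(ref_cases, ref_person_years,
                            target_person_years) {
  k <- length(ref_cases)
  if (length(ref_person_years) != k || length(target_person_years) != k) {
    stop("reference and target must share one age-group scheme",
         call. = FALSE)
  }
  need <- target_person_years > 0
  uncovered <- need & (is.na(ref_person_years) | ref_person_years <= 0)
  if (any(uncovered)) {
    stop("no reference rate for age group(s) ",
         paste(which(uncovered), collapse = ", "), call. = FALSE)
  }
  sum(ifelse(need, ref_cases / ref_person_years * target_person_years, 0))
}

#' Standardized incidence/mortality ratio with confidence interval
#'
#' SIMR = D / E for D observed and E expected events. The default interval
#' is the exact Poisson interval obtained by gamma (chi-square) inversion:
#' lower = qgamma(a/2, D) / E (0 when D = 0), upper = qgamma(1 - a/2,
#' D + 1) / E. Byar's approximation is available for cross-checking. The
#' ratio is significant when 1 lies outside the interval.
#'
#' @param D Observed number of events (non-negative integer).
#' @param E Expected number of events (positive).
#' @param level Confidence level (default 0.95).
#' @param ci_method `"exact"` (default) or `"byar"`.
#' @return Object of class `simr` with `observed`, `expected`, `simr`,
#'   `ci_low`, `ci_high`, `significant`, `level`, `ci_method`.
#' @examples
#' simr_with_ci(117, 100)
#' @export
simr_with_ci <- function(D, E, level = 0.95,
                         ci_method = c("exact", "byar")) {
  ci_method <- match.arg(ci_method)
  if (E <= 0) stop("expected events must be positive", call. = FALSE)
  if (D < 0 || D != round(D)) {
    stop("observed events must be a non-negative integer", call. = FALSE)
  }
  a <- 1 - level
  if (ci_method == "exact") {
    lo <- if (D == 0) 0 else stats::qgamma(a / 2, D) / E
    hi <- stats::qgamma(1 - a / 2, D + 1) / E
  } else {
    # Byar's approximation to the Poisson tail
    z <- stats::qnorm(1 - a / 2)
    lo <- if (D == 0) 0 else (D * (1 - 1 / (9 * D) - z / (3 * sqrt(D)))^3) / E
    hi <- ((D + 1) * (1 - 1 / (9 * (D + 1)) + z / (3 * sqrt(D + 1)))^3) / E
  }
  out <- list(observed = as.integer(D), expected = E, simr = D / E,
              ci_low = lo, ci_high = hi,
              significant = (1 < lo) || (1 > hi),
              level = level, ci_method = ci_method)
  class(out) <- "simr"
  out
}

#' @export
print.simr <- function(x, ...) {
  cat(sprintf(
    "SIMR = %.2f (%.0f%% CI: %.2f, %.2f), D = %d observed, E = %.1f expected\n",
    x$simr, 100 * x$level, x$ci_low, x$ci_high, x$observed, x$expected))
  cat(if (x$significant) {
    if (x$simr > 1) "  significant excess risk vs the reference\n"
    else "  significant risk reduction vs the reference\n"
  } else "  not statistically significant (CI includes 1)\n")
  invisible(x)
}

#' SIMR between two aggregated tables, by sex and disease
#'
#' For each sex x disease stratum present in both tables, pools years
#' within each table, computes the expected count by applying the
#' reference's age-specific rates to the target's person-years, and the
#' SIMR of the target's observed count.
#'
#' @param reference,target `aggregated_counts` tables on the same age-group
#'   scheme.
#' @param n_age_groups Number of age groups in the scheme (default 18).
#' @param ... Passed to [simr_with_ci()].
#' @return Data frame, one row per sex x disease, with observed, expected,
#'   SIMR and CI columns.
#' @export
simr_summary <- function(reference, target, n_age_groups = 18, ...) {
  strata <- unique(target[c("sex", "disease")])
  pool <- function(agg, s, d) {
    sub <- agg[agg$sex == s & agg$disease == d, ]
    list(cases = vapply(seq_len(n_age_groups), function(g)
           sum(sub$cases[sub$age_group == g]), numeric(1)),
         py = vapply(seq_len(n_age_groups), function(g)
           sum(sub$person_years[sub$age_group == g]), numeric(1)))
  }
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    s <- strata$sex[i]; d <- strata$disease[i]
    ref <- pool(reference, s, d)
    tar <- pool(target, s, d)
    E <- expected_events(ref$cases, ref$py, tar$py)
    r <- simr_with_ci(sum(tar$cases), E, ...)
    data.frame(sex = s, disease = d, observed = r$observed,
               expected = r$expected, simr = r$simr, ci_low = r$ci_low,
               ci_high = r$ci_high, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
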