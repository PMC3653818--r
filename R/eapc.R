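# Estimated annual percent change (EAPC) of an age-standardized rate
# series. The rate is assumed to change by a constant percentage per year,
# i.e. log(ASR_T) = alpha + beta * T with Gaussian error, fitted by
# ordinary least squares; EAPC = (exp(beta) - 1) * 100 and its confidence
# interval is the same transform of the interval for beta.

#' Fit the estimated annual percent change of a rate series
#'
#' Ordinary least squares of `log(asr)` on calendar year. The confidence
#' interval for the slope uses the t distribution with n - 2 degrees of
#' freedom by default (normal quantiles optionally), and is transformed to
#' the percent scale.
#'
#' @param year Calendar years (at least 3 distinct).
#' @param asr Age-standardized rates, strictly positive.
#' @param level Confidence level (default 0.95).
#' @param ci_quantile `"t"` (default) or `"normal"`.
#' @param drop_zero_years If `TRUE`, years with `asr <= 0` are dropped with
#'   a warning instead of raising an error.
#' @return Object of class `eapc_fit` with components `beta`, `se_beta`,
#'   `eapc_pct`, `ci_low_pct`, `ci_high_pct`, `level`, `n_years`, `trend`
#'   and the underlying `lm` fit.
#' @examples
#' fit_eapc(2000:2009, 100 * 1.05^(0:9))  # exactly +5% per year
#' @export
fit_eapc <- function(year, asr, level = 0.95,
                     ci_quantile = c("t", "normal"),
                     drop_zero_years = FALSE) {
  ci_quantile <- match.arg(ci_quantile)
  if (length(year) != length(asr)) {
    stop("'year' and 'asr' must have the same length", call. = FALSE)
  }
  bad <- asr <= 0 | is.na(asr)
  if (any(bad)) {
    if (!drop_zero_years) {
      stop("non-positive rate in year(s) ",
           paste(year[bad], collapse = ", "),
           "; the log-linear trend model is undefined there ",
           "(use drop_zero_years = TRUE to exclude them)", call. = FALSE)
    }
    warning("dropping ", sum(bad), " year(s) with non-positive rates",
            call. = FALSE)
    year <- year[!bad]; asr <- asr[!bad]
  }
  if (length(unique(year)) < 3L) {
    stop("at least 3 years with positive rates are required", call. = FALSE)
  }
  fit <- stats::lm(log(asr) ~ year)
  beta <- unname(stats::coef(fit)[2])
  # residual-variance route (avoids summary.lm noise on exact fits)
  sigma2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  se <- sqrt(sigma2 / sum((year - mean(year))^2))
  q <- if (ci_quantile == "t") {
    stats::qt(1 - (1 - level) / 2, df = fit$df.residual)
  } else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  ci <- beta + c(-1, 1) * q * se
  out <- list(beta = beta, se_beta = se,
              eapc_pct = 100 * (exp(beta) - 1),
              ci_low_pct = 100 * (exp(ci[1]) - 1),
              ci_high_pct = 100 * (exp(ci[2]) - 1),
              level = level, n_years = length(year),
              years = range(year), lm_fit = fit)
  out$trend <- interpret_eapc(out)
  class(out) <- "eapc_fit"
  out
}

#' Classify a trend from its EAPC confidence interval
#'
#' `"stable"` when the interval contains 0 (the change is not statistically
#' significant), `"increasing"` when the lower bound is above 0,
#' `"decreasing"` when the upper bound is below 0.
#'
#' @param x An `eapc_fit`, or a list with `ci_low_pct` and `ci_high_pct`.
#' @return One of `"increasing"`, `"decreasing"`, `"stable"`.
#' @export
interpret_eapc <- function(x) {
  if (x$ci_low_pct > 0) "increasing"
  else if (x$ci_high_pct < 0) "decreasing"
  else "stable"
}

#' @export
print.eapc_fit <- function(x, ...) {
  cat(sprintf(
    "EAPC = %.2f%% (%.0f%% CI: %.2f, %.2f), %d years %d-%d: %s trend\n",
    x$eapc_pct, 100 * x$level, x$ci_low_pct, x$ci_high_pct,
    x$n_years, x$years[1], x$years[2], x$trend))
  invisible(x)
}

#' @export
summary.eapc_fit <- function(object, ...) {
  print(object)
  cat(sprintf("log-linear slope beta = %.5f (se %.5f)\n",
              object$beta, object$se_beta))
  invisible(object)
}

#' @export
coef.eapc_fit <- function(object, ...) {
  c(beta = object$beta, eapc_pct = object$eapc_pct)
}

#' @export
confint.eapc_fit <- function(object, parm = "eapc_pct", level = NULL, ...) {
  c(low = object$ci_low_pct, high = object$ci_high_pct)
}

#' EAPC for every sex x disease stratum of an aggregated table
#'
#' Builds the annual ASR series per stratum with [asr_series()] and fits
#' [fit_eapc()] to each.
#'
#' @inheritParams rate_summary
#' @param ... Passed on to [fit_eapc()].
#' @return Data frame with one row per sex x disease: `eapc_pct`, CI
#'   bounds, `trend`, `n_years`.
#' @export
eapc_summary <- function(agg, scheme = age_scheme(),
                         std = world_standard_population(), ...) {
  strata <- unique(agg[c("sex", "disease")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    ser <- asr_series(agg, strata$sex[i], strata$disease[i], scheme, std)
    f <- fit_eapc(ser$year, ser$asr, ...)
    data.frame(sex = strata$sex[i], disease = strata$disease[i],
               eapc_pct = f$eapc_pct, ci_low_pct = f$ci_low_pct,
               ci_high_pct = f$ci_high_pct, trend = f$trend,
               n_years = f$n_years, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
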