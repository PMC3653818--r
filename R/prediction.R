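# Projection of future case counts from log-linear count models of
# age-specific rates: log(C_iT / Y_iT) = alpha_i + beta_i (T - T0)
# (age-specific slopes) or a common slope beta (the age-drift model),
# under Poisson or negative-binomial error, with log person-years as the
# exposure offset. Four candidate models (2 families x 2 slope types) are
# compared by AIC, with a Pearson chi-square goodness-of-fit diagnostic.

#' Fit a log-linear count model to an age x year table
#'
#' @param counts Aggregated counts for one sex x disease stratum: a data
#'   frame with columns `age_group`, `year`, `cases`, `person_years`
#'   (an `aggregated_counts` table restricted to one stratum works).
#' @param family `"poisson"` or `"negative_binomial"`.
#' @param slope_type `"drift"` (common slope) or `"age_specific"`.
#' @param t0 Reference year; `alpha_i` is the log-rate at `t0`. Defaults to
#'   the last observed year.
#' @return Object of class `count_model_fit`: coefficients `alpha` (log
#'   rate at `t0` per age group) and `beta` (scalar for drift, per-group
#'   vector otherwise), `dispersion` (NB shape, `NULL` for Poisson), `aic`,
#'   Pearson `gof_chi2` / `gof_df` / `gof_p`, the age groups used and those
#'   dropped for having zero cases in every year, and the underlying glm.
#' @details Age groups with zero cases in all years cannot be represented
#'   on the log scale; they are excluded from fitting, recorded in
#'   `dropped_groups`, and predicted as zero. The goodness-of-fit degrees
#'   of freedom are the number of fitted cells minus the number of mean
#'   parameters.
#' @export
fit_count_model <- function(counts,
                            family = c("poisson", "negative_binomial"),
                            slope_type = c("drift", "age_specific"),
                            t0 = NULL) {
  family <- match.arg(family)
  slope_type <- match.arg(slope_type)
  d <- as.data.frame(counts)[c("age_group", "year", "cases", "person_years")]
  if (length(unique(d$year)) < 2L) {
    stop("at least 2 distinct years are required", call. = FALSE)
  }
  if (any(d$person_years <= 0)) {
    stop("person-years must be positive in every cell", call. = FALSE)
  }
  if (is.null(t0)) t0 <- max(d$year)

  tot <- tapply(d$cases, d$age_group, sum)
  dropped <- as.integer(names(tot)[tot == 0])
  d <- d[!(d$age_group %in% dropped), , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("all age groups have zero cases; nothing to fit", call. = FALSE)
  }
  d$age_f <- factor(d$age_group)
  d$tt <- d$year - t0
  one_group <- nlevels(d$age_f) == 1L
  form <- if (one_group) {
    cases ~ tt + offset(log(person_years))
  } else if (slope_type == "drift") {
    cases ~ 0 + age_f + tt + offset(log(person_years))
  } else {
    cases ~ 0 + age_f + age_f:tt + offset(log(person_years))
  }

  fit <- tryCatch({
    if (family == "poisson") {
      stats::glm(form, family = stats::poisson(), data = d)
    } else {
      suppressWarnings(MASS::glm.nb(form, data = d))
    }
  }, error = function(e) {
    stop("count-model fit failed (", family, ", ", slope_type, "): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!isTRUE(fit$converged)) {
    stop("count-model fit did not converge (", family, ", ", slope_type,
         ")", call. = FALSE)
  }

  groups <- sort(unique(d$age_group))
  cf <- stats::coef(fit)
  if (one_group) {
    alpha <- unname(cf["(Intercept)"])
    beta <- unname(cf["tt"])
  } else {
    alpha <- unname(cf[paste0("age_f", groups)])
    beta <- if (slope_type == "drift") {
      unname(cf["tt"])
    } else {
      unname(cf[paste0("age_f", groups, ":tt")])
    }
  }
  n_par <- length(cf)
  gof_chi2 <- sum(stats::residuals(fit, type = "pearson")^2)
  gof_df <- nrow(d) - n_par
  out <- list(family = family, slope_type = slope_type, t0 = t0,
              age_groups = groups, dropped_groups = dropped,
              alpha = alpha, beta = beta,
              dispersion = if (family == "negative_binomial") fit$theta,
              aic = stats::AIC(fit), n_parameters = n_par,
              gof_chi2 = gof_chi2, gof_df = gof_df,
              gof_p = if (gof_df > 0) {
                stats::pchisq(gof_chi2, gof_df, lower.tail = FALSE)
              } else NA_real_,
              glm_fit = fit, n_cells = nrow(d))
  class(out) <- "count_model_fit"
  out
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat(sprintf("Log-linear count model: %s, %s slope (T0 = %d)\n",
              x$family, x$slope_type, as.integer(x$t0)))
  if (x$slope_type == "drift") {
    cat(sprintf("  drift beta = %.5f (annual rate change %.2f%%)\n",
                x$beta, 100 * (exp(x$beta) - 1)))
  } else {
    cat(sprintf("  age-specific slopes in [%.4f, %.4f]\n",
                min(x$beta), max(x$beta)))
  }
  if (!is.null(x$dispersion)) {
    cat(sprintf("  NB dispersion (theta) = %.3f\n", x$dispersion))
  }
  cat(sprintf("  AIC = %.2f; Pearson X2 = %.2f on %d df (p = %.3g)\n",
              x$aic, x$gof_chi2, x$gof_df, x$gof_p))
  if (length(x$dropped_groups) > 0L) {
    cat("  age groups with no cases, predicted as zero:",
        paste(x$dropped_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit all four candidate count models
#'
#' Poisson and negative binomial, each with drift and age-specific slopes.
#' Candidates that fail to fit are recorded as `NULL` with the error
#' message in `attr(, "failures")`.
#'
#' @inheritParams fit_count_model
#' @return Named list of `count_model_fit` (or `NULL`) with names
#'   `poisson_drift`, `poisson_age_specific`, `negative_binomial_drift`,
#'   `negative_binomial_age_specific`.
#' @export
fit_count_models <- function(counts, t0 = NULL) {
  grid <- expand.grid(family = c("poisson", "negative_binomial"),
                      slope_type = c("drift", "age_specific"),
                      stringsAsFactors = FALSE)
  failures <- character(0)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch(fit_count_model(counts, grid$family[i], grid$slope_type[i], t0),
             error = function(e) {
               failures[[paste(grid$family[i], grid$slope_type[i],
                               sep = "_")]] <<- conditionMessage(e)
               NULL
             })
  })
  names(fits) <- paste(grid$family, grid$slope_type, sep = "_")
  attr(fits, "failures") <- failures
  fits
}

#' Select the best-fitting count model by AIC
#'
#' Minimum AIC wins; exact ties are broken toward fewer parameters (drift
#' over age-specific, then Poisson over negative binomial). The Pearson
#' goodness-of-fit p-value is reported alongside, with a warning when the
#' selected model fails the fit test at the 0.05 level; it does not veto
#' the AIC choice.
#'
#' @param fits List of candidate `count_model_fit` objects (failures as
#'   `NULL`), e.g. from [fit_count_models()].
#' @return The selected `count_model_fit`, with a `selection` attribute
#'   holding the comparison table (family, slope type, parameters, AIC,
#'   GOF p).
#' @export
select_model <- function(fits) {
  valid <- Filter(function(f) inherits(f, "count_model_fit"), fits)
  if (length(valid) == 0L) {
    stop("no candidate count model could be fitted", call. = FALSE)
  }
  tab <- data.frame(
    family = vapply(valid, `[[`, "", "family"),
    slope_type = vapply(valid, `[[`, "", "slope_type"),
    n_parameters = vapply(valid, `[[`, 0, "n_parameters"),
    aic = vapply(valid, `[[`, 0, "aic"),
    gof_p = vapply(valid, `[[`, 0, "gof_p"),
    stringsAsFactors = FALSE)
  fam_rank <- ifelse(tab$family == "poisson", 0L, 1L)
  near_min <- tab$aic <= min(tab$aic) + 1e-8
  ord <- order(!near_min, tab$n_parameters, fam_rank, tab$aic)
  best <- valid[[ord[1]]]
  if (!is.na(best$gof_p) && best$gof_p < 0.05) {
    warning("selected model (", best$family, ", ", best$slope_type,
            ") fails the Pearson goodness-of-fit test (p = ",
            signif(best$gof_p, 3), ")", call. = FALSE)
  }
  attr(best, "selection") <- tab[order(tab$aic), ]
  best
}

#' Predict expected cases at a future year
#'
#' Applies the fitted rate model at calendar year `future_year` to future
#' person-years: the expectation in age group i is
#' `Y_iF * exp(alpha_i + beta_i * (F - T0))`. Age groups dropped at fitting
#' (no cases observed) are predicted as zero.
#'
#' @param fit A `count_model_fit`.
#' @param future_year Calendar year F of the projection.
#' @param future_person_years Person-years at F, one entry per age group of
#'   the full scheme (indexed 1..k); must cover all fitted age groups.
#' @param std Standard-population weights for the projected ASR; the Segi
#'   world standard when the scheme has 18 groups, otherwise `NULL`, which
#'   skips the ASR.
#' @return Object of class `case_projection`: `expected_by_age`,
#'   `expected_total`, `projected_asr`, `future_year` and the model used.
#' @export
predict_cases <- function(fit, future_year, future_person_years,
                          std = if (length(future_person_years) == 18)
                            world_standard_population()) {
  k <- length(future_person_years)
  if (max(fit$age_groups) > k ||
      any(future_person_years[fit$age_groups] <= 0) ||
      anyNA(future_person_years[fit$age_groups])) {
    stop("future person-years must be positive for every fitted age group",
         call. = FALSE)
  }
  beta <- if (fit$slope_type == "drift") {
    rep(fit$beta, length(fit$age_groups))
  } else {
    fit$beta
  }
  expected <- numeric(k)
  expected[fit$age_groups] <- future_person_years[fit$age_groups] *
    exp(fit$alpha + beta * (future_year - fit$t0))
  out <- list(model = fit, future_year = future_year,
              expected_by_age = expected,
              expected_total = sum(expected),
              projected_asr = if (!is.null(std)) {
                direct_standardized_rate(expected, future_person_years, std)
              } else NA_real_)
  class(out) <- "case_projection"
  out
}

#' @export
print.case_projection <- function(x, ...) {
  cat(sprintf(
    "Projected cases for %d: %.1f total (ASR %.2f per 100,000)\n",
    as.integer(x$future_year), x$expected_total, x$projected_asr))
  cat(sprintf("  model: %s, %s slope\n", x$model$family,
              x$model$slope_type))
  invisible(x)
}
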