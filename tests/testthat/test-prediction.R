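# helper: age x year table from a drift model with known parameters
drift_table <- function(alpha, beta, years, py = 50000, t0 = max(years),
                        noise = TRUE) {
  k <- length(alpha)
  d <- expand.grid(age_group = seq_len(k), year = years,
                   KEEP.OUT.ATTRS = FALSE)
  d$person_years <- py
  mu <- py * exp(alpha[d$age_group] + beta * (d$year - t0))
  d$cases <- if (noise) rpois(nrow(d), mu) else mu
  d
}

test_that("noiseless data reproduce their generating parameters", {
  alpha <- log(c(2e-5, 8e-5, 3e-4))
  d <- drift_table(alpha, beta = 0.02, years = 2000:2009, noise = FALSE)
  f <- suppressWarnings(fit_count_model(d, "poisson", "drift",
                                        t0 = 2009))
  expect_equal(f$beta, 0.02, tolerance = 1e-6)
  expect_equal(f$alpha, alpha, tolerance = 1e-6)
})

test_that("saturated two-point fit has the closed-form slope", {
  d <- data.frame(age_group = 1, year = c(2000, 2001), cases = c(10, 20),
                  person_years = 1000)
  f <- fit_count_model(d, "poisson", "drift", t0 = 2000)
  expect_equal(f$beta, log(2), tolerance = 1e-9)
  expect_equal(f$alpha, log(10 / 1000), tolerance = 1e-9)
  expect_equal(f$gof_chi2, 0, tolerance = 1e-9)
})

test_that("Poisson simulation recovers the drift slope", {
  set.seed(99)
  alpha <- log(seq(2e-5, 3e-4, length.out = 18))
  d <- drift_table(alpha, beta = 0.02, years = 2000:2009)
  f <- fit_count_model(d, "poisson", "drift", t0 = 2009)
  se <- sqrt(stats::vcov(f$glm_fit)["tt", "tt"])
  expect_lt(abs(f$beta - 0.02), 3 * se)
})

test_that("all-zero age rows are dropped and predicted as zero", {
  set.seed(4)
  alpha <- log(c(1e-4, 2e-4))
  d <- drift_table(alpha, 0.01, 2000:2005)
  d$cases[d$age_group == 1] <- 0
  f <- fit_count_model(d, "poisson", "drift")
  expect_equal(f$dropped_groups, 1L)
  p <- predict_cases(f, 2010, rep(5e4, 2))
  expect_equal(p$expected_by_age[1], 0)
  expect_gt(p$expected_by_age[2], 0)
})

test_that("AIC selection breaks exact ties toward the simpler model", {
  # single age group: drift and age-specific are the same model, equal AIC
  set.seed(12)
  d <- drift_table(log(1e-4), 0.02, 2000:2007)
  best <- select_model(fit_count_models(d))
  expect_equal(best$slope_type, "drift")
  expect_equal(best$family, "poisson")
})

test_that("selection ignores failed candidates and reports the table", {
  set.seed(13)
  d <- drift_table(log(c(1e-4, 2e-4)), 0.01, 2000:2008)
  fits <- fit_count_models(d)
  fits$poisson_drift <- NULL  # as if this candidate had failed
  best <- select_model(fits)
  expect_s3_class(best, "count_model_fit")
  tab <- attr(best, "selection")
  expect_equal(nrow(tab), 3L)
  expect_equal(best$aic, min(tab$aic))
  expect_error(select_model(list(NULL, NULL)), "no candidate")
})

test_that("NB AIC never beats Poisson by more than its extra parameter", {
  set.seed(14)
  for (i in 1:10) {
    d <- drift_table(log(runif(5, 5e-5, 4e-4)), 0.015, 2000:2009)
    pois <- fit_count_model(d, "poisson", "drift")
    nb <- tryCatch(fit_count_model(d, "negative_binomial", "drift"),
                   error = function(e) NULL)
    if (!is.null(nb)) expect_gt(nb$aic, pois$aic - 2 - 1e-6)
  }
})

test_that("overdispersed counts raise the NB dispersion diagnostic", {
  set.seed(15)
  k <- 6
  d <- expand.grid(age_group = 1:k, year = 2000:2009,
                   KEEP.OUT.ATTRS = FALSE)
  d$person_years <- 5e4
  mu <- 5e4 * exp(log(2e-4) + 0.01 * (d$year - 2009))
  d$cases <- rnbinom(nrow(d), size = 2, mu = mu)  # strong overdispersion
  best <- suppressWarnings(select_model(fit_count_models(d)))
  expect_equal(best$family, "negative_binomial")
  expect_false(is.null(best$dispersion))
})

test_that("predictions satisfy the reference-year and exposure identities", {
  set.seed(16)
  alpha <- log(seq(5e-5, 3e-4, length.out = 6))
  d <- drift_table(alpha, 0.02, 2000:2009, py = 4e4)
  f <- fit_count_model(d, "poisson", "drift", t0 = 2009)
  py <- rep(4e4, 6)
  # F = T0 with unchanged population reproduces fitted values at T0
  p0 <- predict_cases(f, 2009, py)
  fitted_t0 <- py * exp(f$alpha)
  expect_equal(p0$expected_by_age, fitted_t0, tolerance = 1e-10)
  # doubling exposure doubles cells and total, ASR unchanged
  p1 <- predict_cases(f, 2012, py, std = rep(1, 6))
  p2 <- predict_cases(f, 2012, 2 * py, std = rep(1, 6))
  expect_equal(p2$expected_by_age, 2 * p1$expected_by_age)
  expect_equal(p2$expected_total, 2 * p1$expected_total)
  expect_equal(p2$projected_asr, p1$projected_asr, tolerance = 1e-12)
  # drift beta = log(1.01): one-year horizon grows the total by 1.01
  g <- f
  g$beta <- log(1.01)
  q1 <- predict_cases(g, 2009, py)
  q2 <- predict_cases(g, 2010, py)
  expect_equal(q2$expected_total / q1$expected_total, 1.01,
               tolerance = 1e-12)
  # missing future age group is a coverage error
  expect_error(predict_cases(f, 2012, c(py[-6], 0)), "positive")
})

test_that("model fitting demands two years and positive exposure", {
  d <- data.frame(age_group = 1, year = 2000, cases = 5,
                  person_years = 1000)
  expect_error(fit_count_model(d), "2 distinct years")
  d2 <- data.frame(age_group = 1, year = c(2000, 2001), cases = c(5, 6),
                   person_years = c(1000, 0))
  expect_error(fit_count_model(d2), "positive")
})
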