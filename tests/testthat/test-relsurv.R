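test_that("Kaplan-Meier matches hand product-limit values", {
  # deaths at 1 and 2 years, censorings at 1.5 and 3
  km <- km_observed(c(1, 1.5, 2, 3), c(1, 0, 1, 0), grid = 0:3)
  expect_equal(km$os[km$time == 2], (3 / 4) * (1 / 2))
  expect_equal(km$os[km$time == 0], 1)
  # Greenwood variance of log S at t = 2: 1/(4*3) + 1/(2*1)
  expect_equal(km$var_log_os[km$time == 2], 1 / 12 + 1 / 2)

  none_dead <- km_observed(rep(6, 10), rep(0, 10), grid = 0:5)
  expect_equal(none_dead$os, rep(1, 6))

  single <- km_observed(0.5, 1, grid = 0:2)
  expect_equal(single$os, c(1, 0, 0))
  expect_error(km_observed(numeric(0), numeric(0), 0:2), "empty")
})

test_that("a unit life table makes relative equal observed survival", {
  set.seed(81)
  n <- 60
  fu <- rexp(n, 0.3); status <- as.integer(fu < 8); fu <- pmin(fu, 8)
  rec <- data.frame(sex = rep(1:2, length.out = n),
                    age = sample(50:70, n, TRUE),
                    diagnosis_year = sample(1995:1999, n, TRUE),
                    follow_up = fu, status = status)
  cv <- relsurv_curve(rec, flat_life_table(1), study_end_year = 2007,
                      max_years = 5)
  expect_equal(cv$es, rep(1, 6))
  expect_equal(cv$rs, cv$os)
})

test_that("homogeneous full-follow-up cohort gives the annual product", {
  lt <- flat_life_table(0.9, sexes = 1, ages = 0:109, years = 1990:2020)
  es <- hakulinen_expected(rep(1, 25), rep(60, 25), rep(1995, 25),
                           rep(10, 25), lt, grid = 0:5)
  expect_equal(es, 0.9^(0:5), tolerance = 1e-12)
})

test_that("two full-follow-up strata mix by person weight", {
  # stratum A: p = 0.95; stratum B: p = 0.80 (different attained ages)
  lt <- expand.grid(sex = 1, age = 0:109, year = 1990:2020,
                    KEEP.OUT.ATTRS = FALSE)
  lt$prob <- ifelse(lt$age < 70, 0.95, 0.80)
  lt <- as_life_table(lt)
  nA <- 30; nB <- 10
  es <- hakulinen_expected(rep(1, nA + nB),
                           c(rep(50, nA), rep(80, nB)),
                           rep(1995, nA + nB), rep(10, nA + nB),
                           lt, grid = 0:5)
  mix <- (nA * 0.95^(0:5) + nB * 0.80^(0:5)) / (nA + nB)
  expect_equal(es, mix, tolerance = 1e-12)
})

test_that("patients out of potential follow-up leave the expected side", {
  lt <- flat_life_table(0.9, sexes = 1)
  # one patient potentially followed 1.5 years, one for 5
  es <- hakulinen_expected(c(1, 1), c(60, 60), c(2000, 2000),
                           c(1.5, 5), lt, grid = 0:3)
  expect_equal(es[2], 0.9)            # both contribute in year 1
  # year 2: patient 1 contributes p^0.5 with weight 0.9, then drops out
  p2 <- (0.9 * 0.9^0.5 + 0.9 * 0.9) / (0.9 + 0.9)
  expect_equal(es[3], 0.9 * p2, tolerance = 1e-12)
  expect_equal(es[4], 0.9 * p2 * 0.9, tolerance = 1e-12)
})

test_that("life-table gaps are named; old ages reuse the last row", {
  lt <- flat_life_table(0.9, sexes = 1, ages = 0:99, years = 1995:2000)
  expect_error(
    hakulinen_expected(1, 60, 2000, 5, lt, 0:3),
    "2001")
  expect_warning(
    es <- hakulinen_expected(1, 98, 1995, 5, lt, 0:3),
    "last age row")
  expect_equal(es, 0.9^(0:3), tolerance = 1e-12)
})

test_that("relative survival transforms the observed-survival interval", {
  expect_equal(relative_survival(0.5, 0.5, 0.01)$rs, 1)
  # inverted published-style row: os = 0.282, rs = 0.292
  es <- 0.282 / 0.292
  expect_equal(relative_survival(0.282, es, 0.001)$rs, 0.292,
               tolerance = 1e-12)
  # degenerate variance collapses the interval onto the estimate
  r0 <- relative_survival(0.4, 0.8, 0)
  expect_equal(r0$ci_low, r0$rs)
  expect_equal(r0$ci_high, r0$rs)
  # rs may exceed 1 and is not clipped
  expect_gt(relative_survival(0.99, 0.9, 0.01)$rs, 1)
  expect_error(relative_survival(0.5, 0, 0.01), "positive")
})

test_that("report table has the annual layout, 3-decimal values", {
  set.seed(82)
  rec <- data.frame(sex = 1, age = 60, diagnosis_year = 1995,
                    follow_up = c(1, 1.5, 2, 3), status = c(1, 0, 1, 0))
  cv <- relsurv_curve(rec, flat_life_table(1), study_end_year = 1999,
                      max_years = 3)
  tab <- report_table(cv)
  expect_equal(names(tab), c("Risk", "T", "RS", "LCI", "UCI", "OS"))
  expect_equal(tab$OS, c(1, 0.75, 0.375, 0.375))  # hand product-limit
  expect_equal(tab$T, 0:3)
  f <- tempfile(fileext = ".csv")
  report_table(cv, f)
  expect_equal(read.csv(f)$RS, tab$RS)
  # empty curve -> header-only table
  empty <- cv[0, ]
  expect_equal(nrow(report_table(empty)), 0L)
})

test_that("zero excess hazard recovers relative survival of 1", {
  set.seed(83)
  n_rep <- 60
  rs5 <- numeric(n_rep)
  lt <- flat_life_table(0.95)
  h <- -log(0.95)
  for (i in seq_len(n_rep)) {
    n <- 150
    diag_year <- sample(1995:1999, n, TRUE)
    death <- rexp(n, h)                 # background hazard only
    censor <- 2008 - (diag_year + 0.5)
    rec <- data.frame(sex = rep(1:2, length.out = n),
                      age = sample(40:75, n, TRUE),
                      diagnosis_year = diag_year,
                      follow_up = pmin(death, censor),
                      status = as.integer(death <= censor))
    cv <- relsurv_curve(rec, lt, study_end_year = 2007, max_years = 5)
    rs5[i] <- cv$rs[cv$time == 5]
  }
  mc_se <- sd(rs5) / sqrt(n_rep)
  expect_lt(abs(mean(rs5) - 1), 4 * mc_se)
})
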