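test_that("crude rate is 100000 X / N", {
  expect_equal(crude_rate(0, 50000), 0)
  expect_equal(crude_rate(50, 100000), 50)
  expect_equal(crude_rate(123, 456789), 1e5 * 123 / 456789)
  expect_error(crude_rate(1, 0), "positive")
  expect_error(crude_rate(-1, 100), "non-negative")
})

test_that("standardized rate honours degenerate and constant cases", {
  py <- c(1000, 2000, 3000)
  cases <- c(5, 10, 30)
  r <- 1e5 * cases / py
  # all weight on one group -> that group's rate
  expect_equal(direct_standardized_rate(cases, py, c(0, 1, 0)), r[2])
  # equal rates -> ASR equals that rate for any weights
  expect_equal(direct_standardized_rate(c(10, 20, 30),
                                        c(1000, 2000, 3000),
                                        c(3, 1, 7)), 1000)
  # hand-weighted mean: rates (10, 20, 30), weights (1, 2, 1) -> 20
  expect_equal(direct_standardized_rate(c(10, 20, 30), rep(1e5, 3),
                                        c(1, 2, 1)), 20)
})

test_that("ASR equals an independent brute-force weighted mean", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(3:18, 1)
    cases <- rpois(k, 20)
    py <- runif(k, 100, 1e5)
    w <- runif(k, 0.1, 10)
    # brute force: loop accumulation
    num <- den <- 0
    for (j in seq_len(k)) {
      num <- num + w[j] * 1e5 * cases[j] / py[j]
      den <- den + w[j]
    }
    expect_equal(direct_standardized_rate(cases, py, w), num / den,
                 tolerance = 1e-12)
    # invariance to rescaling the standard
    expect_equal(direct_standardized_rate(cases, py, w * 17.3),
                 direct_standardized_rate(cases, py, w),
                 tolerance = 1e-12)
  }
})

test_that("crude rate equals ASR when weights match own person-years", {
  set.seed(7)
  cases <- rpois(10, 15); py <- runif(10, 1000, 50000)
  expect_equal(direct_standardized_rate(cases, py, py),
               crude_rate(sum(cases), sum(py)))
})

test_that("zero person-years under positive weight is a coverage error", {
  expect_error(direct_standardized_rate(c(1, 1), c(1000, 0), c(1, 1)),
               "no person-years")
  # zero weight and zero person-years is skipped, not an error
  expect_equal(direct_standardized_rate(c(1, 0), c(1000, 0), c(1, 0)),
               100)
})

test_that("truncated rate restricts to aligned groups", {
  scheme <- age_scheme(c(0, 35, 50, 65))
  # constant rate over 35-64 -> TR equals it
  expect_equal(truncated_rate(c(9, 10, 20, 5), c(1e5, 1e5, 2e5, 1e5),
                              scheme, std = c(1, 1, 1, 1)), 10)
  # zero cases in 35-64, nonzero elsewhere -> 0
  expect_equal(truncated_rate(c(50, 0, 0, 9), rep(1e5, 4), scheme,
                              std = rep(1, 4)), 0)
  # two-group toy: rates 10 and 30, equal weights -> 20
  expect_equal(truncated_rate(c(10, 10, 30, 2), rep(1e5, 4), scheme,
                              std = c(5, 1, 1, 5)), 20)
  expect_error(truncated_rate(c(1, 1, 1, 1), rep(1e5, 4), scheme,
                              std = rep(1, 4), lower = 40),
               "align")
})

test_that("cumulative rate sums width times rate; risk is 1 - exp(-CumR)", {
  expect_equal(cumulative_rate_and_risk(rep(0, 18), rep(1000, 18)),
               list(cumulative_rate = 0, cumulative_risk = 0))
  # printed formula: CumR = 0.06 -> risk = 1 - exp(-0.06)
  expect_equal(1 - exp(-0.06), 0.0582355, tolerance = 1e-6)
  # one closed group 0-74 (width 75) at rate 0.001/yr
  one <- age_scheme(c(0, 75))
  got <- cumulative_rate_and_risk(c(100, 0), c(1e5, 1e5), one)
  expect_equal(got$cumulative_rate, 0.075)
  expect_equal(got$cumulative_risk, 1 - exp(-0.075))
  # open-ended group below 75 is an alignment error
  expect_error(cumulative_rate_and_risk(c(1, 1), c(1e3, 1e3),
                                        age_scheme(c(0, 50))),
               "align")
})

test_that("cumulative risk lies in [0, 1) and is monotone in rates", {
  set.seed(3)
  scheme <- age_scheme()
  for (i in 1:50) {
    cases <- rpois(18, 30)
    py <- runif(18, 1e4, 1e5)
    a <- cumulative_rate_and_risk(cases, py, scheme)
    expect_gte(a$cumulative_risk, 0)
    expect_lt(a$cumulative_risk, 1)
    expect_equal(a$cumulative_risk, 1 - exp(-a$cumulative_rate))
    bump <- cases; g <- sample(1:15, 1); bump[g] <- bump[g] + 5
    expect_gt(cumulative_rate_and_risk(bump, py, scheme)$cumulative_risk,
              a$cumulative_risk)
  }
})

test_that("rate summary reports one row per sex and disease", {
  sim <- simulate_registry(registry_spec(seed = 5))
  rs <- rate_summary(sim$aggregated)
  expect_equal(nrow(rs), 2L)
  expect_true(all(rs$asr >= 0))
  for (i in 1:2) {
    expect_gte(rs$asr[i], 0)
    # ASR is a convex combination of age-specific rates
    sub <- sim$aggregated[sim$aggregated$sex == rs$sex[i], ]
    r <- sapply(1:18, function(g)
      1e5 * sum(sub$cases[sub$age_group == g]) /
        sum(sub$person_years[sub$age_group == g]))
    expect_gte(rs$asr[i], min(r))
    expect_lte(rs$asr[i], max(r))
  }
})
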