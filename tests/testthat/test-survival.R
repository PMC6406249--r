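test_that("cohort filter keeps treated patients surviving past the cutoff", {
  clin <- data.frame(sample_id = sprintf("p%d", 1:10),
                     time = c(30, 31, 100, 100, 100, 100, 100, 5, 200, 400),
                     event = 1,
                     treated = c(1, 1, 1, 0, 0, 0, 1, 1, 1, 1))
  suppressMessages(out <- filter_cohort(clin))
  # p1 dies at exactly 30 days (excluded: strictly longer), p8 too early,
  # p4-p6 untreated
  expect_setequal(out$sample_id, c("p2", "p3", "p7", "p9", "p10"))

  all_ok <- data.frame(sample_id = c("a", "b"), time = c(100, 150),
                       event = c(1, 0), treated = 1)
  suppressMessages(expect_identical(filter_cohort(all_ok), all_ok))
  expect_error(suppressMessages(
    filter_cohort(data.frame(sample_id = "a", time = 10, event = 1,
                             treated = 1))),
    "no patients")
})

test_that("KM estimator matches hand computation and the risk-set oracle", {
  # two events, no censoring: S = 1, 0.5, 0 at t = 0, 1, 2
  km <- km_curve(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(1, 0.5, 0))
  expect_equal(km$time, c(0, 1, 2))

  # all censored: survival never drops
  km2 <- km_curve(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km2$surv == 1))

  # duplicating every observation leaves the curve unchanged
  set.seed(12)
  t3 <- rexp(15, 0.1)
  e3 <- rbinom(15, 1, 0.7)
  k1 <- km_curve(t3, e3)
  k2 <- km_curve(c(t3, t3), c(e3, e3))
  expect_equal(k2$surv, k1$surv)

  # brute-force product-limit oracle on a small censored fixture
  expect_equal(k1$surv, km_oracle(t3, e3, k1$time))
  expect_true(all(diff(k1$surv) <= 0))
  expect_equal(k1$surv[1], 1)
})

test_that("log-rank is exact on identical groups and calibrated under the null", {
  t0 <- c(1, 2, 3, 4, 5)
  lr0 <- logrank_test(c(t0, t0), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  set.seed(77)
  pvals <- replicate(1000, {
    time <- rexp(60, 0.1)
    cens <- rexp(60, 0.03)
    logrank_test(pmin(time, cens), as.integer(time <= cens),
                 rep(c("a", "b"), each = 30))$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("log-rank has power against a strong hazard ratio", {
  set.seed(88)
  hits <- replicate(200, {
    n <- 200
    time_a <- rexp(n, 0.10)        # reference hazard
    time_b <- rexp(n, 0.10 * 0.3)  # HR 0.3
    cens <- rexp(2 * n, 0.01)      # light censoring
    time <- pmin(c(time_a, time_b), cens)
    event <- as.integer(c(time_a, time_b) <= cens)
    logrank_test(time, event, rep(c("a", "b"), each = n))$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("log-rank rejects degenerate groups", {
  expect_error(logrank_test(c(0, 0, 1), c(1, 1, 1), c("a", "a", "b")),
               "all follow-up times zero")
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "2 non-empty")
})

test_that("Cox fits recover a planted hazard ratio with nominal coverage", {
  set.seed(101)
  n <- 500
  hrs <- matrix(NA_real_, 100, 3)
  for (r in 1:100) {
    grp <- rbinom(n, 1, 0.5)
    time_ev <- rexp(n, 0.1 * 0.5^grp) # true HR 0.5
    cens <- rexp(n, 0.1 * 0.45)       # ~30% censoring
    cohort <- data.frame(time = pmin(time_ev, cens),
                         event = as.integer(time_ev <= cens), grp = grp)
    fit <- cox_fit(cohort, "grp", "univariate")
    hrs[r, ] <- c(fit$hr, fit$lower, fit$upper)
  }
  expect_lt(abs(mean(hrs[, 1]) - 0.5), 0.05)
  covered <- mean(hrs[, 2] <= 0.5 & hrs[, 3] >= 0.5)
  expect_gte(covered, 0.90)
})

test_that("a null covariate's CI contains 1 at about the nominal rate", {
  set.seed(202)
  covered <- replicate(200, {
    n <- 150
    x <- rbinom(n, 1, 0.5)
    time_ev <- rexp(n, 0.1) # independent of x
    cens <- rexp(n, 0.04)
    cohort <- data.frame(time = pmin(time_ev, cens),
                         event = as.integer(time_ev <= cens), x = x)
    fit <- cox_fit(cohort, "x", "univariate")
    fit$lower <= 1 && fit$upper >= 1
  })
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("swapping a binary coding inverts the hazard ratio", {
  set.seed(303)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  time_ev <- rexp(n, 0.1 * 0.5^x)
  cohort <- data.frame(time = time_ev, event = 1, x = x, xr = 1 - x)
  f1 <- cox_fit(cohort, "x", "univariate")
  f2 <- cox_fit(cohort, "xr", "univariate")
  expect_equal(f2$hr, 1 / f1$hr, tolerance = 1e-6)
})

test_that("multivariate Cox fits all covariates jointly", {
  set.seed(404)
  n <- 400
  a <- rbinom(n, 1, 0.5)
  b <- rbinom(n, 1, 0.4)
  time_ev <- rexp(n, 0.1 * 0.5^a * 2^b)
  cohort <- data.frame(time = time_ev, event = 1, a = a, b = b)
  fit <- cox_fit(cohort, c("a", "b"), "multivariate")
  expect_equal(nrow(fit), 2)
  expect_lt(fit$hr[fit$covariate == "a"], 1)
  expect_gt(fit$hr[fit$covariate == "b"], 1)
  expect_true(all(fit$lower <= fit$hr & fit$hr <= fit$upper))
  expect_error(cox_fit(cohort, c("a", "missing_cov"), "multivariate"),
               "absent")
  cohort$flat <- 1
  expect_error(cox_fit(cohort, "flat", "univariate"), "single level")
})

test_that("panel term coding follows the reporting contrasts", {
  labs <- c("low", "medium", "high", "low")
  expect_equal(panel_term(labs), c(0L, 1L, 1L, 0L))
  expect_equal(panel_term(labs, "high_vs_low"), c(0L, NA, 1L, 0L))
  expect_error(panel_term(c("low", "huh")), "unknown label")
})

test_that("Schoenfeld sample size matches the closed form", {
  expect_equal(schoenfeld_sample_size(0.52, alpha = 0.05, power = 0.70,
                                      event_probability = 1,
                                      group_proportion = 0.776), 84L)
  expect_equal(schoenfeld_sample_size(0.5, alpha = 0.05, power = 0.80,
                                      event_probability = 1,
                                      group_proportion = 0.5), 66L)
  # monotone: more power, rarer events, milder effects all need more patients
  n_base <- schoenfeld_sample_size(0.5, power = 0.8)
  expect_gte(schoenfeld_sample_size(0.5, power = 0.9), n_base)
  expect_gt(schoenfeld_sample_size(0.5, power = 0.8,
                                   event_probability = 0.5), n_base)
  expect_gt(schoenfeld_sample_size(0.7, power = 0.8), n_base)
  expect_error(schoenfeld_sample_size(1, power = 0.8), "infinite")
  expect_error(schoenfeld_sample_size(-2, power = 0.8), "positive")
})
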