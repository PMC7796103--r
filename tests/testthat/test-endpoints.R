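test_that("KM estimate matches the hand-rolled product-limit estimator", {
  # n = 2: one event at 1, one censoring at 2 -> S(1) = 0.5, flat after
  ipd <- pseudo_ipd("a", "OS", c(1, 2), c(TRUE, FALSE))
  km <- km_estimate(ipd)
  expect_equal(km$survival, 0.5)
  expect_equal(km_survival_at(km, c(0.5, 1, 1.9, 2)), c(1, 0.5, 0.5, 0.5))

  set.seed(12)
  for (i in 1:5) {
    ipd <- sim_exp_arm(60, 0.1, accrual = 6, cutoff = 18)
    km <- km_estimate(ipd)
    oracle <- km_by_hand(ipd$records$time_mo, ipd$records$event)
    expect_equal(km$event_times, oracle$time)
    expect_equal(km$survival, oracle$surv, tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(diff(km$greenwood_var) >= -1e-15))
  }
})

test_that("quantiles follow the weak-inequality crossing convention", {
  # S: 0.7 at 3, 0.45 at 7, 0.2 at 12 -> Q1 = 3, median = 7, Q3 = 12
  ipd <- step_ipd(c(3, 7, 12), c(6, 5, 5), n_censor = 4, censor_time = 15)
  km <- km_estimate(ipd)
  expect_equal(km_survival_at(km, c(3, 7, 12)), c(0.7, 0.45, 0.2))
  expect_equal(survival_quantile(km, 0.25)$time, 3)
  expect_equal(survival_quantile(km, 0.5)$time, 7)
  expect_equal(survival_quantile(km, 0.75)$time, 12)
  expect_error(survival_quantile(km, 0.3), "0.25")

  # curve never below 0.6 -> median not reached
  ipd2 <- step_ipd(c(2, 4), c(2, 2), n_censor = 6, censor_time = 10)
  km2 <- km_estimate(ipd2)
  expect_equal(min(km2$survival), 0.6)
  expect_true(is.na(survival_quantile(km2, 0.5)$time))
  expect_false(is.na(survival_quantile(km2, 0.25)$time))

  # crossing-time invariant on sampled arms, and agreement with the survival
  # package's inversion whenever the curve does not sit exactly on the level
  # (at exact equality the conventions differ: we take the first crossing)
  set.seed(5)
  for (i in 1:5) {
    ipd3 <- sim_exp_arm(200, 0.1, accrual = 6, cutoff = 30)
    km3 <- km_estimate(ipd3)
    for (q in c(0.25, 0.5, 0.75)) {
      est <- survival_quantile(km3, q)$time
      if (is.na(est)) next
      expect_lte(km_survival_at(km3, est), 1 - q + 1e-12)
      before <- km3$event_times[km3$event_times < est]
      if (length(before)) {
        expect_gt(min(km3$survival[km3$event_times < est]), 1 - q)
      }
      if (all(abs(km3$survival - (1 - q)) > 1e-9)) {
        qs <- stats::quantile(km3$fit, probs = q)$quantile
        expect_equal(est, unname(qs))
      }
    }
  }
})

test_that("RMST reproduces exact step-function areas", {
  # S = 1 on [0,2), 0.5 on [2,5), 0.25 on [5, inf); tau = 6:
  # 2*1 + 3*0.5 + 1*0.25 = 3.75
  ipd <- step_ipd(c(2, 5), c(2, 1), n_censor = 1, censor_time = 8)
  km <- km_estimate(ipd)
  r <- rmst(km, 6)
  expect_equal(r$value, 3.75)
  expect_true(r$ci_low <= r$value && r$value <= r$ci_high)

  # no events before tau -> RMST = tau with zero variance
  ipd2 <- step_ipd(10, 2, n_censor = 2, censor_time = 12)
  r2 <- rmst(km_estimate(ipd2), 6)
  expect_equal(r2$value, 6)
  expect_equal(r2$se, 0)

  expect_error(rmst(km, 100), "follow-up")
  r_ext <- rmst(km, 100, allow_extend = TRUE)
  expect_equal(r_ext$value, 3.75 + 0.25 * 94)
})

test_that("RMST and quantiles behave monotonically", {
  set.seed(8)
  for (i in 1:5) {
    ipd <- sim_exp_arm(80, 0.12, accrual = 6, cutoff = 24)
    km <- km_estimate(ipd)
    taus <- c(3, 6, 9, 12)
    vals <- vapply(taus, function(tau) rmst(km, tau)$value, numeric(1))
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals <= taus))
    q <- vapply(c(0.25, 0.5, 0.75),
                function(p) survival_quantile(km, p)$time, numeric(1))
    q <- q[!is.na(q)]
    expect_true(all(diff(q) >= 0))
  }
})

test_that("large-sample endpoints agree with exponential closed forms", {
  set.seed(13)
  ipd <- sim_exp_arm(10000, 0.1)
  km <- km_estimate(ipd)
  expect_equal(survival_quantile(km, 0.5)$time, log(2) / 0.1, tolerance = 0.03)
  # the RMST estimator has Monte-Carlo SE ~0.043 at this n, so the
  # closed-form comparison averages independent replicates (SE ~0.014)
  rmsts <- replicate(10, rmst(km_estimate(sim_exp_arm(10000, 0.1)), 12)$value)
  expect_lt(abs(mean(rmsts) - (1 - exp(-1.2)) / 0.1), 0.05)
  rate <- survival_rate_at(km, 12)
  expect_equal(rate$estimate, exp(-1.2), tolerance = 0.02 / exp(-1.2))
  expect_true(rate$ci_low < rate$estimate && rate$estimate < rate$ci_high)
})

test_that("survival rate lookup follows the step function", {
  ipd <- step_ipd(1:4, rep(1, 4))
  km <- km_estimate(ipd)
  expect_equal(survival_rate_at(km, 0.5)$estimate, 1)
  expect_equal(survival_rate_at(km, 2.5)$estimate, 0.5)
  expect_error(survival_rate_at(km, 10), "follow-up")
  # no events yet -> degenerate CI at 1 (Greenwood variance still zero)
  r <- survival_rate_at(km, 0.5)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
})
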