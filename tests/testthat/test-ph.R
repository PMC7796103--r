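test_that("stacking conserves records and checks identifiers", {
  set.seed(41)
  os <- sim_exp_arm(100, 0.05, arm_id = "x", endpoint = "OS")
  pfs <- sim_exp_arm(100, 0.1, arm_id = "x", endpoint = "PFS")
  st <- stack_endpoints(os, pfs)
  expect_equal(nrow(st), 200L)
  expect_equal(mean(st$endpoint), 0.5)
  expect_error(stack_endpoints(pfs, os), "OS and PFS")
  other <- sim_exp_arm(50, 0.1, arm_id = "y", endpoint = "PFS")
  expect_error(stack_endpoints(os, other), "different arms")
  # a group with no events cannot identify the hazard ratio
  cens <- pseudo_ipd("x", "PFS", runif(50, 1, 10), rep(FALSE, 50))
  expect_error(cox_ph_test(stack_endpoints(os, cens)), "at least one event")
})

test_that("two identical groups give exactly zero log hazard ratio", {
  t <- c(1, 2, 3, 5, 8, 13)
  st <- rbind(data.frame(time_mo = t, event = TRUE, endpoint = 0),
              data.frame(time_mo = t, event = TRUE, endpoint = 1))
  d <- cox_ph_test(st)
  expect_equal(d$log_hr, 0, tolerance = 1e-10)
  expect_true(d$ph_holds)
})

test_that("relabeling the endpoint indicator negates the log HR, not the PH p-value", {
  set.seed(42)
  os <- sim_exp_arm(150, 0.05, arm_id = "x", endpoint = "OS")
  pfs <- sim_exp_arm(150, 0.12, arm_id = "x", endpoint = "PFS")
  st <- stack_endpoints(os, pfs)
  flipped <- transform(st, endpoint = 1 - endpoint)
  d1 <- cox_ph_test(st)
  d2 <- cox_ph_test(flipped)
  expect_equal(d1$log_hr, -d2$log_hr, tolerance = 1e-8)
  expect_equal(d1$schoenfeld_p, d2$schoenfeld_p, tolerance = 1e-8)
})

test_that("Cox estimate agrees with a brute-force partial-likelihood grid search", {
  set.seed(43)
  for (i in 1:4) {
    n <- 10
    st <- data.frame(
      time_mo = round(rexp(2 * n, 0.1), 1) + 0.1,
      event = runif(2 * n) < 0.8,
      endpoint = rep(c(0, 1), each = n))
    if (sum(st$event[st$endpoint == 0]) == 0 ||
        sum(st$event[st$endpoint == 1]) == 0) next
    d <- cox_ph_test(st)
    grid <- seq(-2.5, 2.5, by = 1e-4)
    ll <- vapply(grid, breslow_loglik, numeric(1),
                 time = st$time_mo, event = st$event, x = st$endpoint)
    expect_lt(abs(d$log_hr - grid[which.max(ll)]), 1e-4 + 1e-8)
  }
})

test_that("the hazard ratio between exponential endpoint groups is recovered", {
  set.seed(44)
  lhr <- replicate(20, {
    os <- sim_exp_arm(500, 0.05, arm_id = "x", endpoint = "OS")
    pfs <- sim_exp_arm(500, 0.10, arm_id = "x", endpoint = "PFS")
    cox_ph_test(stack_endpoints(os, pfs))$log_hr
  })
  expect_true(exp(mean(lhr)) > 1.8 && exp(mean(lhr)) < 2.2)
})

test_that("AIC model selection prefers parsimony under proportional hazards", {
  set.seed(45)
  chosen <- replicate(40, {
    os <- sim_exp_arm(250, 0.05, arm_id = "x", endpoint = "OS")
    pfs <- sim_exp_arm(250, 0.10, arm_id = "x", endpoint = "PFS")
    time_dependent_hr(stack_endpoints(os, pfs))$chosen_time_fn
  })
  expect_gt(mean(chosen == "none"), 0.6)
})

test_that("a log-time interaction coefficient is recovered from its own model", {
  # group 1 hazard: lambda0 * exp(0.5 + 0.3 log t) = Weibull-type t^0.3 hazard
  set.seed(46)
  n <- 2000
  lam0 <- 0.08
  u <- rexp(n)
  t1 <- (u * 1.3 / (lam0 * exp(0.5)))^(1 / 1.3)
  st <- rbind(data.frame(time_mo = rexp(n, lam0), event = TRUE, endpoint = 0),
              data.frame(time_mo = t1, event = TRUE, endpoint = 1))
  d <- time_dependent_hr(st, candidates = c("linear", "log"))
  expect_false(d$ph_holds)
  expect_equal(d$chosen_time_fn, "log")
  fit <- survival::coxph(survival::Surv(time_mo, event) ~ endpoint + tt(endpoint),
                         data = st, ties = "breslow",
                         tt = function(x, t, ...) x * log(t))
  expect_lt(abs(unname(coef(fit)[2]) - 0.3), 0.1)
  # hr_t has one entry per month within follow-up
  expect_equal(nrow(d$hr_t), floor(max(st$time_mo)))
  expect_true(all(d$hr_t$hr > 0))
})

test_that("AIC accounting makes the PH and time-dependent models comparable", {
  set.seed(47)
  os <- sim_exp_arm(200, 0.05, arm_id = "x", endpoint = "OS")
  pfs <- sim_exp_arm(200, 0.10, arm_id = "x", endpoint = "PFS")
  st <- stack_endpoints(os, pfs)
  d <- time_dependent_hr(st)
  fit <- survival::coxph(survival::Surv(time_mo, event) ~ endpoint,
                         data = st, ties = "breslow")
  expect_equal(unname(d$aic_by_model["none"]),
               2 * 1 - 2 * as.numeric(logLik(fit)))
  expect_equal(d$chosen_time_fn, names(which.min(d$aic_by_model)))
})

test_that("the non-PH percentage is a rounded arm fraction", {
  mk <- function(holds) structure(list(ph_holds = holds),
                                  class = "ph_diagnostics")
  expect_equal(nonph_fraction(c(replicate(10, mk(TRUE), simplify = FALSE),
                                replicate(20, mk(FALSE), simplify = FALSE))),
               66.7)
  expect_equal(nonph_fraction(replicate(5, mk(TRUE), simplify = FALSE)), 0)
  expect_equal(nonph_fraction(c(replicate(2, mk(TRUE), simplify = FALSE),
                                replicate(5, mk(FALSE), simplify = FALSE))),
               71.4)
})
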