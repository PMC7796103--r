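#' Kaplan-Meier estimate for one arm-endpoint
#'
#' Product-limit estimator with Greenwood variance, computed with
#' [survival::survfit()] (ties handled events-before-censorings, the standard
#' KM convention). The returned object keeps the per-time risk/event counts
#' and the underlying records, which downstream pooling and digitization use.
#'
#' @param ipd A [pseudo_ipd()] object.
#' @return An object of class `km_curve` with elements `event_times`,
#'   `survival` and `greenwood_var` (at event times; the accumulated
#'   Greenwood sum `sum d / (n (n - d))`, i.e. the variance of the log
#'   cumulative hazard scale -- multiply by `S(t)^2` for the variance of
#'   the survival estimate), the full `time` / `surv` / `n_risk` /
#'   `n_event` / `n_censor` step table, `n`, `max_followup`, identifiers,
#'   the records, and the underlying `survfit` fit (log-log confidence
#'   intervals).
#' @export
km_estimate <- function(ipd) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  rec <- ipd$records
  fit <- survival::survfit(
    survival::Surv(rec$time_mo, rec$event) ~ 1,
    conf.type = "log-log", se.fit = TRUE)
  ev <- fit$n.event > 0
  structure(list(arm_id = ipd$arm_id, endpoint = ipd$endpoint,
                 time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor,
                 event_times = fit$time[ev], survival = fit$surv[ev],
                 greenwood_var = fit$std.err[ev]^2,
                 n = nrow(rec), max_followup = max(rec$time_mo),
                 data = rec, fit = fit),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km A `km_curve`.
#' @param times Times (months) at which to evaluate the estimator.
#' @return Survival probabilities; 1 before the first event.
#' @export
km_survival_at <- function(km, times) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(times, km$event_times)
  c(1, km$survival)[idx + 1L]
}

#' Survival quantile with confidence interval
#'
#' The q-quantile is the first event time at which the estimated survival
#' drops to `1 - q` or below (`NA` = not reached within follow-up). The 95%
#' CI inverts the complementary log-log pointwise confidence band
#' (Brookmeyer-Crowley style, as implemented by
#' [survival::quantile.survfit()]).
#'
#' @param km A `km_curve`.
#' @param q Event fraction: 0.25 (Q1), 0.5 (median) or 0.75 (Q3).
#' @return List of class `quantile_estimate`: `level`, `time`, `ci_low`,
#'   `ci_high` (months; `NA` where not reached).
#' @export
survival_quantile <- function(km, q) {
  stopifnot(inherits(km, "km_curve"))
  if (!isTRUE(q %in% c(0.25, 0.5, 0.75))) {
    stop("q must be one of 0.25, 0.5, 0.75")
  }
  hit <- which(km$survival <= 1 - q + 1e-12)
  time <- if (length(hit)) km$event_times[hit[1]] else NA_real_
  qf <- stats::quantile(km$fit, probs = q, conf.int = TRUE)
  structure(list(level = q, time = time,
                 ci_low = unname(qf$lower[1]),
                 ci_high = unname(qf$upper[1])),
            class = "quantile_estimate")
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier step function on `[0, tau]`, with the
#' standard large-sample variance
#' `sum over event times t <= tau of A(t)^2 * d / (n (n - d))`
#' where `A(t)` is the area under the curve between `t` and `tau`, and a
#' normal 95% CI. By default `tau` must not exceed the observed follow-up;
#' `allow_extend = TRUE` carries the last estimate forward instead.
#'
#' @param km A `km_curve`.
#' @param tau Horizon in months (> 0).
#' @param allow_extend Permit `tau` beyond the observed follow-up.
#' @return List of class `rmst_estimate`: `tau`, `value`, `se`, `ci_low`,
#'   `ci_high` (months).
#' @export
rmst <- function(km, tau, allow_extend = FALSE) {
  stopifnot(inherits(km, "km_curve"), tau > 0)
  if (tau > km$max_followup + 1e-9 && !allow_extend) {
    stop(sprintf(
      "tau = %g exceeds the observed follow-up (%g mo); the restricted mean is only estimable within follow-up (set allow_extend = TRUE to carry the last estimate forward)",
      tau, km$max_followup))
  }
  tt <- km$event_times[km$event_times <= tau]
  ss <- km$survival[km$event_times <= tau]
  steps <- c(0, tt, tau)
  value <- sum(diff(steps) * c(1, ss))
  # area beyond each event time, then Greenwood-type increments
  if (length(tt)) {
    area_beyond <- rev(cumsum(rev(diff(steps)[-1] * ss)))
    idx <- match(tt, km$event_times)
    d <- km$n_event[match(tt, km$time)]
    n <- km$n_risk[match(tt, km$time)]
    incr <- ifelse(n - d > 0, d / (n * (n - d)), 0)
    var <- sum(area_beyond^2 * incr)
  } else {
    var <- 0
  }
  se <- sqrt(var)
  structure(list(tau = tau, value = value, se = se,
                 ci_low = value - stats::qnorm(0.975) * se,
                 ci_high = value + stats::qnorm(0.975) * se),
            class = "rmst_estimate")
}

#' Survival rate at a time point
#'
#' Kaplan-Meier estimate at time `t` with a complementary log-log 95% CI.
#'
#' @param km A `km_curve`.
#' @param t Time in months, within the observed follow-up.
#' @return List with `time`, `estimate`, `ci_low`, `ci_high` (probabilities).
#' @export
survival_rate_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  if (t > km$max_followup + 1e-9) {
    stop(sprintf("t = %g exceeds the observed follow-up (%g mo)",
                 t, km$max_followup))
  }
  s <- km_survival_at(km, t)
  before <- km$event_times <= t
  cumhaz_var <- sum((km$n_event / (km$n_risk * (km$n_risk - km$n_event)))[
    match(km$event_times[before], km$time)])
  if (s <= 0 || s >= 1 || cumhaz_var == 0) {
    lo <- hi <- s
  } else {
    lam <- -log(s)
    se_loglam <- sqrt(cumhaz_var) / lam
    z <- stats::qnorm(0.975)
    lo <- s^exp(z * se_loglam)
    hi <- s^exp(-z * se_loglam)
  }
  list(time = t, estimate = s, ci_low = lo, ci_high = hi)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("KM curve for arm '%s' (%s): n = %d, %d events, follow-up %.2f mo\n",
              x$arm_id, x$endpoint, x$n, sum(x$n_event), x$max_followup))
  invisible(x)
}
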