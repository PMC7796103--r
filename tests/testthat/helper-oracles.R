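# Independent oracles and small data builders shared across the test files.

# Exponential arm with uniform accrual + administrative cutoff.
sim_exp_arm <- function(n, lambda, accrual = 0, cutoff = Inf,
                        arm_id = "arm", endpoint = "OS") {
  t <- stats::rexp(n, lambda)
  cens <- if (is.finite(cutoff)) cutoff - stats::runif(n, 0, accrual) else
    rep(Inf, n)
  pseudo_ipd(arm_id, endpoint, pmin(t, cens), t <= cens)
}

# Build a pseudo-IPD whose KM is an exact prescribed step function:
# counts of events at given times, plus censorings at a late time.
step_ipd <- function(event_times, event_counts, n_censor = 0,
                     censor_time = NULL, arm_id = "arm", endpoint = "OS") {
  times <- rep(event_times, event_counts)
  ev <- rep(TRUE, length(times))
  if (n_censor > 0) {
    times <- c(times, rep(censor_time, n_censor))
    ev <- c(ev, rep(FALSE, n_censor))
  }
  pseudo_ipd(arm_id, endpoint, times, ev)
}

# Hand-rolled product-limit estimator (oracle for km_estimate).
km_by_hand <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_at <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / n_at)
    out[i] <- s
  }
  list(time = ut, surv = out)
}

# Breslow log partial likelihood for a single binary covariate (oracle for
# the Cox fit; independent of the survival package).
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    d_idx <- time == t & event
    d <- sum(d_idx)
    ll <- ll + beta * sum(x[d_idx]) -
      d * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Weighted squared Pearson correlation, straight from the definition.
wr2_oracle <- function(x, y, w) {
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  sum(w * (x - mx) * (y - my))^2 /
    (sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

ici_rmst_rows <- function() {
  t2 <- rmst_table()
  t2[t2$drug_class == "ICI", ]
}
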