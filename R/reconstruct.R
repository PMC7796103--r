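#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Implements the Guyot-style inversion of the Kaplan-Meier construction.
#' Within each numbers-at-risk interval `[t_j, t_{j+1})` the censoring count
#' is initialized from the discrepancy between the published at-risk drop and
#' the drop implied by the KM steps, censorings are spread evenly over the
#' interval (at deterministic mid-offset positions, a reproducible stand-in
#' for "uniform over the interval"), integer event counts at each digitized
#' step are recovered from the product-limit recursion
#' `S(t_k) = S(t_{k-1}) (1 - d_k / n_k)` with the fractional residual carried
#' to the next step, and the censoring count is adjusted until the implied
#' number at risk at `t_{j+1}` matches the published value exactly. Beyond
#' the last risk-table entry, the published total event count (when
#' available) pins down the residual events; otherwise the tail is treated
#' as event-per-step with survivors censored at the end of the digitized
#' span. Events take precedence over censorings at tied times.
#'
#' @param curve A [digitized_curve()].
#' @return A [pseudo_ipd()] with one record per patient at risk at time 0.
#' @references Guyot P, Ades AE, Ouwens MJ, Welton NJ (2012). Enhanced
#'   secondary analysis of survival data: reconstructing the data from
#'   published Kaplan-Meier survival curves. BMC Med Res Methodol 12:9.
#' @export
reconstruct <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  pts <- curve$points
  rt <- curve$risk_table
  if (nrow(rt) < 1L) stop("risk table must contain at least one interval")
  n0 <- rt$n_risk[1]
  if (n0 < 1L) stop("number at risk at time 0 must be positive")

  event_times <- numeric(0); event_counts <- integer(0)
  censor_times <- numeric(0)
  n_cur <- n0
  s_prev <- 1
  carry <- 0
  boundaries <- c(rt$time_mo, Inf)
  t_end <- max(pts$time_mo, rt$time_mo)

  for (j in seq_len(nrow(rt))) {
    lo <- boundaries[j]; hi <- boundaries[j + 1]
    step_idx <- which(pts$time_mo >= lo & pts$time_mo < hi & pts$time_mo > 0)
    last_interval <- !is.finite(hi)
    if (last_interval) {
      # tail beyond the published risk table
      target_d <- if (!is.null(curve$total_events)) {
        curve$total_events - sum(event_counts)
      } else NA_integer_
      res <- solve_tail(pts, step_idx, n_cur, s_prev, carry, lo, t_end,
                        target_d)
    } else {
      res <- solve_interval(pts, step_idx, n_cur, s_prev, carry, lo, hi,
                            rt$n_risk[j + 1], j)
    }
    event_times <- c(event_times, res$event_times)
    event_counts <- c(event_counts, res$event_counts)
    censor_times <- c(censor_times, res$censor_times)
    n_cur <- res$n_out; s_prev <- res$s_out; carry <- res$carry
  }
  # survivors at the end of the digitized span are administratively censored
  if (n_cur > 0) censor_times <- c(censor_times, rep(t_end, n_cur))
  times <- c(rep(event_times, event_counts), censor_times)
  events <- c(rep(TRUE, sum(event_counts)), rep(FALSE, length(censor_times)))
  keep <- times > 0  # guard: all digitized steps are at positive times
  pseudo_ipd(curve$arm_id, curve$endpoint, times[keep], events[keep])
}

# walk one risk interval for a given censor count; deterministic
walk_interval <- function(pts, step_idx, n_in, s_in, carry_in, lo, hi,
                          n_censor) {
  width <- hi - lo
  cens <- if (n_censor > 0) {
    lo + (seq_len(n_censor) - 0.5) / n_censor * width
  } else numeric(0)
  items <- rbind(
    if (length(step_idx)) data.frame(time = pts$time_mo[step_idx],
                                     surv = pts$surv[step_idx], ev = TRUE),
    if (length(cens)) data.frame(time = cens, surv = NA_real_, ev = FALSE))
  ev_t <- numeric(0); ev_d <- integer(0)
  n_run <- n_in; s_run <- s_in; carry <- carry_in
  if (!is.null(items) && nrow(items)) {
    items <- items[order(items$time, !items$ev), , drop = FALSE]
    for (i in seq_len(nrow(items))) {
      if (items$ev[i]) {
        if (s_run <= 0) {
          d <- 0L
        } else {
          d_raw <- n_run * (1 - items$surv[i] / s_run) + carry
          d <- as.integer(max(0, min(n_run, round(d_raw))))
          carry <- d_raw - d
        }
        if (d > 0) { ev_t <- c(ev_t, items$time[i]); ev_d <- c(ev_d, d) }
        n_run <- n_run - d
        s_run <- items$surv[i]
      } else {
        n_run <- n_run - 1L
      }
    }
  }
  list(event_times = ev_t, event_counts = ev_d,
       censor_times = cens, n_out = n_run, s_out = s_run, carry = carry)
}

solve_interval <- function(pts, step_idx, n_in, s_in, carry_in, lo, hi,
                           n_target, interval_id) {
  if (n_target > n_in) {
    stop(sprintf("interval %d: published number at risk increases (infeasible)",
                 interval_id))
  }
  s_end <- if (length(step_idx)) pts$surv[max(step_idx)] else s_in
  if (s_end <= 0 && n_target > 0) {
    stop(sprintf(
      "interval %d: cannot match published number at risk %d (infeasible constraints: survival reaches 0 with patients still reported at risk)",
      interval_id, n_target))
  }
  d_hat <- if (s_in > 0) round(n_in * (1 - s_end / s_in)) else 0
  c_try <- max(0L, as.integer(n_in - n_target - d_hat))
  seen <- integer(0)
  for (iter in seq_len(1000L)) {
    res <- walk_interval(pts, step_idx, n_in, s_in, carry_in, lo, hi, c_try)
    diff <- res$n_out - n_target
    if (diff == 0L) return(res)
    c_next <- c_try + diff
    c_next <- max(0L, min(n_in, c_next))
    if (c_next == c_try || c_next %in% seen) {
      # integer jumps in the event solution can make some targets
      # unreachable by censor count alone: take the closest and reconcile
      best <- NULL; best_gap <- Inf
      for (cc in 0:n_in) {
        cand <- walk_interval(pts, step_idx, n_in, s_in, carry_in, lo, hi, cc)
        gap <- abs(cand$n_out - n_target)
        if (gap < best_gap) { best <- cand; best_gap <- gap }
        if (gap == 0) return(cand)
      }
      return(reconcile_interval(best, n_target, lo, hi, interval_id))
    }
    seen <- c(seen, c_try)
    c_try <- c_next
  }
  stop(sprintf("interval %d: censoring iteration did not converge after 1000 adjustments",
               interval_id))
}

# Force exact agreement with the published number at risk when rounding noise
# makes it unreachable: surplus patients are censored just before the interval
# end; a deficit removes events from the latest steps (those patients stay at
# risk). The fractional carry is reset, since the digitized steps and the
# risk table genuinely disagree at this point.
reconcile_interval <- function(res, n_target, lo, hi, interval_id) {
  diff <- res$n_out - n_target
  if (diff > 0) {
    res$censor_times <- c(res$censor_times,
                          rep(hi - (hi - lo) * 1e-3, diff))
    res$n_out <- n_target
  } else if (diff < 0) {
    need <- -diff
    k <- length(res$event_counts)
    while (need > 0 && k >= 1) {
      take <- min(need, res$event_counts[k])
      res$event_counts[k] <- res$event_counts[k] - take
      need <- need - take
      k <- k - 1
    }
    if (need > 0) {
      stop(sprintf(
        "interval %d: cannot match published number at risk %d (infeasible constraints)",
        interval_id, n_target))
    }
    keep <- res$event_counts > 0
    res$event_times <- res$event_times[keep]
    res$event_counts <- res$event_counts[keep]
    res$n_out <- n_target
  }
  res$carry <- 0
  res
}

solve_tail <- function(pts, step_idx, n_in, s_in, carry_in, lo, t_end,
                       target_d) {
  if (is.na(target_d)) {
    return(walk_interval(pts, step_idx, n_in, s_in, carry_in, lo, t_end, 0L))
  }
  best <- NULL; best_gap <- Inf
  for (cc in 0:n_in) {
    res <- walk_interval(pts, step_idx, n_in, s_in, carry_in, lo, t_end, cc)
    gap <- abs(sum(res$event_counts) - target_d)
    if (gap < best_gap) { best <- res; best_gap <- gap }
    if (gap == 0) break
  }
  best
}

#' Fidelity report for a reconstruction
#'
#' Compares the Kaplan-Meier curve recomputed from reconstructed pseudo-IPD
#' with the digitized input: sup-norm deviation at the digitized time points,
#' exact integer comparison of the implied numbers at risk at the published
#' risk-table times, and (when the published total event count is available)
#' the event-count discrepancy.
#'
#' @param ipd A [pseudo_ipd()] produced by [reconstruct()].
#' @param curve The [digitized_curve()] it was reconstructed from.
#' @return List with `sup_norm` (max absolute survival deviation),
#'   `risk_match` (logical per risk-table row), `implied_n_risk`, and
#'   `events_delta` (reconstructed minus published; `NULL` when the input
#'   carries no total event count).
#' @export
validate_reconstruction <- function(ipd, curve) {
  stopifnot(inherits(ipd, "pseudo_ipd"), inherits(curve, "digitized_curve"))
  if (!identical(ipd$arm_id, curve$arm_id) ||
      !identical(ipd$endpoint, curve$endpoint)) {
    stop("arm/endpoint identifiers do not match between IPD and curve")
  }
  km <- km_estimate(ipd)
  sup_norm <- max(abs(km_survival_at(km, curve$points$time_mo) -
                        curve$points$surv))
  implied <- vapply(curve$risk_table$time_mo,
                    function(t) sum(ipd$records$time_mo >= t), numeric(1))
  list(sup_norm = sup_norm,
       risk_match = implied == curve$risk_table$n_risk,
       implied_n_risk = as.integer(implied),
       events_delta = if (is.null(curve$total_events)) NULL else
         sum(ipd$records$event) - curve$total_events)
}
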