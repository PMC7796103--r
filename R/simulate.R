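#' Configuration for the synthetic trial generator
#'
#' The generator emulates a meta-analytic collection of single- or multi-arm
#' oncology trials with coupled progression-free survival (PFS) and overall
#' survival (OS), built on an illness-death model with exponential (optionally
#' Weibull) transition times:
#' \itemize{
#'   \item progression at rate `h_prog`, death before progression at
#'     `h_death_pre`, death after progression at `h_death_post` (per month);
#'   \item PFS = min(progression, death); OS = time of death, so PFS <= OS
#'     for every patient by construction;
#'   \item trial-level log-hazard random effects: the PFS effect multiplies
#'     the progression hazard, the OS effect multiplies both death hazards,
#'     drawn bivariate normal with SDs `trial_effect_sd_pfs`,
#'     `trial_effect_sd_os` and correlation `trial_effect_corr` (the knob
#'     that induces trial-level surrogacy);
#'   \item censoring by uniform accrual over `accrual_mo` months plus an
#'     administrative cutoff at `admin_censor_mo` months.
#' }
#' Defaults are calibrated to pooled immune-checkpoint-inhibitor trials in
#' advanced hepatocellular carcinoma: median PFS ~4.9 and median OS ~15.4
#' months, with more between-trial heterogeneity in PFS than in OS.
#' `shape_*` are Weibull shape parameters (1 = exponential); values away
#' from 1 exist to create non-proportional hazards for diagnostic tests.
#'
#' @param n_trials,arms_per_trial,n_per_arm Trial-set dimensions.
#' @param h_prog,h_death_pre,h_death_post Baseline transition hazards, per
#'   month, all positive.
#' @param trial_effect_sd_pfs,trial_effect_sd_os SDs (log-hazard scale) of
#'   the trial-level random effects; 0 disables heterogeneity.
#' @param trial_effect_corr Correlation in \[-1, 1\] between the two trial
#'   effects.
#' @param accrual_mo,admin_censor_mo Accrual window and administrative
#'   cutoff, months.
#' @param shape_prog,shape_death_pre,shape_death_post Weibull shapes.
#' @param seed Optional integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 20, arms_per_trial = 1, n_per_arm = 300,
                       h_prog = 0.096, h_death_pre = 0.045,
                       h_death_post = 0.045,
                       trial_effect_sd_pfs = 0.4, trial_effect_sd_os = 0.2,
                       trial_effect_corr = 0.7,
                       accrual_mo = 12, admin_censor_mo = 36,
                       shape_prog = 1, shape_death_pre = 1,
                       shape_death_post = 1, seed = NULL) {
  cfg <- list(n_trials = as.integer(n_trials),
              arms_per_trial = as.integer(arms_per_trial),
              n_per_arm = as.integer(n_per_arm),
              h_prog = h_prog, h_death_pre = h_death_pre,
              h_death_post = h_death_post,
              trial_effect_sd_pfs = trial_effect_sd_pfs,
              trial_effect_sd_os = trial_effect_sd_os,
              trial_effect_corr = trial_effect_corr,
              accrual_mo = accrual_mo, admin_censor_mo = admin_censor_mo,
              shape_prog = shape_prog, shape_death_pre = shape_death_pre,
              shape_death_post = shape_death_post, seed = seed)
  with(cfg, {
    if (any(c(h_prog, h_death_pre, h_death_post) <= 0)) {
      stop("transition hazards must be positive")
    }
    stopifnot(n_trials >= 1, arms_per_trial >= 1, n_per_arm >= 1,
              trial_effect_sd_pfs >= 0, trial_effect_sd_os >= 0,
              abs(trial_effect_corr) <= 1,
              accrual_mo >= 0, admin_censor_mo > 0,
              shape_prog > 0, shape_death_pre > 0, shape_death_post > 0)
  })
  structure(cfg, class = "sim_config")
}

# Weibull draw with hazard h(t) = rate * shape * t^(shape-1); shape 1 => Exp(rate)
rweib_rate <- function(n, rate, shape) {
  (-log(stats::runif(n)) / rate)^(1 / shape)
}

#' Simulate a set of trials with coupled PFS and OS
#'
#' Draws per-trial log-hazard effects, simulates patient-level illness-death
#' transitions, applies accrual + administrative censoring, and summarizes
#' each arm. Deterministic for a fixed `config$seed` (per-trial substreams
#' are derived from the master seed, so results do not depend on trial
#' evaluation order).
#'
#' @param config A [sim_config()].
#' @return A list with one element per arm, each containing:
#'   `arm` (one-row arm-table data frame, see [read_arm_table()]),
#'   `ipd_os` / `ipd_pfs` ([pseudo_ipd()] with censoring applied),
#'   `effects` (named vector: the trial's `b_pfs`, `b_os` log-hazard shifts),
#'   and `true` (named vector of true endpoint values from
#'   [true_endpoint_values()], exponential case only).
#' @export
simulate_trial_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L,
                            config$n_trials * (config$arms_per_trial + 1L))
  exponential <- all(c(config$shape_prog, config$shape_death_pre,
                       config$shape_death_post) == 1)
  out <- list()
  sd_p <- config$trial_effect_sd_pfs
  sd_o <- config$trial_effect_sd_os
  rho <- config$trial_effect_corr
  for (i in seq_len(config$n_trials)) {
    set.seed(trial_seeds[i])
    z1 <- stats::rnorm(1)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
    b_pfs <- sd_p * z1
    b_os <- sd_o * z2
    a <- config$h_prog * exp(b_pfs)
    b <- config$h_death_pre * exp(b_os)
    cc <- config$h_death_post * exp(b_os)
    for (j in seq_len(config$arms_per_trial)) {
      set.seed(trial_seeds[config$n_trials + (i - 1L) * config$arms_per_trial + j])
      n <- config$n_per_arm
      t_prog <- rweib_rate(n, a, config$shape_prog)
      t_dpre <- rweib_rate(n, b, config$shape_death_pre)
      died_first <- t_dpre < t_prog
      pfs <- pmin(t_prog, t_dpre)
      os <- ifelse(died_first, t_dpre,
                   t_prog + rweib_rate(n, cc, config$shape_death_post))
      cens <- config$admin_censor_mo -
        stats::runif(n, 0, min(config$accrual_mo, config$admin_censor_mo))
      arm_id <- sprintf("trial%02d_arm%d", i, j)
      ipd_pfs <- pseudo_ipd(arm_id, "PFS", pmin(pfs, cens), pfs <= cens)
      ipd_os <- pseudo_ipd(arm_id, "OS", pmin(os, cens), os <= cens)
      truth <- if (exponential) {
        true_endpoint_values(config, c(b_pfs = b_pfs, b_os = b_os))
      } else NULL
      out[[length(out) + 1L]] <- list(
        arm = summarize_sim_arm(sprintf("trial%02d", i), arm_id, n,
                                ipd_os, ipd_pfs, config),
        ipd_os = ipd_os, ipd_pfs = ipd_pfs,
        effects = c(b_pfs = b_pfs, b_os = b_os),
        true = truth)
    }
  }
  out
}

summarize_sim_arm <- function(trial_id, arm_id, n, ipd_os, ipd_pfs, config) {
  km_os <- km_estimate(ipd_os)
  km_pfs <- km_estimate(ipd_pfs)
  qt <- function(km, q) survival_quantile(km, q)$time
  rate_end <- tryCatch(
    100 * survival_rate_at(km_os, min(config$admin_censor_mo - config$accrual_mo,
                                      km_os$max_followup))$estimate,
    error = function(e) NA_real_)
  data.frame(trial_id = trial_id, arm_id = arm_id, drug_class = "ICI",
             line = "first", n = n, phase = "I_II", controlled = FALSE,
             median_os = qt(km_os, 0.5), q1_os = qt(km_os, 0.25),
             q3_os = qt(km_os, 0.75),
             median_pfs = qt(km_pfs, 0.5), q1_pfs = qt(km_pfs, 0.25),
             q3_pfs = qt(km_pfs, 0.75),
             hr_os = NA_real_, hr_pfs = NA_real_, orr_pct = NA_real_,
             os_rate_end_fu_pct = rate_end,
             followup_mo = config$admin_censor_mo)
}

#' True endpoint values under trial-adjusted exponential hazards
#'
#' Closed-form medians, first quartiles and restricted means for PFS and OS
#' under the illness-death model with exponential transitions. With
#' progression rate `a`, pre-progression death rate `b` and post-progression
#' death rate `c` (all trial-adjusted), PFS is exponential with rate `a + b`
#' and the OS survival function is
#' `S(t) = exp(-(a+b) t) + a / (a+b-c) * (exp(-c t) - exp(-(a+b) t))`
#' (with the obvious limit when `a + b = c`, where OS is exponential with
#' rate `c` whenever `b = c`).
#'
#' @param config A [sim_config()] with all Weibull shapes equal to 1.
#' @param effects Named vector with `b_pfs`, `b_os` log-hazard shifts
#'   (default 0: the baseline trial).
#' @param taus RMST horizons in months.
#' @return Named numeric vector: `median_pfs`, `q1_pfs`, `median_os`,
#'   `q1_os`, and `rmst<tau>_pfs` / `rmst<tau>_os` per horizon.
#' @export
true_endpoint_values <- function(config, effects = c(b_pfs = 0, b_os = 0),
                                 taus = c(6, 12)) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c(config$shape_prog, config$shape_death_pre,
             config$shape_death_post) == 1)) {
    stop("closed-form endpoint values require exponential transitions")
  }
  a <- config$h_prog * exp(effects[["b_pfs"]])
  b <- config$h_death_pre * exp(effects[["b_os"]])
  cc <- config$h_death_post * exp(effects[["b_os"]])
  s_os <- function(t) os_survival_exp(t, a, b, cc)
  lam_pfs <- a + b
  out <- c(median_pfs = log(2) / lam_pfs,
           q1_pfs = -log(0.75) / lam_pfs,
           median_os = stats::uniroot(function(t) s_os(t) - 0.5,
                                      c(1e-9, 1e4), tol = 1e-10)$root,
           q1_os = stats::uniroot(function(t) s_os(t) - 0.75,
                                  c(1e-9, 1e4), tol = 1e-10)$root)
  for (tau in taus) {
    out[sprintf("rmst%g_pfs", tau)] <- (1 - exp(-lam_pfs * tau)) / lam_pfs
    out[sprintf("rmst%g_os", tau)] <- os_rmst_exp(tau, a, b, cc)
  }
  out
}

os_survival_exp <- function(t, a, b, cc) {
  ab <- a + b
  if (abs(ab - cc) < 1e-12) {
    exp(-ab * t) * (1 + a * t)
  } else {
    exp(-ab * t) + a / (ab - cc) * (exp(-cc * t) - exp(-ab * t))
  }
}

os_rmst_exp <- function(tau, a, b, cc) {
  ab <- a + b
  int_exp <- function(r) (1 - exp(-r * tau)) / r
  if (abs(ab - cc) < 1e-12) {
    # integral of exp(-ab t)(1 + a t) on [0, tau]
    int_exp(ab) + a * (1 - exp(-ab * tau) * (1 + ab * tau)) / ab^2
  } else {
    k <- a / (ab - cc)
    (1 - k) * int_exp(ab) + k * int_exp(cc)
  }
}

#' Emulate plot digitization of a Kaplan-Meier curve
#'
#' Samples the estimated survival function on a regular grid (plus the exact
#' step times), rounds the probabilities to a fixed number of decimals, and
#' attaches the true numbers at risk at the requested risk-table times --
#' the information a reader extracts from a published figure.
#'
#' @param km A [km_estimate()] result.
#' @param grid_step Sampling step in months (> 0).
#' @param risk_times Times (months) at which numbers at risk are published;
#'   must lie within the observed follow-up.
#' @param rounding Number of decimals kept for survival probabilities.
#' @return A [digitized_curve()] carrying the true total event count.
#' @export
digitize <- function(km, grid_step = 1, risk_times = NULL, rounding = 3) {
  stopifnot(inherits(km, "km_curve"), grid_step > 0)
  if (is.null(risk_times)) {
    risk_times <- seq(0, floor(km$max_followup), by = 3)
  }
  if (any(risk_times < 0 | risk_times > km$max_followup)) {
    stop("risk_times outside the observed follow-up")
  }
  grid <- sort(unique(c(seq(0, km$max_followup, by = grid_step),
                        km$event_times)))
  surv <- round(km_survival_at(km, grid), rounding)
  at_risk <- vapply(risk_times, function(t) sum(km$data$time_mo >= t),
                    numeric(1))
  digitized_curve(km$arm_id, km$endpoint,
                  data.frame(time_mo = grid, surv = surv),
                  data.frame(time_mo = risk_times, n_risk = at_risk),
                  total_events = sum(km$data$event))
}
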