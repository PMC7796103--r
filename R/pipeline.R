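#' Run the full surrogacy-evaluation pipeline on synthetic trials
#'
#' Orchestrates simulate -> digitize -> reconstruct -> endpoints -> pool ->
#' PH diagnostics -> surrogacy regression from one configuration, emulating
#' the full published-data workflow: the simulated curves are digitized (grid
#' sampling + rounding) and reconstructed before any endpoint is computed, so
#' every downstream number passes through the same lossy path as published
#' figures.
#'
#' @param config A list (or path to a YAML file) with optional sections:
#'   `seed` (integer), `sim` (arguments for [sim_config()]), `digitize`
#'   (`grid_step`, `rounding`, `risk_every`), `taus` (RMST horizons,
#'   default `c(6, 12)`), `ph` (`candidates` for [time_dependent_hr()]).
#' @return A report bundle (class `surromet_report`): `arm_endpoints` (per
#'   arm: quantiles, RMSTs with CIs), `pooled` (per endpoint: pooled median,
#'   CI, I-squared), `ph` (`per_arm` diagnostics, `nonph_pct`, `pooled`
#'   time-dependent diagnostics), `surrogacy` (fits + exclusion log),
#'   `fidelity` (reconstruction sup-norms), and `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  dig <- utils::modifyList(list(grid_step = 0.25, rounding = 3,
                                risk_every = 3), config$digitize %||% list())
  taus <- config$taus %||% c(6, 12)
  cfg <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                               config$sim %||% list()))
  sim <- simulate_trial_set(cfg)

  arm_rows <- list(); fid_rows <- list(); diags <- list()
  recon <- list()
  for (s in sim) {
    row <- list(trial_id = s$arm$trial_id, arm_id = s$arm$arm_id,
                drug_class = s$arm$drug_class, n = s$arm$n)
    rec <- list()
    for (ep in c("OS", "PFS")) {
      ipd_true <- if (ep == "OS") s$ipd_os else s$ipd_pfs
      km_true <- km_estimate(ipd_true)
      risk_times <- seq(0, floor(km_true$max_followup), by = dig$risk_every)
      curve <- digitize(km_true, grid_step = dig$grid_step,
                        risk_times = risk_times, rounding = dig$rounding)
      ipd <- tryCatch(reconstruct(curve), error = function(e) {
        stop(sprintf("stage reconstruct, arm %s (%s): %s",
                     s$arm$arm_id, ep, conditionMessage(e)))
      })
      rec[[ep]] <- ipd
      rep <- validate_reconstruction(ipd, curve)
      fid_rows[[paste(s$arm$arm_id, ep)]] <- data.frame(
        arm_id = s$arm$arm_id, endpoint = ep, sup_norm = rep$sup_norm,
        risk_match = all(rep$risk_match), events_delta = rep$events_delta)
      km <- km_estimate(ipd)
      lab <- tolower(ep)
      for (q in c(0.25, 0.5, 0.75)) {
        qe <- survival_quantile(km, q)
        row[[sprintf("%s_%s", c("q1", "median", "q3")[q * 4 - 0], lab)]] <-
          qe$time
      }
      for (tau in taus) {
        if (tau <= km$max_followup) {
          r <- rmst(km, tau)
          row[[sprintf("rmst%g_%s", tau, lab)]] <- r$value
          row[[sprintf("rmst%g_%s_se", tau, lab)]] <- r$se
        }
      }
    }
    recon[[s$arm$arm_id]] <- rec
    diags[[s$arm$arm_id]] <- cox_ph_test(stack_endpoints(rec$OS, rec$PFS))
    arm_rows[[s$arm$arm_id]] <- as.data.frame(row)
  }
  arm_endpoints <- do.call(rbind, c(arm_rows, list(make.row.names = FALSE)))

  pooled <- list()
  for (ep in c("OS", "PFS")) {
    pc <- pool_curves(lapply(recon, `[[`, ep))
    med <- pooled_quantile(pc, 0.5)
    pooled[[ep]] <- list(curve = pc, median = med$time,
                         median_ci = c(med$ci_low, med$ci_high),
                         i2_pct = pc$i2_pct)
  }

  stacked_all <- do.call(rbind, lapply(recon, function(r) {
    stack_endpoints(r$OS, r$PFS)
  }))
  # quarter-month rounding before the pooled time-dependent fit: the
  # risk-set expansion of the time-interaction model grows with the number
  # of distinct event times, and a monthly HR(t) summary does not resolve
  # finer structure anyway
  stacked_all$time_mo <- pmax(0.125, round(stacked_all$time_mo * 4) / 4)
  ph_pooled <- time_dependent_hr(
    stacked_all, candidates = config$ph$candidates %||%
      c("linear", "log", "step6mo"))

  pairs <- list(median = c("median_pfs", "median_os"),
                q1 = c("q1_pfs", "q1_os"),
                q3 = c("q3_pfs", "q3_os"))
  for (tau in taus) {
    pairs[[sprintf("rmst%g", tau)]] <-
      sprintf("rmst%g_%s", tau, c("pfs", "os"))
  }
  pairs <- Filter(function(pr) all(pr %in% names(arm_endpoints)), pairs)
  surro <- surrogacy_suite(arm_endpoints, pairs = pairs)

  structure(list(arm_endpoints = arm_endpoints,
                 pooled = pooled,
                 ph = list(per_arm = diags,
                           nonph_pct = nonph_fraction(diags),
                           pooled = ph_pooled),
                 surrogacy = surro,
                 fidelity = do.call(rbind, c(fid_rows,
                                             list(make.row.names = FALSE))),
                 config = list(seed = seed, sim = unclass(cfg),
                               digitize = dig, taus = taus)),
            class = "surromet_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format helpers matching the reporting conventions
#'
#' Months are printed with 2 decimals, R-squared with 2 decimals, and
#' percentages with 1 decimal.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_months <- function(x) ifelse(is.na(x), "NR", sprintf("%.2f", x))

#' @rdname format_months
#' @export
format_r2 <- function(x) sprintf("%.2f", x)

#' @rdname format_months
#' @export
format_pct <- function(x) sprintf("%.1f", x)

#' Render a report bundle to formatted tables
#'
#' Writes the per-arm endpoint table, the pooled summaries, the PH summary
#' and the surrogacy fits as CSV or pipe-delimited markdown tables. Every
#' number is formatted from the bundle contents; nothing is recomputed.
#'
#' @param report A [run_pipeline()] bundle.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"markdown"`.
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(report, dir, format = c("csv", "markdown")) {
  stopifnot(inherits(report, "surromet_report"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "csv") "csv" else "md"
  paths <- character(0)

  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".", ext))
    if (format == "csv") {
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
      con <- file(path, "w")
      writeLines(paste0("| ", paste(names(df), collapse = " | "), " |"), con)
      writeLines(paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
                 con)
      apply(df, 1, function(r) {
        writeLines(paste0("| ", paste(r, collapse = " | "), " |"), con)
      })
      close(con)
    }
    paths <<- c(paths, path)
  }

  ep <- report$arm_endpoints
  num <- vapply(ep, is.numeric, logical(1)) & names(ep) != "n"
  ep[num] <- lapply(ep[num], format_months)
  emit(ep, "arm_endpoints")

  pooled <- do.call(rbind, lapply(names(report$pooled), function(e) {
    p <- report$pooled[[e]]
    data.frame(endpoint = e, pooled_median = format_months(p$median),
               ci_low = format_months(p$median_ci[1]),
               ci_high = format_months(p$median_ci[2]),
               i2_pct = format_pct(p$i2_pct))
  }))
  emit(pooled, "pooled_summaries")

  ph <- data.frame(
    arm_id = names(report$ph$per_arm),
    log_hr = vapply(report$ph$per_arm, function(d) d$log_hr, numeric(1)),
    schoenfeld_p = vapply(report$ph$per_arm, function(d) d$schoenfeld_p,
                          numeric(1)),
    ph_holds = vapply(report$ph$per_arm, function(d) d$ph_holds, logical(1)))
  ph$log_hr <- sprintf("%.3f", ph$log_hr)
  ph$schoenfeld_p <- sprintf("%.4f", ph$schoenfeld_p)
  ph <- rbind(ph, data.frame(arm_id = "nonph_pct",
                             log_hr = "", schoenfeld_p = "",
                             ph_holds = format_pct(report$ph$nonph_pct)))
  emit(ph, "ph_summary")

  fits <- report$surrogacy$fits
  sur <- do.call(rbind, lapply(names(fits), function(k) {
    f <- fits[[k]]
    data.frame(fit = k, n_arms = f$n_arms, r2 = format_r2(f$r2),
               r2_ci_low = format_r2(f$r2_ci_low),
               r2_ci_high = format_r2(f$r2_ci_high),
               slope = sprintf("%.3f", f$slope))
  }))
  emit(sur, "surrogacy_fits")
  invisible(paths)
}

#' @export
print.surromet_report <- function(x, ...) {
  cat(sprintf(
    "surromet pipeline report: %d arms\n  pooled median OS %.2f mo (I2 %.1f%%), PFS %.2f mo (I2 %.1f%%)\n  non-PH arms: %.1f%%\n  surrogacy fits: %s\n",
    nrow(x$arm_endpoints),
    x$pooled$OS$median, x$pooled$OS$i2_pct,
    x$pooled$PFS$median, x$pooled$PFS$i2_pct,
    x$ph$nonph_pct,
    paste(names(x$surrogacy$fits), collapse = ", ")))
  invisible(x)
}
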