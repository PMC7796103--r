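#' Sample-size-weighted linear surrogacy fit
#'
#' Weighted least squares of a true-endpoint statistic `y` on a surrogate
#' statistic `x` with arm sample sizes as weights -- the trial-level
#' meta-regression used to quantify surrogacy. The coefficient of
#' determination is the squared weighted Pearson correlation,
#' `R2 = (sum w dx dy)^2 / (sum w dx^2 * sum w dy^2)` with deviations about
#' the weighted means, which equals the R2 of the WLS fit.
#'
#' @param x,y Numeric vectors (no missing values; filter arms first).
#' @param w Positive weights, typically arm sample sizes.
#' @param x_label,y_label Names of the statistics, for reporting.
#' @return Object of class `surrogacy_fit`: `slope`, `intercept`, `r2`,
#'   `r2_ci_low` / `r2_ci_high` (Wald, see [r2_confidence()]), `n_arms`,
#'   and the data (`x`, `y`, `weights`).
#' @export
weighted_linear_fit <- function(x, y, w, x_label = "surrogate",
                                y_label = "true_endpoint") {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop("x, y, w must have equal length")
  }
  if (length(x) < 3L) stop("a surrogacy fit needs at least 3 arms")
  if (anyNA(x) || anyNA(y) || anyNA(w)) stop("missing values are not allowed")
  if (any(w <= 0)) stop("weights must be positive")
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  sxy <- sum(w * (x - mx) * (y - my))
  if (sxx == 0 || syy == 0) {
    stop("zero weighted variance in x or y; R2 undefined")
  }
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  fit <- structure(list(x_label = x_label, y_label = y_label,
                        slope = slope, intercept = my - slope * mx,
                        r2 = r2, n_arms = length(x),
                        x = x, y = y, weights = w),
                   class = "surrogacy_fit")
  ci <- r2_confidence(fit)
  fit$r2_ci_low <- ci[1]
  fit$r2_ci_high <- ci[2]
  fit
}

#' Confidence interval for the surrogacy R-squared
#'
#' `"wald"` (default) uses the Olkin-Finn large-sample variance for a
#' squared correlation with one predictor,
#' `var(R2) = 4 R2 (1 - R2)^2 (n - 2)^2 / ((n^2 - 1) (n + 3))`,
#' giving a symmetric interval that is deliberately not truncated to
#' \[0, 1\] (weak surrogacy with few arms legitimately yields a negative
#' lower bound). `"bootstrap"` resamples arms with replacement (weights
#' carried along) and reports the percentile interval.
#'
#' @param fit A [weighted_linear_fit()] result.
#' @param method `"wald"` or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates.
#' @param seed Optional seed for the bootstrap.
#' @return Length-2 numeric vector `c(low, high)`.
#' @references Olkin I, Finn JD (1995). Correlations redux. Psychol Bull
#'   118(1):155-164.
#' @export
r2_confidence <- function(fit, method = c("wald", "bootstrap"), level = 0.95,
                          n_boot = 2000, seed = NULL) {
  stopifnot(inherits(fit, "surrogacy_fit"))
  method <- match.arg(method)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    n <- fit$n_arms
    v <- 4 * fit$r2 * (1 - fit$r2)^2 * (n - 2)^2 / ((n^2 - 1) * (n + 3))
    return(fit$r2 + c(-1, 1) * z * sqrt(v))
  }
  if (fit$n_arms < 4L) stop("bootstrap CI needs at least 4 arms")
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(fit$n_arms, replace = TRUE)
    tryCatch(
      weighted_linear_fit(fit$x[idx], fit$y[idx], fit$weights[idx])$r2,
      error = function(e) NA_real_)
  }, numeric(1))
  unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                         na.rm = TRUE))
}

#' Subgroup interaction test for a surrogacy relationship
#'
#' Weighted least squares of `y` on `x`, group, and their product; the
#' interaction p-value is the two-sided t-test on the product coefficient.
#' Used to check whether the surrogate relationship differs between strata
#' (drug class, control arm, phase, treatment line, follow-up duration).
#'
#' @param x,y,w As in [weighted_linear_fit()].
#' @param group Vector with exactly two distinct labels, each contributing
#'   at least 2 arms.
#' @return Object of class `subgroup_interaction`: `subgroup_var`,
#'   `interaction_coef`, `interaction_p`, `groups`.
#' @param subgroup_var Name of the subgroup variable, for reporting.
#' @export
interaction_test <- function(x, y, w, group, subgroup_var = "group") {
  stopifnot(length(x) == length(y), length(x) == length(w),
            length(x) == length(group))
  levels <- sort(unique(as.character(group)))
  if (length(levels) != 2L) stop("interaction test needs exactly 2 groups")
  if (any(table(group) < 2L)) {
    stop("each subgroup must contribute at least 2 arms")
  }
  g <- as.numeric(as.character(group) == levels[2])
  fit <- stats::lm(y ~ x * g, weights = w)
  cf <- summary(fit)$coefficients
  if (!"x:g" %in% rownames(cf)) stop("singular design in interaction test")
  structure(list(subgroup_var = subgroup_var,
                 interaction_coef = unname(cf["x:g", "Estimate"]),
                 interaction_p = unname(cf["x:g", "Pr(>|t|)"]),
                 groups = levels),
            class = "subgroup_interaction")
}

#' Run the full set of surrogacy fits over an arm table
#'
#' For each endpoint pair (surrogate column, true-endpoint column) and each
#' stratum (overall, ICI-only, MKI-only), fits the sample-size-weighted
#' regression on the arms where both statistics are reported; arms with
#' missing / not-reached values are excluded pairwise and every exclusion is
#' recorded. Strata with fewer than 3 usable arms are skipped with a reason.
#'
#' @param arms Data frame with at least `arm_id`, `drug_class`, `n`, and the
#'   statistic columns named by `pairs` (e.g. the [read_arm_table()] dialect,
#'   optionally merged with RMST columns).
#' @param pairs Named list; each element is `c(x_column, y_column)`.
#' @return List with `fits` (named list of [weighted_linear_fit()] results,
#'   names `<pair>.<stratum>`, each carrying an `arm_ids` attribute) and
#'   `log` (data frame of fitted/skipped decisions per pair and stratum).
#' @export
surrogacy_suite <- function(arms,
                            pairs = list(
                              median = c("median_pfs", "median_os"),
                              q1 = c("q1_pfs", "q1_os"),
                              q3 = c("q3_pfs", "q3_os"))) {
  stopifnot(is.data.frame(arms), all(c("arm_id", "drug_class", "n") %in%
                                       names(arms)))
  strata <- list(overall = rep(TRUE, nrow(arms)),
                 ICI = arms$drug_class == "ICI",
                 MKI = arms$drug_class == "MKI")
  fits <- list()
  log <- list()
  for (pname in names(pairs)) {
    pr <- pairs[[pname]]
    if (!all(pr %in% names(arms))) {
      stop("columns not found in arm table: ", paste(pr, collapse = ", "))
    }
    for (sname in names(strata)) {
      sel <- strata[[sname]] & !is.na(arms[[pr[1]]]) & !is.na(arms[[pr[2]]]) &
        !is.na(arms$n)
      key <- paste(pname, sname, sep = ".")
      if (sum(sel) < 3L) {
        log[[key]] <- data.frame(pair = pname, stratum = sname,
                                 n_arms = sum(sel), fitted = FALSE,
                                 reason = "fewer than 3 arms with both statistics")
        next
      }
      fit <- weighted_linear_fit(arms[[pr[1]]][sel], arms[[pr[2]]][sel],
                                 arms$n[sel],
                                 x_label = pr[1], y_label = pr[2])
      attr(fit, "arm_ids") <- arms$arm_id[sel]
      fits[[key]] <- fit
      log[[key]] <- data.frame(pair = pname, stratum = sname,
                               n_arms = sum(sel), fitted = TRUE,
                               reason = "")
    }
  }
  list(fits = fits, log = do.call(rbind, c(log, list(make.row.names = FALSE))))
}

#' ORR vs OS-rate surrogacy
#'
#' The objective response rate is not a time-to-event statistic, so its
#' surrogacy is assessed against the OS rate at the end of follow-up:
#' a sample-size-weighted regression of `os_rate_end_fu_pct` on `orr_pct`
#' over the arms reporting both.
#'
#' @param arms Arm table ([read_arm_table()] dialect).
#' @return A [weighted_linear_fit()] result.
#' @export
orr_surrogacy <- function(arms) {
  sel <- !is.na(arms$orr_pct) & !is.na(arms$os_rate_end_fu_pct) & !is.na(arms$n)
  fit <- weighted_linear_fit(arms$orr_pct[sel], arms$os_rate_end_fu_pct[sel],
                             arms$n[sel],
                             x_label = "orr_pct", y_label = "os_rate_end_fu_pct")
  attr(fit, "arm_ids") <- arms$arm_id[sel]
  fit
}

#' @export
print.surrogacy_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted surrogacy fit of %s on %s (%d arms)\n  R2 = %.2f (95%% CI %.2f; %.2f), slope %.3f, intercept %.3f\n",
    x$y_label, x$x_label, x$n_arms, x$r2, x$r2_ci_low, x$r2_ci_high,
    x$slope, x$intercept))
  invisible(x)
}
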