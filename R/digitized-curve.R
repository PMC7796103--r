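#' Construct a digitized Kaplan-Meier curve
#'
#' Bundles digitized survival-probability coordinates with the published
#' numbers-at-risk table for one arm and endpoint. Coordinates are
#' preprocessed: survival values are clipped to \[0, 1\] and made monotone
#' non-increasing by decreasing isotonic least-squares projection
#' (pool-adjacent-violators), which absorbs the pixel-level jitter that plot
#' digitization introduces instead of rejecting the input.
#'
#' @param arm_id Arm identifier.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param points Data frame with columns `time_mo` (months, strictly
#'   increasing, first row at 0) and `surv` (the first point must be 1).
#' @param risk_table Data frame with columns `time_mo` (non-decreasing,
#'   first row at 0) and `n_risk` (non-increasing positive integers; the
#'   time-0 entry is the arm's sample size).
#' @param total_events Optional total number of events, when published.
#' @return An object of class `digitized_curve`.
#' @seealso [read_digitized_curve()], [reconstruct()]
#' @export
digitized_curve <- function(arm_id, endpoint, points, risk_table,
                            total_events = NULL) {
  stopifnot(is.data.frame(points), all(c("time_mo", "surv") %in% names(points)),
            is.data.frame(risk_table),
            all(c("time_mo", "n_risk") %in% names(risk_table)))
  endpoint <- match.arg(endpoint, c("OS", "PFS"))
  if (nrow(points) < 2L) stop("digitized curve needs at least 2 points")
  t <- as.numeric(points$time_mo)
  s <- pmin(1, pmax(0, as.numeric(points$surv)))
  if (any(diff(t) <= 0)) {
    stop("invariant violated: point times must be strictly increasing")
  }
  if (t[1] != 0) stop("invariant violated: first point must be at time 0")
  s <- isotonic_decreasing(s)
  if (abs(s[1] - 1) > 1e-9) {
    stop("invariant violated: first point must have survival 1")
  }
  s[1] <- 1
  rt <- risk_table[order(risk_table$time_mo), , drop = FALSE]
  rtt <- as.numeric(rt$time_mo)
  rtn <- as.numeric(rt$n_risk)
  if (rtt[1] != 0) stop("risk table must contain the time-0 entry")
  if (any(rtn != round(rtn)) || any(rtn < 0)) {
    stop("invariant violated: n_risk must be non-negative integers")
  }
  if (any(diff(rtn) > 0)) {
    stop("invariant violated: n_risk must be non-increasing in time")
  }
  if (!is.null(total_events)) {
    stopifnot(length(total_events) == 1L, total_events >= 0,
              total_events == round(total_events))
    total_events <- as.integer(total_events)
  }
  structure(list(arm_id = as.character(arm_id), endpoint = endpoint,
                 points = data.frame(time_mo = t, surv = s),
                 risk_table = data.frame(time_mo = rtt,
                                         n_risk = as.integer(rtn)),
                 total_events = total_events),
            class = "digitized_curve")
}

#' Decreasing isotonic least-squares projection
#'
#' Projects a numeric vector onto the cone of non-increasing sequences in the
#' least-squares sense (pool-adjacent-violators). Idempotent.
#'
#' @param s Numeric vector.
#' @return Non-increasing vector of the same length.
#' @export
isotonic_decreasing <- function(s) {
  # isoreg fits non-decreasing; negate to get the non-increasing projection
  if (length(s) <= 1L) return(s)
  -stats::isoreg(seq_along(s), -s)$yf
}

#' Read a digitized curve from coordinate and risk-table CSV files
#'
#' @param points_path CSV with columns `time_mo`, `surv`.
#' @param risk_path CSV with columns `time_mo`, `n_risk`.
#' @param arm_id,endpoint Identifiers attached to the curve.
#' @param total_events Optional published total event count.
#' @return A [digitized_curve()] object.
#' @export
read_digitized_curve <- function(points_path, risk_path, arm_id = "arm",
                                 endpoint = "OS", total_events = NULL) {
  stopifnot(file.exists(points_path), file.exists(risk_path))
  digitized_curve(arm_id, endpoint,
                  utils::read.csv(points_path),
                  utils::read.csv(risk_path),
                  total_events = total_events)
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("Digitized %s curve for arm '%s': %d points over %.2f mo, n = %d%s\n",
              x$endpoint, x$arm_id, nrow(x$points), max(x$points$time_mo),
              x$risk_table$n_risk[1],
              if (is.null(x$total_events)) ""
              else sprintf(", %d events reported", x$total_events)))
  invisible(x)
}
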