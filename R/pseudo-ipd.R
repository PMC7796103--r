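#' Pseudo individual-patient data for one arm and endpoint
#'
#' Per-patient `(time, event)` records, either simulated or reconstructed
#' from a published Kaplan-Meier curve. Times are months from randomization.
#'
#' @param arm_id Arm identifier.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param time_mo Positive event/censoring times in months.
#' @param event Logical (or 0/1) event indicators; `FALSE` = censored.
#' @return An object of class `pseudo_ipd`: a list with `arm_id`, `endpoint`
#'   and a `records` data frame (`time_mo`, `event`).
#' @export
pseudo_ipd <- function(arm_id, endpoint, time_mo, event) {
  endpoint <- match.arg(endpoint, c("OS", "PFS"))
  if (length(time_mo) == 0L) stop("pseudo-IPD must contain at least one record")
  if (length(time_mo) != length(event)) stop("time_mo/event length mismatch")
  if (any(!event %in% c(0, 1, TRUE, FALSE))) {
    stop("invariant violated: event flags must be 0/1")
  }
  if (any(time_mo <= 0)) {
    stop("invariant violated: record times must be positive")
  }
  structure(list(arm_id = as.character(arm_id), endpoint = endpoint,
                 records = data.frame(time_mo = as.numeric(time_mo),
                                      event = as.logical(event))),
            class = "pseudo_ipd")
}

#' Write / read pseudo-IPD CSV files
#'
#' The on-disk dialect is `arm_id, endpoint, time_mo, event` with times
#' serialized at 6-decimal precision; `read_ipd(write_ipd(x))` is the
#' identity at that precision.
#'
#' @param ipd A [pseudo_ipd()] object.
#' @param path CSV file path.
#' @return `write_ipd()` returns `path` invisibly; `read_ipd()` returns a
#'   [pseudo_ipd()] object.
#' @export
write_ipd <- function(ipd, path) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  df <- data.frame(arm_id = ipd$arm_id, endpoint = ipd$endpoint,
                   time_mo = sprintf("%.6f", ipd$records$time_mo),
                   event = as.integer(ipd$records$event))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path)
  need <- c("arm_id", "endpoint", "time_mo", "event")
  if (!all(need %in% names(df))) {
    stop("pseudo-IPD file must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("pseudo-IPD file contains no records")
  if (any(!df$event %in% c(0L, 1L))) {
    stop("invariant violated: event flags must be 0/1")
  }
  if (length(unique(df$arm_id)) != 1L || length(unique(df$endpoint)) != 1L) {
    stop("pseudo-IPD file must contain a single arm_id/endpoint")
  }
  pseudo_ipd(df$arm_id[1], df$endpoint[1], df$time_mo, df$event == 1L)
}

#' @export
print.pseudo_ipd <- function(x, ...) {
  cat(sprintf("Pseudo-IPD for arm '%s' (%s): %d records, %d events\n",
              x$arm_id, x$endpoint, nrow(x$records), sum(x$records$event)))
  invisible(x)
}
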