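#' Read an arm-level summary table
#'
#' Reads a CSV of trial-arm summary statistics (one row per treatment arm)
#' into a validated data frame. This is the container for published arm-level
#' outcomes: survival quantiles (months), hazard ratios, objective response
#' rates and follow-up duration. Cells that are empty or contain `"NA"` /
#' `"NR"` (not reported / not reached) become `NA` and are excluded pairwise
#' by downstream regressions, never imputed.
#'
#' @param path Path to a CSV file with the exact lower-case header
#'   `trial_id, arm_id, drug_class, line, n, phase, controlled, median_os,
#'   q1_os, q3_os, median_pfs, q1_pfs, q3_pfs, hr_os, hr_pfs, orr_pct,
#'   os_rate_end_fu_pct, followup_mo`.
#' @return A `data.frame` with one validated row per arm. Numeric columns are
#'   in months except `hr_*` (ratios) and `*_pct` (percent). `drug_class` is
#'   one of `"ICI"`, `"MKI"`, `"other"`; `line` one of `"first"`, `"second"`,
#'   `"mixed"`; `phase` one of `"I_II"`, `"III"`; `controlled` logical.
#' @examples
#' arms <- read_arm_table(system.file("extdata", "table1_ici_arms.csv",
#'                                    package = "surromet"))
#' subset(arms, drug_class == "ICI", c(arm_id, n, median_os, median_pfs))
#' @export
read_arm_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  expected <- c("trial_id", "arm_id", "drug_class", "line", "n", "phase",
                "controlled", "median_os", "q1_os", "q3_os", "median_pfs",
                "q1_pfs", "q3_pfs", "hr_os", "hr_pfs", "orr_pct",
                "os_rate_end_fu_pct", "followup_mo")
  if (!identical(names(raw), expected)) {
    stop("arm table header mismatch; expected columns: ",
         paste(expected, collapse = ", "))
  }
  if (nrow(raw) == 0L) return(raw_to_arm_df(raw))
  out <- raw_to_arm_df(raw)
  validate_arm_table(out)
  out
}

# "NR"/"NA"/"" -> NA; anything else must parse as a number
parse_num_col <- function(x, col) {
  x[x %in% c("", "NA", "NR", "-")] <- NA_character_
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(val))
  if (length(bad)) {
    stop(sprintf("arm table row %d, column '%s': cannot parse value '%s'",
                 bad[1], col, x[bad[1]]))
  }
  val
}

raw_to_arm_df <- function(raw) {
  num_cols <- c("n", "median_os", "q1_os", "q3_os", "median_pfs", "q1_pfs",
                "q3_pfs", "hr_os", "hr_pfs", "orr_pct", "os_rate_end_fu_pct",
                "followup_mo")
  out <- raw
  for (cl in num_cols) out[[cl]] <- parse_num_col(raw[[cl]], cl)
  out$n <- as.integer(out$n)
  out$controlled <- toupper(raw$controlled) %in% c("TRUE", "T", "1", "YES")
  out
}

validate_arm_table <- function(arms) {
  chk_enum <- function(col, levels) {
    bad <- which(!arms[[col]] %in% levels)
    if (length(bad)) {
      stop(sprintf("arm table row %d, column '%s': value '%s' not in {%s}",
                   bad[1], col, arms[[col]][bad[1]],
                   paste(levels, collapse = ", ")))
    }
  }
  chk_enum("drug_class", c("ICI", "MKI", "other"))
  chk_enum("line", c("first", "second", "mixed"))
  chk_enum("phase", c("I_II", "III"))
  if (any(is.na(arms$n) | arms$n < 1L)) {
    stop("arm table: invariant violated: n must be a positive integer (row ",
         which(is.na(arms$n) | arms$n < 1L)[1], ")")
  }
  chk_quantile_order <- function(q1, med, q3, label) {
    full <- !is.na(q1) & !is.na(med) & !is.na(q3)
    bad <- which(full & !(q1 <= med & med <= q3))
    if (length(bad)) {
      stop(sprintf(
        "arm table row %d: invariant violated: %s quantile order q1 <= median <= q3",
        bad[1], label))
    }
  }
  chk_quantile_order(arms$q1_os, arms$median_os, arms$q3_os, "OS")
  chk_quantile_order(arms$q1_pfs, arms$median_pfs, arms$q3_pfs, "PFS")
  for (cl in c("orr_pct", "os_rate_end_fu_pct")) {
    bad <- which(!is.na(arms[[cl]]) & (arms[[cl]] < 0 | arms[[cl]] > 100))
    if (length(bad)) {
      stop(sprintf("arm table row %d: invariant violated: %s within [0, 100]",
                   bad[1], cl))
    }
  }
  for (cl in c("hr_os", "hr_pfs")) {
    bad <- which(!is.na(arms[[cl]]) & arms[[cl]] <= 0)
    if (length(bad)) {
      stop(sprintf("arm table row %d: invariant violated: %s must be positive",
                   bad[1], cl))
    }
  }
  invisible(arms)
}

#' Packaged arm-level and RMST fixtures
#'
#' Convenience accessors for the two fixture tables shipped with the package:
#' the arm-level characteristics/outcomes of the immune-checkpoint inhibitor
#' (ICI) trials in advanced hepatocellular carcinoma, and the per-arm 6- and
#' 12-month restricted mean survival times for both drug classes.
#'
#' @return `ici_arm_table()`: the validated arm table (see
#'   [read_arm_table()]). `rmst_table()`: a data frame with columns `arm_id`,
#'   `drug_class`, `n` (`NA` where the source arm table does not report it),
#'   and point estimate / CI columns `rmst{6,12}_{pfs,os}[_lo|_hi]` in months.
#' @export
ici_arm_table <- function() {
  read_arm_table(system.file("extdata", "table1_ici_arms.csv",
                             package = "surromet", mustWork = TRUE))
}

#' @rdname ici_arm_table
#' @export
rmst_table <- function() {
  utils::read.csv(system.file("extdata", "table2_rmst.csv",
                              package = "surromet", mustWork = TRUE),
                  check.names = FALSE)
}
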