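#' A longitudinal LDH biomarker series for one patient
#'
#' @param patient_id Patient label.
#' @param times Months since therapy start; strictly increasing, first 0.
#' @param ldh Measured LDH at each time, U/L.
#' @param basal Normal-tissue LDH level, U/L (default 100). The baseline
#'   observation must exceed it (tumor-attributable LDH positive at t = 0).
#' @return A `patient_series` object.
#' @export
patient_series <- function(patient_id, times, ldh, basal = 100) {
  check_finite(times, "times"); check_finite(ldh, "ldh")
  if (length(times) != length(ldh)) stop_invalid("times and ldh lengths differ")
  if (length(times) < 4) stop_invalid("need at least 4 observations")
  if (times[1] != 0) stop_invalid("first observation must be at t = 0")
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  if (ldh[1] <= basal) stop_invalid("baseline LDH must exceed the basal level")
  if (any(ldh <= 0)) stop_invalid("LDH must be positive")
  structure(list(patient_id = as.character(patient_id), times = times,
                 ldh = ldh, basal = basal),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient series %s: %d observations over %.1f months, LDH0 = %.1f U/L>\n",
              x$patient_id, length(x$times), max(x$times), x$ldh[1]))
  invisible(x)
}

#' Write patient LDH series to CSV
#'
#' Columns: `patient_id`, `time_months`, `ldh_u_per_l`.
#'
#' @param series_list A `patient_series` or list of them.
#' @param file Output path.
#' @export
write_patient_series_csv <- function(series_list, file) {
  if (inherits(series_list, "patient_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    data.frame(patient_id = s$patient_id, time_months = s$times,
               ldh_u_per_l = s$ldh)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Read patient LDH series from CSV
#'
#' @param file CSV with columns `patient_id`, `time_months`, `ldh_u_per_l`.
#' @param basal Basal LDH assigned to every series.
#' @param min_obs Patients with fewer observations are dropped with a
#'   warning.
#' @return Named list of `patient_series`.
#' @export
read_patient_series_csv <- function(file, basal = 100, min_obs = 4) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "ldh_u_per_l")
  if (!all(need %in% names(df))) {
    stop_invalid("CSV must have columns ", paste(need, collapse = ", "))
  }
  if (!nrow(df)) stop_invalid("empty input CSV")
  out <- list()
  for (pid in unique(df$patient_id)) {
    sub <- df[df$patient_id == pid, ]
    sub <- sub[order(sub$time_months), ]
    if (nrow(sub) < min_obs) {
      warning(sprintf("patient %s skipped: only %d observations", pid, nrow(sub)))
      next
    }
    out[[as.character(pid)]] <- patient_series(pid, sub$time_months,
                                               sub$ldh_u_per_l, basal)
  }
  if (!length(out)) stop_invalid("no usable patients in input")
  out
}
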