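# Direction of "worst" per scored parameter: min for quantities whose fall
# marks dysfunction, max for those whose rise does.
worst_direction <- c(
  oxygenation_ratio = "min", spo2 = "min", pao2 = "min", platelets = "min",
  map = "min", gcs = "min", urine_output = "min",
  bilirubin = "max", creatinine = "max",
  dopamine = "max", dobutamine = "max", norepinephrine = "max"
)

#' Worst value of a parameter within a time window
#'
#' Severity scoring uses the worst value of each parameter over the 24-h
#' window, where "worst" is the minimum for oxygenation ratio, SpO2, PaO2,
#' platelets, MAP, GCS and urine output, and the maximum for bilirubin,
#' creatinine and vasopressor doses.
#'
#' @param time numeric vector of observation times (hours since admission).
#' @param value numeric vector of parameter values (may contain `NA`).
#' @param window length-2 numeric `c(start, end)` in hours; the interval is
#'   `[start, end)` unless `closed_right = TRUE` (used for the final window).
#' @param parameter parameter name; must be one listed above.
#' @param closed_right include observations at exactly `end`?
#' @return The extremum over in-window non-missing values, or `NA` if none.
#' @examples
#' worst_in_window(c(0, 6, 12), c(160, 140, 155), c(0, 24), "platelets")  # 140
#' @export
worst_in_window <- function(time, value, window, parameter,
                            closed_right = FALSE) {
  if (!parameter %in% names(worst_direction))
    stop("unknown parameter: ", parameter)
  stopifnot(length(time) == length(value), length(window) == 2)
  sel <- time >= window[1] &
    (if (closed_right) time <= window[2] else time < window[2])
  v <- value[sel & !is.na(value)]
  if (!length(v)) return(NA_real_)
  if (worst_direction[[parameter]] == "min") min(v) else max(v)
}

#' Impute isolated gaps in a time-ordered series
#'
#' A single missing value flanked by a present value on each side is replaced
#' by the arithmetic mean of its two neighbors. Leading and trailing
#' absences, and runs of two or more consecutive absences, are left missing
#' and flagged.
#'
#' @param x numeric vector in time order, `NA` marking absent values.
#' @return `x` with isolated interior gaps filled; attribute `"unfilled"`
#'   holds the indices that remain missing.
#' @examples
#' impute_single_gap(c(2, NA, 4))  # 2 3 4
#' @export
impute_single_gap <- function(x) {
  n <- length(x)
  out <- x
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (is.na(x[i]) && !is.na(x[i - 1]) && !is.na(x[i + 1]))
        out[i] <- (x[i - 1] + x[i + 1]) / 2
    }
  }
  attr(out, "unfilled") <- which(is.na(out))
  out
}
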