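#' Scoring band table
#'
#' One declarative table holding every threshold used by the six organ
#' subscores, so tests (and users) can enumerate the band structure rather
#' than reverse-engineer it from code.
#'
#' Each element is a data frame with columns `score`, `lower`, `upper`,
#' `lower_closed` and `upper_closed` describing the interval assigned to that
#' score. The intervals partition the admissible range of each criterion with
#' no gaps and no overlaps; boundary values the published score card leaves
#' ambiguous (e.g. an SpO2/FiO2 ratio of exactly 221, platelets of exactly
#' 150) are resolved by the conventions documented in the package vignette
#' and encoded here once.
#'
#' @format A named list of data frames, one per banded criterion:
#'   `respiratory_spo2`, `respiratory_pao2` (oxygenation ratio, worse = lower),
#'   `coagulation` (platelets, 10^3/mm^3), `liver` (bilirubin, mg/dL),
#'   `cns` (Glasgow Coma Scale), `renal_creatinine` (mg/dL),
#'   `renal_urine_output` (mL/day).
#' @examples
#' msofa_bands$respiratory_spo2
#' @export
msofa_bands <- local({
  tab <- function(score, lower, upper, lower_closed, upper_closed) {
    data.frame(score = as.integer(score), lower = lower, upper = upper,
               lower_closed = lower_closed, upper_closed = upper_closed)
  }
  list(
    # oxygenation ratio: score 1 keeps its printed upper edge (221-301, 300-400)
    respiratory_spo2 = tab(
      c(4, 3, 2, 1, 0),
      lower = c(0, 67, 142, 221, 301), upper = c(67, 142, 221, 301, Inf),
      lower_closed = c(TRUE, TRUE, TRUE, TRUE, FALSE),
      upper_closed = c(FALSE, FALSE, FALSE, TRUE, TRUE)),
    respiratory_pao2 = tab(
      c(4, 3, 2, 1, 0),
      lower = c(0, 100, 200, 300, 400), upper = c(100, 200, 300, 400, Inf),
      lower_closed = c(TRUE, TRUE, TRUE, TRUE, FALSE),
      upper_closed = c(FALSE, FALSE, FALSE, TRUE, TRUE)),
    coagulation = tab(
      c(4, 3, 2, 1, 0),
      lower = c(0, 20, 50, 100, 150), upper = c(20, 50, 100, 150, Inf),
      lower_closed = c(TRUE, TRUE, TRUE, TRUE, TRUE),
      upper_closed = c(FALSE, FALSE, FALSE, FALSE, TRUE)),
    liver = tab(
      c(0, 1, 2, 3, 4),
      lower = c(0, 1.2, 2.0, 6.0, 12.0), upper = c(1.2, 2.0, 6.0, 12.0, Inf),
      lower_closed = c(TRUE, TRUE, TRUE, TRUE, TRUE),
      upper_closed = c(FALSE, FALSE, FALSE, FALSE, TRUE)),
    # GCS 15 alone is normal; domain is the integer range 3..15
    cns = tab(
      c(4, 3, 2, 1, 0),
      lower = c(3, 6, 10, 13, 15), upper = c(6, 10, 13, 15, 15),
      lower_closed = c(TRUE, TRUE, TRUE, TRUE, TRUE),
      upper_closed = c(FALSE, FALSE, FALSE, FALSE, TRUE)),
    renal_creatinine = tab(
      c(0, 1, 2, 3, 4),
      lower = c(0, 1.2, 2.0, 3.5, 5.0), upper = c(1.2, 2.0, 3.5, 5.0, Inf),
      lower_closed = c(TRUE, TRUE, TRUE, TRUE, TRUE),
      upper_closed = c(FALSE, FALSE, FALSE, FALSE, TRUE)),
    renal_urine_output = tab(
      c(4, 3, 0),
      lower = c(0, 200, 500), upper = c(200, 500, Inf),
      lower_closed = c(TRUE, TRUE, TRUE),
      upper_closed = c(FALSE, FALSE, TRUE))
  )
})

# Score a numeric vector against one band table. NA passes through as NA;
# domain checks belong to the public subscore functions.
band_lookup <- function(x, bands) {
  out <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(bands))) {
    in_lo <- if (bands$lower_closed[i]) x >= bands$lower[i] else x > bands$lower[i]
    in_hi <- if (bands$upper_closed[i]) x <= bands$upper[i] else x < bands$upper[i]
    hit <- which(!is.na(x) & in_lo & in_hi)
    out[hit] <- bands$score[i]
  }
  out
}
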