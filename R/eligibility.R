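#' Apply the study's eligibility and exclusion rules
#'
#' Enrollment covers adults (> 12 years) staying in the ICU for more than
#' 24 h. Records are excluded, with exactly one primary reason each and in
#' this order of precedence, when: the patient is 12 or younger
#' (`age_le_12`), the admission was flagged as low-risk monitoring
#' (`low_risk_monitoring`), the patient died or was discharged within the
#' first 24 h (`died_or_discharged_lt_24h`, `icu_los_days <= 1`), or no
#' outcome was recorded by study end (`no_outcome`).
#'
#' @param cohort an `msofa_cohort` from [read_cohort()] or
#'   [generate_cohort()].
#' @return A list with `included` (an `msofa_cohort` restricted to analyzed
#'   patients) and `report` (class `msofa_eligibility`: counts `screened`,
#'   `enrolled`, `analyzed`, and a data frame `excluded` with one row per
#'   excluded patient and its primary `reason`).
#' @export
apply_eligibility <- function(cohort) {
  stopifnot(inherits(cohort, "msofa_cohort"))
  pat <- cohort$patients
  reason <- rep(NA_character_, nrow(pat))
  low_risk <- !is.na(pat$low_risk_monitoring) & pat$low_risk_monitoring
  reason[is.na(reason) & pat$age <= 12] <- "age_le_12"
  reason[is.na(reason) & low_risk] <- "low_risk_monitoring"
  reason[is.na(reason) & pat$icu_los_days <= 1] <- "died_or_discharged_lt_24h"
  reason[is.na(reason) & (is.na(pat$outcome) | pat$outcome == "none")] <- "no_outcome"
  excluded <- data.frame(patient_id = pat$patient_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- pat$patient_id[is.na(reason)]
  included <- structure(
    list(patients = pat[is.na(reason), , drop = FALSE],
         observations = cohort$observations[
           cohort$observations$patient_id %in% keep, , drop = FALSE]),
    class = "msofa_cohort")
  rownames(included$patients) <- rownames(included$observations) <- NULL
  report <- structure(list(screened = nrow(pat), enrolled = nrow(pat),
                           excluded = excluded,
                           analyzed = nrow(pat) - nrow(excluded)),
                      class = "msofa_eligibility")
  stopifnot(report$analyzed == report$enrolled - nrow(excluded))
  list(included = included, report = report)
}

#' @export
print.msofa_eligibility <- function(x, ...) {
  cat("Eligibility: screened", x$screened, "| enrolled", x$enrolled,
      "| analyzed", x$analyzed, "\n")
  if (nrow(x$excluded)) {
    tab <- table(x$excluded$reason)
    for (r in names(tab)) cat("  excluded -", r, ":", tab[[r]], "\n")
  }
  invisible(x)
}
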