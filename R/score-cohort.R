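# Parameters whose per-observation series feed window extraction.
score_parameters <- c("oxygenation_ratio", "platelets", "bilirubin",
                      "creatinine", "urine_output", "map", "gcs",
                      "dopamine", "dobutamine", "norepinephrine")

# Per-observation oxygenation ratio for one patient's observation rows.
# In spo2 mode FiO2 comes from the recorded value or the device estimate;
# missing numerator or FiO2 leaves the ratio missing for that observation.
obs_oxygenation_ratio <- function(obs, mode) {
  n <- nrow(obs)
  fio2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dev <- obs$device[i]
    if (is.na(dev)) {
      if (!is.na(obs$fio2[i])) fio2[i] <- obs$fio2[i]
      next
    }
    ok <- !(dev == "nasal_cannula" && is.na(obs$flow[i])) &&
      !(dev %in% c("face_mask", "ventilator") && is.na(obs$fio2[i]))
    if (ok) fio2[i] <- estimate_fio2(dev, obs$flow[i], obs$fio2[i])
  }
  num <- if (mode == "spo2") obs$spo2 else obs$pao2
  ifelse(is.na(num) | is.na(fio2), NA_real_, num / fio2)
}

#' Score one patient at admission and 48 hours
#'
#' Computes the (m)SOFA total at T0 (window `[0, 24)` h from ICU admission)
#' and T48 (window `[24, 48]` h) and the derived score family. Per parameter,
#' the time-ordered observation series is gap-imputed ([impute_single_gap()])
#' and the worst in-window value selected ([worst_in_window()]); the six
#' organ subscores then come from the scoring functions. An organ with no
#' usable data in a window is scored 0 and counted in the completeness flags
#' (`t0_n_missing`, `t48_n_missing`); a window containing no observations at
#' all makes the record unscorable.
#'
#' @param observations data frame of this patient's observation rows
#'   (schema of [msofa_schema]), sorted by time.
#' @param mode respiratory mode, `"spo2"` (default) or `"pao2"`.
#' @return A one-row data frame: the six subscores at each timepoint
#'   (`t0_respiratory` ... `t48_renal`), `t0_total`, `t48_total`, the derived
#'   family (`initial`, `at48`, `mean_score`, `highest`, `delta`,
#'   `total_sum`), completeness counts, and `scorable` (FALSE when a window
#'   had no observations).
#' @export
score_timepoints <- function(observations, mode = c("spo2", "pao2")) {
  mode <- match.arg(mode)
  obs <- observations[order(observations$time_h), , drop = FALSE]
  obs$oxygenation_ratio <- obs_oxygenation_ratio(obs, mode)
  windows <- list(t0 = c(0, 24), t48 = c(24, 48))
  worst <- list()
  for (p in score_parameters) {
    series <- impute_single_gap(obs[[p]])
    worst[[p]] <- c(
      t0  = worst_in_window(obs$time_h, series, windows$t0, p),
      t48 = worst_in_window(obs$time_h, series, windows$t48, p,
                            closed_right = TRUE))
  }
  out <- list()
  for (tp in c("t0", "t48")) {
    in_win <- obs$time_h >= windows[[tp]][1] &
      (if (tp == "t48") obs$time_h <= windows[[tp]][2]
       else obs$time_h < windows[[tp]][2])
    if (!any(in_win)) {
      out[[tp]] <- NULL
      next
    }
    w <- vapply(worst, `[[`, numeric(1), tp)
    sub <- organ_subscores(
      respiratory = respiratory_subscore(w["oxygenation_ratio"], mode),
      coagulation = coagulation_subscore(w["platelets"]),
      liver = liver_subscore(w["bilirubin"]),
      cardiovascular = cardiovascular_subscore(
        w["map"], w["dopamine"], w["dobutamine"], w["norepinephrine"]),
      cns = cns_subscore(w["gcs"]),
      renal = renal_subscore(w["creatinine"], w["urine_output"]),
      respiratory_mode = mode)
    out[[tp]] <- sub
  }
  scorable <- !is.null(out$t0) && !is.null(out$t48)
  blank <- organ_subscores(NA, NA, NA, NA, NA, NA, respiratory_mode = mode)
  t0 <- if (is.null(out$t0)) blank else out$t0
  t48 <- if (is.null(out$t48)) blank else out$t48
  res <- data.frame(
    t0_respiratory = t0$respiratory, t0_coagulation = t0$coagulation,
    t0_liver = t0$liver, t0_cardiovascular = t0$cardiovascular,
    t0_cns = t0$cns, t0_renal = t0$renal,
    t48_respiratory = t48$respiratory, t48_coagulation = t48$coagulation,
    t48_liver = t48$liver, t48_cardiovascular = t48$cardiovascular,
    t48_cns = t48$cns, t48_renal = t48$renal,
    t0_total = t0$total, t48_total = t48$total,
    t0_n_missing = t0$n_missing, t48_n_missing = t48$n_missing,
    scorable = scorable)
  res$initial <- res$t0_total
  res$at48 <- res$t48_total
  res$mean_score <- (res$t0_total + res$t48_total) / 2
  res$highest <- pmax(res$t0_total, res$t48_total)
  res$delta <- res$t48_total - res$t0_total
  res$total_sum <- res$t0_total + res$t48_total
  res
}

#' Score every patient in a cohort
#'
#' Runs [score_timepoints()] over each patient of an (already
#' eligibility-filtered) cohort and assembles the per-patient score table.
#'
#' @param cohort an `msofa_cohort`.
#' @param mode respiratory mode, `"spo2"` or `"pao2"`.
#' @param strict_missing if `TRUE`, patients with any organ unscorable after
#'   imputation are dropped (reason `missing_component`) instead of having
#'   that organ scored 0.
#' @return A data frame, one row per analyzed patient: `patient_id`, outcome
#'   and demographics joined from the patients table, then the
#'   [score_timepoints()] columns. Dropped patients and reasons are in
#'   attribute `"dropped"`.
#' @export
score_cohort <- function(cohort, mode = c("spo2", "pao2"),
                         strict_missing = FALSE) {
  stopifnot(inherits(cohort, "msofa_cohort"))
  mode <- match.arg(mode)
  pat <- cohort$patients
  rows <- vector("list", nrow(pat))
  dropped <- list()
  for (i in seq_len(nrow(pat))) {
    pid <- pat$patient_id[i]
    obs <- cohort$observations[cohort$observations$patient_id == pid, , drop = FALSE]
    if (nrow(obs) == 0) {
      dropped[[pid]] <- "no_observations"
      next
    }
    sc <- score_timepoints(obs, mode)
    if (!sc$scorable) {
      dropped[[pid]] <- "empty_window"
      next
    }
    if (strict_missing && (sc$t0_n_missing > 0 || sc$t48_n_missing > 0)) {
      dropped[[pid]] <- "missing_component"
      next
    }
    rows[[i]] <- cbind(pat[i, , drop = FALSE], sc)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) res <- data.frame()
  rownames(res) <- NULL
  attr(res, "dropped") <- if (length(dropped))
    data.frame(patient_id = names(dropped), reason = unlist(dropped),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(patient_id = character(0), reason = character(0))
  res
}
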