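#' Input schema for cohort files
#'
#' The pipeline consumes two comma-separated UTF-8 files with header rows:
#'
#' * **observations** (long format, one row per patient per timepoint):
#'   `patient_id`, `time_h` (hours since ICU admission), `spo2` (percent),
#'   `pao2` (mmHg), `device` (`room_air`/`nasal_cannula`/`face_mask`/
#'   `ventilator`), `flow` (L/min, nasal cannula), `fio2` (fraction, face
#'   mask/ventilator), `map` (mmHg), `gcs` (3-15), `platelets` (10^3/mm^3),
#'   `bilirubin` (mg/dL), `creatinine` (mg/dL), `urine_output` (mL/day),
#'   `dopamine`, `dobutamine`, `norepinephrine` (ug/kg/min).
#' * **patients** (one row per patient): `patient_id`, `age` (years), `sex`
#'   (`male`/`female`), `admission_source`, `admission_type`
#'   (`medical`/`surgical`), `mechanically_ventilated` (logical),
#'   `vasopressor_used` (logical), `low_risk_monitoring` (logical),
#'   `icu_los_days`, `outcome` (`survived`/`died`/`none`).
#'
#' Empty cells are missing values. `msofa_schema` lists, per numeric column,
#' the physiologic validity range the reader enforces.
#'
#' @format A list with elements `observations` and `patients`, each a list of
#'   per-column descriptors (`type`, `range`, `levels`, `required`).
#' @export
msofa_schema <- list(
  observations = list(
    patient_id   = list(type = "character", required = TRUE),
    time_h       = list(type = "numeric", range = c(0, 24 * 365), required = TRUE),
    spo2         = list(type = "numeric", range = c(0, 100)),
    pao2         = list(type = "numeric", range = c(0, 700)),
    device       = list(type = "factor",
                        levels = c("room_air", "nasal_cannula", "face_mask", "ventilator")),
    flow         = list(type = "numeric", range = c(0, 60)),
    fio2         = list(type = "numeric", range = c(0.21, 1)),
    map          = list(type = "numeric", range = c(10, 250)),
    gcs          = list(type = "numeric", range = c(3, 15)),
    platelets    = list(type = "numeric", range = c(0, 2000)),
    bilirubin    = list(type = "numeric", range = c(0, 80)),
    creatinine   = list(type = "numeric", range = c(0, 40)),
    urine_output = list(type = "numeric", range = c(0, 12000)),
    dopamine     = list(type = "numeric", range = c(0, 100)),
    dobutamine   = list(type = "numeric", range = c(0, 100)),
    norepinephrine = list(type = "numeric", range = c(0, 10))
  ),
  patients = list(
    patient_id   = list(type = "character", required = TRUE),
    age          = list(type = "numeric", range = c(0, 120), required = TRUE),
    sex          = list(type = "factor", levels = c("male", "female"), required = TRUE),
    admission_source = list(type = "factor",
      levels = c("emergency_room", "operating_room", "pacu", "obstetric_theatre",
                 "medical_ward", "surgical_ward", "obstetric_gynecology_ward",
                 "other_hospital")),
    admission_type = list(type = "factor", levels = c("medical", "surgical")),
    mechanically_ventilated = list(type = "logical"),
    vasopressor_used = list(type = "logical"),
    low_risk_monitoring = list(type = "logical", required = TRUE),
    icu_los_days = list(type = "numeric", range = c(0, 3650), required = TRUE),
    outcome      = list(type = "factor", levels = c("survived", "died", "none"),
                        required = TRUE)
  )
)

validate_table <- function(df, schema, what) {
  errs <- character(0)
  unknown <- setdiff(names(df), names(schema))
  if (length(unknown))
    errs <- c(errs, paste0(what, ": unknown column(s) ", paste(unknown, collapse = ", ")))
  missing_cols <- setdiff(names(schema), names(df))
  required_missing <- missing_cols[vapply(schema[missing_cols],
                                          function(s) isTRUE(s$required), logical(1))]
  if (length(required_missing))
    errs <- c(errs, paste0(what, ": required column(s) absent: ",
                           paste(required_missing, collapse = ", ")))
  for (col in intersect(names(df), names(schema))) {
    s <- schema[[col]]
    x <- df[[col]]
    if (s$type == "numeric") {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & is.na(xn))
      if (length(bad))
        errs <- c(errs, paste0(what, " column '", col, "': non-numeric value(s) at row(s) ",
                               paste(utils::head(bad, 5), collapse = ", ")))
      oor <- which(!is.na(xn) & (xn < s$range[1] | xn > s$range[2]))
      if (length(oor))
        errs <- c(errs, paste0(what, " column '", col, "': value(s) outside [",
                               s$range[1], ", ", s$range[2], "] at row(s) ",
                               paste(utils::head(oor, 5), collapse = ", ")))
      df[[col]] <- xn
    } else if (s$type == "factor") {
      x <- as.character(x)
      x[!is.na(x) & x == ""] <- NA
      bad <- which(!is.na(x) & !(x %in% s$levels))
      if (length(bad))
        errs <- c(errs, paste0(what, " column '", col, "': invalid level(s) at row(s) ",
                               paste(utils::head(bad, 5), collapse = ", "),
                               " (allowed: ", paste(s$levels, collapse = "/"), ")"))
      df[[col]] <- x
    } else if (s$type == "logical") {
      if (!is.logical(x)) {
        xl <- toupper(as.character(x))
        conv <- rep(NA, length(xl))
        conv[xl %in% c("TRUE", "T", "1")] <- TRUE
        conv[xl %in% c("FALSE", "F", "0")] <- FALSE
        bad <- which(!is.na(x) & x != "" & is.na(conv))
        if (length(bad))
          errs <- c(errs, paste0(what, " column '", col, "': non-logical value(s) at row(s) ",
                                 paste(utils::head(bad, 5), collapse = ", ")))
        df[[col]] <- conv
      }
    } else {
      df[[col]] <- as.character(x)
    }
  }
  list(df = df, errors = errs)
}

#' Read a cohort from delimited text files
#'
#' Reads and validates the observations and patients files described in
#' [msofa_schema]. Malformed rows (unknown columns, non-numeric values,
#' out-of-range physiology, duplicate patient/timestamp pairs) raise one hard
#' error listing the offenders with row numbers.
#'
#' @param observations_path,patients_path paths to the two CSV files.
#' @return An object of class `msofa_cohort`: a list with data frames
#'   `patients` and `observations` (the latter sorted by patient and time).
#' @export
read_cohort <- function(observations_path, patients_path) {
  obs <- utils::read.csv(observations_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  pat <- utils::read.csv(patients_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(obs) == 0 || nrow(pat) == 0)
    warning("empty cohort: ", if (nrow(pat) == 0) "no patients" else "no observations")
  vo <- validate_table(obs, msofa_schema$observations, "observations")
  vp <- validate_table(pat, msofa_schema$patients, "patients")
  errs <- c(vo$errors, vp$errors)
  obs <- vo$df; pat <- vp$df
  if (nrow(obs) > 0 && all(c("patient_id", "time_h") %in% names(obs))) {
    dup <- duplicated(obs[c("patient_id", "time_h")])
    if (any(dup))
      errs <- c(errs, paste0("observations: duplicate (patient, timestamp) at row(s) ",
                             paste(utils::head(which(dup), 5), collapse = ", ")))
  }
  if (nrow(pat) > 0 && anyDuplicated(pat$patient_id))
    errs <- c(errs, "patients: duplicate patient_id")
  orphans <- setdiff(unique(obs$patient_id), pat$patient_id)
  if (length(orphans))
    errs <- c(errs, paste0("observations for unknown patient(s): ",
                           paste(utils::head(orphans, 5), collapse = ", ")))
  if (length(errs))
    stop("cohort validation failed:\n  ", paste(errs, collapse = "\n  "))
  if (nrow(obs) > 0)
    obs <- obs[order(obs$patient_id, obs$time_h), , drop = FALSE]
  rownames(obs) <- rownames(pat) <- NULL
  structure(list(patients = pat, observations = obs), class = "msofa_cohort")
}

#' @export
print.msofa_cohort <- function(x, ...) {
  cat("msofa_cohort:", nrow(x$patients), "patients,",
      nrow(x$observations), "observations\n")
  if (nrow(x$patients))
    cat("  outcomes:", paste(names(table(x$patients$outcome)),
                             table(x$patients$outcome), collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort back to delimited text
#'
#' Emits the same two-file schema [read_cohort()] consumes, so generated and
#' filtered cohorts round-trip.
#'
#' @param cohort an `msofa_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (`observations`, `patients`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "msofa_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(observations = file.path(dir, "observations.csv"),
             patients = file.path(dir, "patients.csv"))
  utils::write.csv(cohort$observations, paths["observations"], row.names = FALSE, na = "")
  utils::write.csv(cohort$patients, paths["patients"], row.names = FALSE, na = "")
  invisible(paths)
}
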