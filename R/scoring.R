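#' Estimate the fraction of inspired oxygen from the delivery device
#'
#' Room air is 0.21 by definition. For nasal cannulae the FiO2 is estimated
#' from the oxygen flow as `0.21 + 0.03 * flow` (L/min), capped at 1.0; for
#' face masks and ventilators a measured/set FiO2 must be supplied and is
#' returned unchanged.
#'
#' @param device character vector: `"room_air"`, `"nasal_cannula"`,
#'   `"face_mask"` or `"ventilator"`.
#' @param flow numeric vector of oxygen flows in L/min; required (non-NA)
#'   where `device == "nasal_cannula"`.
#' @param fio2 numeric vector of known FiO2 fractions in `[0.21, 1]`;
#'   required where the device is a face mask or ventilator.
#' @return Numeric vector of FiO2 fractions in `[0.21, 1]`.
#' @examples
#' estimate_fio2("nasal_cannula", flow = 2)   # 0.27
#' estimate_fio2("room_air")
#' @export
estimate_fio2 <- function(device, flow = NA_real_, fio2 = NA_real_) {
  device <- as.character(device)
  known <- c("room_air", "nasal_cannula", "face_mask", "ventilator")
  bad <- setdiff(unique(device[!is.na(device)]), known)
  if (length(bad))
    stop("unknown oxygen delivery device: ", paste(bad, collapse = ", "))
  n <- length(device)
  flow <- rep_len(flow, n)
  fio2 <- rep_len(fio2, n)
  if (any(flow < 0, na.rm = TRUE)) stop("oxygen flow must be non-negative")
  nc <- !is.na(device) & device == "nasal_cannula"
  direct <- !is.na(device) & device %in% c("face_mask", "ventilator")
  if (any(nc & is.na(flow)))
    stop("incomplete observation: nasal cannula without a flow rate")
  if (any(direct & is.na(fio2)))
    stop("incomplete observation: ", device[direct & is.na(fio2)][1],
         " without a known FiO2")
  if (any(fio2[direct] < 0.21 | fio2[direct] > 1, na.rm = TRUE))
    stop("FiO2 must lie in [0.21, 1]")
  out <- rep(NA_real_, n)
  out[!is.na(device) & device == "room_air"] <- 0.21
  out[nc] <- pmin(pmax(0.21 + 0.03 * flow[nc], 0.21), 1)
  out[direct] <- fio2[direct]
  out
}

#' Oxygenation ratio (SpO2/FiO2 or PaO2/FiO2)
#'
#' The modified respiratory criterion divides the pulse-oximetry saturation
#' in percent by the FiO2 fraction, so that SpO2 90\% on FiO2 1.0 gives a
#' ratio of 90; the original criterion divides PaO2 in mmHg by the same
#' fraction.
#'
#' @param spo2 SpO2 in percent (0-100); required in `"spo2"` mode.
#' @param pao2 PaO2 in mmHg; required in `"pao2"` mode.
#' @param fio2 FiO2 fraction in `[0.21, 1]`.
#' @param mode `"spo2"` (default, the modification) or `"pao2"`.
#' @return Numeric vector of dimensionless ratios.
#' @examples
#' oxygenation_ratio(spo2 = 90, fio2 = 1)                  # 90
#' oxygenation_ratio(pao2 = 60, fio2 = 1, mode = "pao2")   # 60
#' @export
oxygenation_ratio <- function(spo2 = NULL, pao2 = NULL, fio2,
                              mode = c("spo2", "pao2")) {
  mode <- match.arg(mode)
  if (any(fio2 < 0.21 | fio2 > 1, na.rm = TRUE))
    stop("FiO2 must lie in [0.21, 1]")
  num <- if (mode == "spo2") spo2 else pao2
  if (is.null(num) || all(is.na(num)))
    stop("missing measurement: ", if (mode == "spo2") "SpO2" else "PaO2",
         " required in ", mode, " mode")
  if (mode == "spo2" && any(num < 0 | num > 100, na.rm = TRUE))
    stop("SpO2 must lie in [0, 100] percent")
  if (mode == "pao2" && any(num < 0, na.rm = TRUE))
    stop("PaO2 must be non-negative")
  num / fio2
}

#' Respiratory subscore from an oxygenation ratio
#'
#' @param ratio oxygenation ratio (SpO2\%/FiO2 or PaO2/FiO2), non-negative.
#' @param mode `"spo2"` (bands >301 / 221-301 / 142-220 / 67-141 / <67) or
#'   `"pao2"` (bands >400 / 300-400 / 200-299 / 100-199 / <100).
#' @return Integer subscore in 0..4.
#' @examples
#' respiratory_subscore(90)                  # 3
#' respiratory_subscore(60, mode = "pao2")   # 4
#' @export
respiratory_subscore <- function(ratio, mode = c("spo2", "pao2")) {
  mode <- match.arg(mode)
  if (any(ratio < 0, na.rm = TRUE)) stop("oxygenation ratio must be non-negative")
  band_lookup(ratio, msofa_bands[[paste0("respiratory_", mode)]])
}

#' Coagulation subscore from the platelet count
#'
#' @param platelets platelet count in 10^3/mm^3, non-negative.
#' @return Integer subscore in 0..4.
#' @export
coagulation_subscore <- function(platelets) {
  if (any(platelets < 0, na.rm = TRUE)) stop("platelet count must be non-negative")
  band_lookup(platelets, msofa_bands$coagulation)
}

#' Liver subscore from total bilirubin
#'
#' @param bilirubin total bilirubin in mg/dL, non-negative.
#' @return Integer subscore in 0..4.
#' @export
liver_subscore <- function(bilirubin) {
  if (any(bilirubin < 0, na.rm = TRUE)) stop("bilirubin must be non-negative")
  band_lookup(bilirubin, msofa_bands$liver)
}

#' Cardiovascular subscore from MAP and vasopressor support
#'
#' Scores hypotension and vasopressor requirement: 0 = no hypotension,
#' 1 = MAP < 70 mmHg without vasopressors, 2 = dopamine at most
#' 5 ug/kg/min or any dobutamine, 3 = dopamine above 5 or norepinephrine at
#' most 0.1 ug/kg/min, 4 = dopamine above 15 or norepinephrine above
#' 0.1 ug/kg/min. With several simultaneous agents each is scored and the
#' maximum taken, consistent with worst-value scoring.
#'
#' @param map mean arterial pressure in mmHg (may be `NA` when any
#'   vasopressor is running, since the drug then determines the score).
#' @param dopamine,dobutamine,norepinephrine doses in ug/kg/min; 0 or `NA`
#'   means the drug is not running.
#' @return Integer subscore in 0..4 (scalar).
#' @examples
#' cardiovascular_subscore(65)                      # 1
#' cardiovascular_subscore(70, dopamine = 16)       # 4
#' @export
cardiovascular_subscore <- function(map = NA_real_, dopamine = 0,
                                    dobutamine = 0, norepinephrine = 0) {
  doses <- c(dopamine = unname(dopamine), dobutamine = unname(dobutamine),
             norepinephrine = unname(norepinephrine))
  map <- unname(map)
  doses[is.na(doses)] <- 0
  if (any(doses < 0)) stop("vasopressor doses must be non-negative")
  if (!is.na(map) && map <= 0) stop("MAP must be positive")
  cat_dopamine <- if (doses["dopamine"] > 15) 4L else if (doses["dopamine"] > 5) 3L
    else if (doses["dopamine"] > 0) 2L else 0L
  cat_dobutamine <- if (doses["dobutamine"] > 0) 2L else 0L
  cat_norepi <- if (doses["norepinephrine"] > 0.1) 4L
    else if (doses["norepinephrine"] > 0) 3L else 0L
  cat_map <- if (!is.na(map) && map < 70) 1L else 0L
  if (all(doses == 0) && is.na(map)) return(NA_integer_)
  max(cat_dopamine, cat_dobutamine, cat_norepi, cat_map)
}

#' Central-nervous-system subscore from the Glasgow Coma Scale
#'
#' @param gcs integer GCS in 3..15.
#' @return Integer subscore in 0..4.
#' @export
cns_subscore <- function(gcs) {
  if (any(gcs < 3 | gcs > 15, na.rm = TRUE)) stop("GCS must lie in [3, 15]")
  band_lookup(gcs, msofa_bands$cns)
}

#' Renal subscore from creatinine and urine output
#'
#' The creatinine band and the urine-output band (oliguria: < 500 mL/day
#' scores 3, < 200 mL/day scores 4) are combined by maximum; an absent urine
#' output contributes nothing.
#'
#' @param creatinine serum creatinine in mg/dL, non-negative.
#' @param urine_output urine output in mL/day, non-negative, or `NA`.
#' @return Integer subscore in 0..4; `NA` (unscorable) when both inputs are
#'   absent.
#' @export
renal_subscore <- function(creatinine, urine_output = NA_real_) {
  if (any(creatinine < 0, na.rm = TRUE)) stop("creatinine must be non-negative")
  if (any(urine_output < 0, na.rm = TRUE)) stop("urine output must be non-negative")
  n <- max(length(creatinine), length(urine_output))
  creatinine <- rep_len(creatinine, n)
  urine_output <- rep_len(urine_output, n)
  sc <- band_lookup(creatinine, msofa_bands$renal_creatinine)
  su <- band_lookup(urine_output, msofa_bands$renal_urine_output)
  as.integer(pmax(sc, su, na.rm = TRUE))
}

#' Organ subscore set for one evaluation
#'
#' Bundles the six 0-4 components of one (m)SOFA evaluation and their total.
#'
#' @param respiratory,coagulation,liver,cardiovascular,cns,renal integers in
#'   0..4 (`NA` marks a component that could not be scored).
#' @param respiratory_mode `"spo2"` or `"pao2"`.
#' @return An object of class `msofa_subscores`: a list with the six
#'   components, `respiratory_mode`, `n_missing` and `total` (missing
#'   components count 0 towards the total).
#' @export
organ_subscores <- function(respiratory, coagulation, liver, cardiovascular,
                            cns, renal, respiratory_mode = "spo2") {
  comp <- c(respiratory = respiratory, coagulation = coagulation,
            liver = liver, cardiovascular = cardiovascular,
            cns = cns, renal = renal)
  ok <- is.na(comp) | (comp == floor(comp) & comp >= 0 & comp <= 4)
  if (!all(ok))
    stop("subscores must be integers in [0, 4]: ",
         paste(names(comp)[!ok], collapse = ", "))
  structure(list(respiratory = comp[["respiratory"]],
                 coagulation = comp[["coagulation"]],
                 liver = comp[["liver"]],
                 cardiovascular = comp[["cardiovascular"]],
                 cns = comp[["cns"]],
                 renal = comp[["renal"]],
                 respiratory_mode = respiratory_mode,
                 n_missing = sum(is.na(comp)),
                 total = as.integer(sum(comp, na.rm = TRUE))),
            class = "msofa_subscores")
}

#' Total (m)SOFA score
#'
#' Sum of the six organ components, 0 (normal organ function) to 24 (worst
#' organ dysfunction).
#'
#' @param subscores an [organ_subscores()] object.
#' @return Integer total in 0..24.
#' @export
total_msofa <- function(subscores) {
  stopifnot(inherits(subscores, "msofa_subscores"))
  comp <- unlist(subscores[c("respiratory", "coagulation", "liver",
                             "cardiovascular", "cns", "renal")])
  if (any(is.na(comp)))
    stop("all six components must be present; missing: ",
         paste(names(comp)[is.na(comp)], collapse = ", "))
  total <- as.integer(sum(comp))
  stopifnot(total >= 0L, total <= 24L)
  total
}

#' @export
print.msofa_subscores <- function(x, ...) {
  cat("mSOFA subscores (respiratory mode: ", x$respiratory_mode, ")\n", sep = "")
  comp <- unlist(x[c("respiratory", "coagulation", "liver",
                     "cardiovascular", "cns", "renal")])
  print(comp)
  cat("total:", x$total,
      if (x$n_missing > 0) paste0("(", x$n_missing, " component(s) missing, scored 0)"),
      "\n")
  invisible(x)
}
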