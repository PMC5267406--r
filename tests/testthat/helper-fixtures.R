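# Shared fixtures built in code.

# A tiny hand-written cohort: 3 patients x 4 timepoints with known worst
# values, plus one decoy of each exclusion class appended on demand.
make_tiny_cohort <- function() {
  obs_row <- function(pid, t, spo2 = 97, pao2 = NA, device = "room_air",
                      flow = NA, fio2 = NA, map = 85, gcs = 15,
                      platelets = 250, bilirubin = 0.5, creatinine = 0.8,
                      urine_output = 2000, dopamine = 0, dobutamine = 0,
                      norepinephrine = 0) {
    data.frame(patient_id = pid, time_h = t, spo2 = spo2, pao2 = pao2,
               device = device, flow = flow, fio2 = fio2, map = map,
               gcs = gcs, platelets = platelets, bilirubin = bilirubin,
               creatinine = creatinine, urine_output = urine_output,
               dopamine = dopamine, dobutamine = dobutamine,
               norepinephrine = norepinephrine, stringsAsFactors = FALSE)
  }
  obs <- rbind(
    # A: fully normal at both timepoints
    obs_row("A", 2), obs_row("A", 14), obs_row("A", 30), obs_row("A", 46),
    # B: deranged at T0, recovering at T48
    obs_row("B", 2, spo2 = 80, device = "ventilator", fio2 = 1.0, map = 55,
            gcs = 6, platelets = 40, bilirubin = 7.0, creatinine = 3.8,
            urine_output = 300, norepinephrine = 0.2),
    obs_row("B", 14, spo2 = 85, device = "ventilator", fio2 = 0.8),
    obs_row("B", 30, spo2 = 94, device = "nasal_cannula", flow = 2),
    obs_row("B", 46),
    # C: worsening; includes an imputable platelet gap at t=14
    obs_row("C", 2, platelets = 160),
    obs_row("C", 14, platelets = NA),
    obs_row("C", 30, platelets = 90, spo2 = 88, device = "face_mask",
            fio2 = 0.6, gcs = 9, creatinine = 2.4),
    obs_row("C", 46, platelets = 95, map = 62, dopamine = 7))
  pat <- data.frame(
    patient_id = c("A", "B", "C"),
    age = c(30, 45, 60), sex = c("male", "female", "male"),
    admission_source = c("emergency_room", "operating_room", "medical_ward"),
    admission_type = c("surgical", "surgical", "medical"),
    mechanically_ventilated = c(FALSE, TRUE, TRUE),
    vasopressor_used = c(FALSE, TRUE, TRUE),
    low_risk_monitoring = FALSE,
    icu_los_days = c(5, 9, 3),
    outcome = c("survived", "survived", "died"),
    stringsAsFactors = FALSE)
  structure(list(patients = pat, observations = obs), class = "msofa_cohort")
}

add_decoys <- function(cohort) {
  decoy <- function(pid, age = 40, low_risk = FALSE, los = 5, outcome = "survived") {
    data.frame(patient_id = pid, age = age, sex = "male",
               admission_source = "emergency_room", admission_type = "medical",
               mechanically_ventilated = FALSE, vasopressor_used = FALSE,
               low_risk_monitoring = low_risk, icu_los_days = los,
               outcome = outcome, stringsAsFactors = FALSE)
  }
  pat <- rbind(cohort$patients,
               decoy("D_child", age = 12),
               decoy("D_lowrisk", low_risk = TRUE),
               decoy("D_early", los = 0.8),
               decoy("D_noout", outcome = "none"))
  obs <- cohort$observations
  for (pid in c("D_child", "D_lowrisk", "D_early", "D_noout")) {
    o <- cohort$observations[cohort$observations$patient_id == "A", ]
    o$patient_id <- pid
    obs <- rbind(obs, o)
  }
  structure(list(patients = pat, observations = obs), class = "msofa_cohort")
}

write_tiny_cohort <- function(dir, cohort = make_tiny_cohort()) {
  write_cohort(cohort, dir)
}
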