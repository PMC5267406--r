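#' Simulation configuration
#'
#' Parameters of the synthetic ICU cohort generator. The defaults emulate
#' the study conditions the package is tested against: 170 enrolled
#' patients of whom roughly 118 survive the eligibility filter (42/170
#' low-risk-monitoring admissions, 9/170 early deaths/discharges, 1/170
#' without an outcome), an ICU mortality near 46.6\%, age ~ Normal(37, 17)
#' truncated at 13 years, and 90\% missing PaO2.
#'
#' @param n_patients number of enrolled patients generated (>= 2).
#' @param target_mortality expected death fraction among eligible patients;
#'   the logistic intercept is calibrated by root-finding so the expected
#'   mortality equals this target.
#' @param severity_effect log-odds of ICU death per unit baseline latent
#'   severity.
#' @param delta_effect log-odds of death per unit latent severity drift
#'   between admission and 48 h.
#' @param trajectory_divergence length-2 numeric `c(survivor, nonsurvivor)`:
#'   additional mean latent drift by eventual outcome (negative for
#'   survivors, positive for non-survivors).
#' @param missingness named vector of per-parameter probabilities that an
#'   observed value is blanked (see [inject_missingness()]).
#' @param low_risk_fraction,early_death_fraction,no_outcome_fraction
#'   fractions of enrolled patients injected as eligibility decoys.
#' @param age_le_12_fraction fraction injected with age <= 12 (0 by
#'   default; the generator otherwise produces adults only).
#' @param seed integer seed; the same config and seed give a byte-identical
#'   cohort.
#' @return A list of class `msofa_sim_config`.
#' @export
simulation_config <- function(n_patients = 170,
                              target_mortality = 0.466,
                              severity_effect = 0.8,
                              delta_effect = 0.5,
                              trajectory_divergence = c(-0.8, 0.5),
                              missingness = c(pao2 = 0.9, spo2 = 0.02,
                                              map = 0.02, gcs = 0.02,
                                              urine_output = 0.1),
                              low_risk_fraction = 42 / 170,
                              early_death_fraction = 9 / 170,
                              no_outcome_fraction = 1 / 170,
                              age_le_12_fraction = 0,
                              seed = 1L) {
  stopifnot(n_patients >= 2,
            target_mortality >= 0, target_mortality <= 1,
            all(missingness >= 0), all(missingness <= 1),
            low_risk_fraction >= 0, low_risk_fraction <= 1,
            early_death_fraction >= 0, early_death_fraction <= 1,
            no_outcome_fraction >= 0, no_outcome_fraction <= 1,
            age_le_12_fraction >= 0, age_le_12_fraction <= 1,
            length(trajectory_divergence) == 2)
  structure(list(n_patients = as.integer(n_patients),
                 target_mortality = target_mortality,
                 severity_effect = severity_effect,
                 delta_effect = delta_effect,
                 trajectory_divergence = trajectory_divergence,
                 missingness = missingness,
                 low_risk_fraction = low_risk_fraction,
                 early_death_fraction = early_death_fraction,
                 no_outcome_fraction = no_outcome_fraction,
                 age_le_12_fraction = age_le_12_fraction,
                 seed = as.integer(seed)),
            class = "msofa_sim_config")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Organ-level physiology links: clipped linear/log-linear functions of the
# latent severity z plus Gaussian noise, centered so a typical patient
# (z = 0) lands near the study cohort's admission subscore means. Documented
# as one table in the methods vignette.
physiology_from_z <- function(z) {
  n <- length(z)
  fio2_target <- clip(0.45 + 0.18 * z + stats::rnorm(n, 0, 0.06), 0.21, 1)
  spo2 <- clip(94 - 5 * z + stats::rnorm(n, 0, 4), 40, 100)
  pao2 <- clip(30 + 1.8 * (spo2 - 30) + stats::rnorm(n, 0, 10), 30, 500)
  device <- ifelse(fio2_target <= 0.25, "room_air",
                   ifelse(fio2_target <= 0.66, "nasal_cannula", "ventilator"))
  flow <- ifelse(device == "nasal_cannula",
                 round((fio2_target - 0.21) / 0.03, 1), NA_real_)
  fio2 <- ifelse(device == "ventilator",
                 round(clip(fio2_target, 0.3, 1), 2), NA_real_)
  data.frame(
    spo2 = round(spo2), pao2 = round(pao2),
    device = device, flow = flow, fio2 = fio2,
    map = round(clip(82 - 7 * z + stats::rnorm(n, 0, 8), 30, 180)),
    gcs = round(clip(10 - 3 * z + stats::rnorm(n, 0, 2), 3, 15)),
    platelets = round(clip(230 - 60 * z + stats::rnorm(n, 0, 40), 5, 900)),
    bilirubin = round(clip(exp(-0.5 + 0.5 * z + stats::rnorm(n, 0, 0.4)), 0.1, 60), 2),
    creatinine = round(clip(exp(0.2 + 0.4 * z + stats::rnorm(n, 0, 0.35)), 0.2, 25), 2),
    urine_output = round(clip(1500 - 320 * z + stats::rnorm(n, 0, 300), 0, 5000)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic ICU cohort
#'
#' Draws a baseline latent severity `z0 ~ N(0, 1)` and a pre-outcome drift
#' `d ~ N(0, 1)` per patient; ICU death follows
#' `Bernoulli(plogis(alpha + severity_effect * z0 + delta_effect * d))`,
#' with `alpha` calibrated by root-finding so the expected mortality equals
#' `target_mortality`. The 48-h latent severity is
#' `z48 = z0 + d + trajectory_divergence[outcome]`, so survivors drift down
#' and non-survivors up on average. Organ physiology at each observation
#' time (4 and 16 h for the admission window; 28 and 44 h for the 48-h
#' window) is produced by monotone clipped linear-Gaussian links of the
#' prevailing latent severity; missingness is then injected per
#' [inject_missingness()], and eligibility decoys (low-risk monitoring,
#' early death/discharge, missing outcome, optionally age <= 12) are
#' flagged for the filter to remove.
#'
#' @param config an [simulation_config()] object.
#' @return A list of class `msofa_sim`: `cohort` (an `msofa_cohort`),
#'   `ground_truth` (data frame with `patient_id`, `z0`, `z48`, `drift`,
#'   `p_death`, `outcome01`) and `config`. The ground truth never appears in
#'   the exported cohort files.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "msofa_sim_config"))
  if (config$target_mortality <= 0 || config$target_mortality >= 1)
    stop("infeasible calibration: target mortality must be in (0, 1)")
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%04d", seq_len(n))

  z0 <- stats::rnorm(n)
  drift <- stats::rnorm(n)
  eta <- config$severity_effect * z0 + config$delta_effect * drift
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta)) - config$target_mortality,
    lower = -30, upper = 30)$root
  p_death <- stats::plogis(alpha + eta)
  died <- stats::rbinom(n, 1, p_death)
  z48 <- z0 + drift +
    ifelse(died == 1, config$trajectory_divergence[2],
           config$trajectory_divergence[1])

  # decoys: disjoint sets of patients re-flagged for the eligibility filter
  n_low <- round(config$low_risk_fraction * n)
  n_early <- round(config$early_death_fraction * n)
  n_noout <- round(config$no_outcome_fraction * n)
  n_child <- round(config$age_le_12_fraction * n)
  idx <- sample.int(n)
  take <- function(k, used) {
    avail <- setdiff(idx, used)
    utils::head(avail, k)
  }
  i_low <- take(n_low, integer(0))
  i_early <- take(n_early, i_low)
  i_noout <- take(n_noout, c(i_low, i_early))
  i_child <- take(n_child, c(i_low, i_early, i_noout))
  low_risk <- seq_len(n) %in% i_low
  # low-risk monitoring admissions are systematically milder
  z0[low_risk] <- z0[low_risk] - 1.5
  z48[low_risk] <- z48[low_risk] - 1.5

  age <- pmax(13, round(stats::rnorm(n, 37, 17)))
  age[i_child] <- sample(4:12, length(i_child), replace = TRUE)
  sex <- ifelse(stats::runif(n) < 0.58, "male", "female")
  src_levels <- msofa_schema$patients$admission_source$levels
  src_prob <- c(33, 21, 2, 3, 25, 11, 7, 16) / 118
  admission_source <- sample(src_levels, n, replace = TRUE, prob = src_prob)
  admission_type <- ifelse(stats::runif(n) < 0.34, "medical", "surgical")
  mech_vent <- stats::runif(n) < stats::plogis(1.8 + 0.8 * z0)
  on_vaso <- stats::runif(n) < stats::plogis(-2.0 + 1.0 * z0)
  vaso_drug <- sample(c("norepinephrine", "dopamine", "dobutamine"), n,
                      replace = TRUE, prob = c(0.6, 0.3, 0.1))
  icu_los <- pmax(1.1, round(stats::rlnorm(n, log(6), 0.8), 1))
  icu_los[i_early] <- round(stats::runif(length(i_early), 0.1, 0.9), 1)
  outcome <- ifelse(died == 1, "died", "survived")
  outcome[i_noout] <- "none"

  patients <- data.frame(
    patient_id = pid, age = age, sex = sex,
    admission_source = admission_source, admission_type = admission_type,
    mechanically_ventilated = mech_vent, vasopressor_used = on_vaso,
    low_risk_monitoring = low_risk, icu_los_days = icu_los,
    outcome = outcome, stringsAsFactors = FALSE)

  times <- c(4, 16, 28, 44)
  obs <- data.frame(patient_id = rep(pid, each = length(times)),
                    time_h = rep(times, n), stringsAsFactors = FALSE)
  z_t <- ifelse(obs$time_h < 24, rep(z0, each = length(times)),
                rep(z48, each = length(times))) +
    stats::rnorm(nrow(obs), 0, 0.25)
  obs <- cbind(obs, physiology_from_z(z_t))
  obs$dopamine <- obs$dobutamine <- obs$norepinephrine <- 0
  run <- rep(on_vaso, each = length(times))
  drug <- rep(vaso_drug, each = length(times))
  dose_scale <- c(norepinephrine = 0.08, dopamine = 6, dobutamine = 5)
  base <- dose_scale[drug] * exp(0.5 * z_t + stats::rnorm(nrow(obs), 0, 0.3))
  for (d in names(dose_scale)) {
    sel <- run & drug == d
    obs[[d]][sel] <- round(pmin(base[sel],
                                if (d == "norepinephrine") 3 else 50), 3)
  }
  obs <- inject_missingness(obs, config$missingness,
                            seed = NULL) # RNG stream continues from above
  cohort <- structure(list(patients = patients, observations = obs),
                      class = "msofa_cohort")
  gt <- data.frame(patient_id = pid, z0 = z0, z48 = z48, drift = drift,
                   p_death = p_death, outcome01 = died,
                   stringsAsFactors = FALSE)
  structure(list(cohort = cohort, ground_truth = gt, config = config),
            class = "msofa_sim")
}

#' Blank observation values at configured per-parameter rates
#'
#' Each value of each named parameter is independently set missing with its
#' configured probability, emulating incomplete clinical measurement (e.g.
#' PaO2 available for only a small minority of timepoints).
#'
#' @param observations observation data frame ([msofa_schema]).
#' @param missingness named numeric vector of probabilities in `[0, 1]`;
#'   names must be observation columns.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return The observations with values blanked; attribute `"realized"`
#'   reports the realized per-parameter missing fraction.
#' @export
inject_missingness <- function(observations, missingness, seed = NULL) {
  stopifnot(all(missingness >= 0), all(missingness <= 1))
  if (!is.null(seed)) set.seed(seed)
  realized <- numeric(0)
  for (p in names(missingness)) {
    if (!p %in% names(observations)) stop("unknown parameter: ", p)
    hit <- stats::runif(nrow(observations)) < missingness[[p]]
    observations[[p]][hit] <- NA
    realized[p] <- mean(is.na(observations[[p]]))
  }
  attr(observations, "realized_missingness") <- realized
  observations
}

#' Write a simulated cohort (and its ground truth) to a directory
#'
#' @param sim an `msofa_sim` from [generate_cohort()].
#' @param dir output directory.
#' @return Invisibly, the paths written (`observations`, `patients`,
#'   `ground_truth`).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "msofa_sim"))
  paths <- write_cohort(sim$cohort, dir)
  gt_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(sim$ground_truth, gt_path, row.names = FALSE, na = "")
  invisible(c(paths, ground_truth = gt_path))
}
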