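#' Run configuration for the pipeline commands
#'
#' Bundles every knob of the simulate / score / analyze pipeline. The
#' configuration is fully serializable; every command echoes it as
#' `run_config.csv` into its output directory so a run can be reproduced
#' from its outputs alone.
#'
#' @param mode respiratory mode, `"spo2"` or `"pao2"`.
#' @param strict_missing drop patients with unscorable organs instead of
#'   scoring them 0.
#' @param covariates character vector of adjustment covariates for the
#'   logistic model (columns of the patients table, plus the score variant
#'   which is always included).
#' @param score_variant score entered into the logistic model (`"initial"`,
#'   `"at48"`, `"mean_score"`, `"highest"`, `"delta"`).
#' @param ci_method `"delong"` or `"bootstrap"` for AUC intervals.
#' @param emit_roc also write ROC coordinates per score variant.
#' @param sim [simulation_config()] used by [msofa_simulate()].
#' @param seed integer seed for any stochastic step.
#' @return A list of class `msofa_run_config`.
#' @export
run_config <- function(mode = c("spo2", "pao2"), strict_missing = FALSE,
                       covariates = c("age", "sex", "mechanically_ventilated",
                                      "vasopressor_used"),
                       score_variant = "initial",
                       ci_method = c("delong", "bootstrap"),
                       emit_roc = FALSE, sim = simulation_config(),
                       seed = 1L) {
  structure(list(mode = match.arg(mode), strict_missing = strict_missing,
                 covariates = covariates, score_variant = score_variant,
                 ci_method = match.arg(ci_method), emit_roc = emit_roc,
                 sim = sim, seed = as.integer(seed)),
            class = "msofa_run_config")
}

echo_config <- function(config, dir) {
  flat <- c(mode = config$mode, strict_missing = config$strict_missing,
            covariates = paste(config$covariates, collapse = ";"),
            score_variant = config$score_variant,
            ci_method = config$ci_method, emit_roc = config$emit_roc,
            seed = config$seed,
            stats::setNames(
              vapply(config$sim, function(x) paste(x, collapse = ";"),
                     character(1)),
              paste0("sim.", names(config$sim))))
  utils::write.csv(data.frame(key = names(flat), value = unname(flat)),
                   file.path(dir, "run_config.csv"), row.names = FALSE)
}

#' Simulate a cohort and write it to disk
#'
#' @param config a [run_config()]; its `sim` element (with `seed` overridden
#'   by the run seed) drives [generate_cohort()].
#' @param out output directory.
#' @return Invisibly, the paths written.
#' @export
msofa_simulate <- function(config = run_config(), out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sim_cfg <- config$sim
  sim_cfg$seed <- config$seed
  sim <- generate_cohort(sim_cfg)
  paths <- write_simulation(sim, out)
  echo_config(config, out)
  invisible(paths)
}

#' Read, filter and score a cohort, writing the score table
#'
#' Runs [read_cohort()], [apply_eligibility()] and [score_cohort()], and
#' writes `scores.csv` (one row per analyzed patient) plus
#' `eligibility.csv` (per-excluded-patient reasons) into `out`.
#'
#' @param config a [run_config()].
#' @param observations_path,patients_path input files.
#' @param out output directory.
#' @return Invisibly, the score table (with the eligibility report as
#'   attribute `"eligibility"`).
#' @export
msofa_score <- function(config = run_config(), observations_path,
                        patients_path, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(observations_path, patients_path)
  elig <- apply_eligibility(cohort)
  scores <- score_cohort(elig$included, mode = config$mode,
                         strict_missing = config$strict_missing)
  dropped <- attr(scores, "dropped")
  utils::write.csv(scores, file.path(out, "scores.csv"), row.names = FALSE,
                   na = "")
  elig_tab <- rbind(elig$report$excluded, dropped)
  utils::write.csv(
    cbind(elig_tab,
          screened = elig$report$screened, enrolled = elig$report$enrolled,
          analyzed = elig$report$analyzed - nrow(dropped)),
    file.path(out, "eligibility.csv"), row.names = FALSE)
  echo_config(config, out)
  attr(scores, "eligibility") <- elig$report
  invisible(scores)
}

score_variants <- c(initial = "initial", at48 = "at48", mean = "mean_score",
                    highest = "highest", delta = "delta")

#' Analyze a per-patient score table
#'
#' Emits the study-style analysis tables: (i) demographics/clinical
#' characteristics by outcome, (ii) subscore and total comparisons at both
#' timepoints with the derived score family, (iii) the AUC table for the
#' initial, 48-h, mean, highest and delta scores with confidence intervals
#' and the mean-vs-initial paired AUC comparison, and (iv) the logistic
#' odds-ratio table. Tables are returned and, when `out` is given, written
#' as CSV.
#'
#' @param scores score table from [msofa_score()]/[score_cohort()].
#' @param config a [run_config()].
#' @param out optional output directory.
#' @return A list of class `msofa_analysis` with data frames
#'   `characteristics`, `score_comparison`, `auc` (attribute
#'   `"mean_vs_initial_p"` also in column `comparison_p`), and `logistic`.
#' @export
msofa_analyze <- function(scores, config = run_config(), out = NULL) {
  if (!nrow(scores)) stop("empty score table")
  died01 <- as.integer(scores$outcome == "died")
  if (length(unique(died01)) < 2)
    stop("single-outcome cohort: both survivors and non-survivors required")
  grp <- scores$outcome

  # (i) characteristics by outcome
  chr_rows <- list()
  cont_chars <- c(age = "age", icu_los_days = "icu_los_days")
  for (nm in names(cont_chars)) {
    cc <- group_compare_continuous(scores[[cont_chars[[nm]]]], grp)
    s <- cc$groups
    chr_rows[[nm]] <- data.frame(
      characteristic = nm, type = "continuous", test = cc$test,
      survived_mean = s$survived[["mean"]], survived_sd = s$survived[["sd"]],
      died_mean = s$died[["mean"]], died_sd = s$died[["sd"]],
      survived_pct = NA_real_, died_pct = NA_real_, p_value = cc$p_value)
  }
  cat_chars <- c(sex_male = NA, medical_admission = NA,
                 mechanically_ventilated = NA, vasopressor_used = NA)
  cat_flag <- list(
    sex_male = scores$sex == "male",
    medical_admission = scores$admission_type == "medical",
    mechanically_ventilated = scores$mechanically_ventilated,
    vasopressor_used = scores$vasopressor_used)
  for (nm in names(cat_chars)) {
    f <- cat_flag[[nm]]
    tab <- rbind(table(factor(f[grp == "survived"], c(FALSE, TRUE))),
                 table(factor(f[grp == "died"], c(FALSE, TRUE))))
    cc <- tryCatch(group_compare_categorical(tab), error = function(e) NULL)
    chr_rows[[nm]] <- data.frame(
      characteristic = nm, type = "categorical",
      test = "chi_square",
      survived_mean = NA_real_, survived_sd = NA_real_,
      died_mean = NA_real_, died_sd = NA_real_,
      survived_pct = 100 * mean(f[grp == "survived"]),
      died_pct = 100 * mean(f[grp == "died"]),
      p_value = if (is.null(cc)) NA_real_ else cc$p_value)
  }
  characteristics <- do.call(rbind, chr_rows)
  rownames(characteristics) <- NULL

  # (ii) subscore/total comparison table
  organ_cols <- c(paste0("t0_", c("respiratory", "coagulation", "liver",
                                  "cardiovascular", "cns", "renal")),
                  "t0_total",
                  paste0("t48_", c("respiratory", "coagulation", "liver",
                                   "cardiovascular", "cns", "renal")),
                  "t48_total",
                  "mean_score", "highest", "delta", "total_sum")
  cmp_rows <- lapply(organ_cols, function(col) {
    cc <- group_compare_continuous(scores[[col]], grp)
    s <- cc$groups
    data.frame(score = col,
               all_mean = mean(scores[[col]]), all_sd = stats::sd(scores[[col]]),
               survived_mean = s$survived[["mean"]], survived_sd = s$survived[["sd"]],
               died_mean = s$died[["mean"]], died_sd = s$died[["sd"]],
               test = cc$test, p_value = cc$p_value)
  })
  score_comparison <- do.call(rbind, cmp_rows)

  # (iii) AUC table over the score family
  auc_rows <- lapply(names(score_variants), function(v) {
    ci <- delong_ci(scores[[score_variants[[v]]]], died01,
                    method = config$ci_method)
    data.frame(variant = v, auc = ci$auc, ci_low = ci$ci_low,
               ci_high = ci$ci_high, method = ci$method)
  })
  auc <- do.call(rbind, auc_rows)
  pt <- delong_paired_test(scores$mean_score, scores$initial, died01)
  auc$comparison_p <- NA_real_
  auc$comparison_p[auc$variant == "mean"] <- pt$p_value
  attr(auc, "mean_vs_initial_p") <- pt$p_value

  # (iv) logistic odds-ratio table
  covs <- intersect(config$covariates, names(scores))
  lg_df <- scores[, covs, drop = FALSE]
  lg_df[[config$score_variant]] <- scores[[config$score_variant]]
  lg <- fit_logistic(died01, lg_df)
  logistic <- lg$table
  logistic$covariates_used <- paste(c(config$score_variant, covs),
                                    collapse = ";")

  res <- structure(list(characteristics = characteristics,
                        score_comparison = score_comparison,
                        auc = auc, logistic = logistic,
                        n_tests = nrow(characteristics) +
                          nrow(score_comparison) + 1),
                   class = "msofa_analysis")
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(characteristics, file.path(out, "characteristics.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(score_comparison, file.path(out, "score_comparison.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(auc, file.path(out, "auc.csv"), row.names = FALSE, na = "")
    utils::write.csv(logistic, file.path(out, "logistic.csv"),
                     row.names = FALSE, na = "")
    if (config$emit_roc) {
      for (v in names(score_variants)) {
        utils::write.csv(
          roc_coordinates(scores[[score_variants[[v]]]], died01),
          file.path(out, paste0("roc_", v, ".csv")), row.names = FALSE)
      }
    }
    echo_config(config, out)
  }
  res
}

#' @export
print.msofa_analysis <- function(x, ...) {
  cat("mSOFA analysis —", nrow(x$auc), "score variants\n\nAUC table:\n")
  print(transform(x$auc, auc = round(auc, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3),
                  comparison_p = signif(comparison_p, 3)), row.names = FALSE)
  cat("\n(", x$n_tests, "hypothesis tests performed; no multiplicity",
      "correction applied)\n")
  invisible(x)
}

#' Run the full simulate-score-analyze pipeline
#'
#' @param config a [run_config()].
#' @param out output directory; subdirectories `cohort/`, `scores/` and
#'   `analysis/` are written.
#' @return The `msofa_analysis`, invisibly.
#' @export
msofa_run_all <- function(config = run_config(), out) {
  paths <- msofa_simulate(config, file.path(out, "cohort"))
  scores <- msofa_score(config, paths[["observations"]], paths[["patients"]],
                        file.path(out, "scores"))
  invisible(msofa_analyze(scores, config, file.path(out, "analysis")))
}
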