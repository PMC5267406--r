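test_that("cohort files round-trip through the reader with full validation", {
  d <- withr::local_tempdir()
  p <- write_tiny_cohort(d)
  co <- read_cohort(p["observations"], p["patients"])
  expect_s3_class(co, "msofa_cohort")
  expect_identical(nrow(co$patients), 3L)
  expect_identical(nrow(co$observations), 12L)
  expect_identical(unname(table(co$observations$patient_id)["A"]), 4L)
  # observations come back sorted by patient and time
  expect_true(all(diff(order(co$observations$patient_id,
                             co$observations$time_h)) == 1))
})

test_that("the reader rejects malformed input naming the offending rows", {
  d <- withr::local_tempdir()
  co <- make_tiny_cohort()
  co$observations$platelets[3] <- -10
  p <- write_cohort(co, d)
  expect_error(read_cohort(p["observations"], p["patients"]),
               "platelets.*row\\(s\\) 3")

  co <- make_tiny_cohort()
  co$observations$time_h[2] <- co$observations$time_h[1]
  p <- write_cohort(co, file.path(d, "dup"))
  expect_error(read_cohort(p["observations"], p["patients"]), "duplicate")

  co <- make_tiny_cohort()
  names(co$observations)[3] <- "sp02_typo"
  p <- write_cohort(co, file.path(d, "unk"))
  expect_error(read_cohort(p["observations"], p["patients"]), "unknown column")

  # non-numeric value in a numeric column
  obs_path <- file.path(d, "nn_obs.csv")
  writeLines(c("patient_id,time_h,platelets", "A,0,abc"), obs_path)
  pat_path <- file.path(d, "nn_pat.csv")
  writeLines(paste0("patient_id,age,sex,low_risk_monitoring,icu_los_days,",
                    "outcome"), pat_path)
  writeLines(c(readLines(pat_path), "A,40,male,FALSE,5,survived"), pat_path)
  expect_error(read_cohort(obs_path, pat_path), "non-numeric")
})

test_that("an empty file yields an empty cohort with a warning", {
  d <- withr::local_tempdir()
  p <- write_tiny_cohort(d)
  empty_obs <- file.path(d, "empty_obs.csv")
  writeLines(readLines(p["observations"])[1], empty_obs)
  expect_warning(co <- read_cohort(empty_obs, p["patients"]), "empty cohort")
  expect_identical(nrow(co$observations), 0L)
})

test_that("eligibility excludes each decoy class with one primary reason", {
  co <- add_decoys(make_tiny_cohort())
  res <- apply_eligibility(co)
  expect_identical(res$report$enrolled, 7L)
  expect_identical(res$report$analyzed, 3L)
  expect_setequal(res$included$patients$patient_id, c("A", "B", "C"))
  got <- res$report$excluded
  expect_identical(got$reason[got$patient_id == "D_child"], "age_le_12")
  expect_identical(got$reason[got$patient_id == "D_lowrisk"], "low_risk_monitoring")
  expect_identical(got$reason[got$patient_id == "D_early"],
                   "died_or_discharged_lt_24h")
  expect_identical(got$reason[got$patient_id == "D_noout"], "no_outcome")
  # reason counts sum to enrolled - analyzed
  expect_identical(nrow(got), res$report$enrolled - res$report$analyzed)
  # a 12-year-old is excluded (enrollment requires age > 12)
  co$patients$age[co$patients$patient_id == "D_child"] <- 12
  expect_true("D_child" %in% apply_eligibility(co)$report$excluded$patient_id)
})

test_that("worst_in_window matches a brute-force scan on random series", {
  expect_equal(worst_in_window(c(0, 6, 12), c(160, 140, 155), c(0, 24),
                               "platelets"), 140)
  expect_equal(worst_in_window(c(0, 12), c(1.0, 2.5), c(0, 24), "bilirubin"), 2.5)
  expect_true(is.na(worst_in_window(c(30, 40), c(1, 2), c(0, 24), "platelets")))
  expect_error(worst_in_window(0, 1, c(0, 24), "lactate"), "unknown parameter")
  set.seed(103)
  for (rep in 1:200) {
    n <- sample(1:12, 1)
    t <- sort(runif(n, 0, 48))
    v <- ifelse(runif(n) < 0.3, NA, runif(n, 0, 100))
    p <- sample(names(msofa:::worst_direction), 1)
    win <- sort(runif(2, 0, 48))
    got <- worst_in_window(t, v, win, p)
    inw <- which(t >= win[1] & t < win[2] & !is.na(v))
    if (!length(inw)) {
      expect_true(is.na(got))
    } else {
      oracle <- if (msofa:::worst_direction[[p]] == "min") min(v[inw]) else max(v[inw])
      expect_identical(got, oracle)
    }
  }
})

test_that("single-gap imputation fills isolated interior gaps only, idempotently", {
  expect_equal(as.numeric(impute_single_gap(c(2, NA, 4))), c(2, 3, 4))
  x <- impute_single_gap(c(NA, 5))
  expect_true(is.na(x[1]))
  expect_identical(attr(x, "unfilled"), 1L)
  expect_equal(as.numeric(impute_single_gap(c(1, 2, 3))), c(1, 2, 3))
  # runs of >= 2 absences and edges stay absent
  x <- impute_single_gap(c(1, NA, NA, 4, NA, 6, NA))
  expect_equal(as.numeric(x), c(1, NA, NA, 4, 5, 6, NA))
  expect_identical(attr(x, "unfilled"), c(2L, 3L, 7L))
  set.seed(104)
  for (rep in 1:100) {
    v <- ifelse(runif(8) < 0.4, NA_real_, runif(8))
    once <- impute_single_gap(v)
    twice <- impute_single_gap(as.numeric(once))
    expect_identical(as.numeric(once), as.numeric(twice))    # idempotent
    expect_identical(v[!is.na(v)], as.numeric(once)[!is.na(v)])  # present values untouched
  }
})

test_that("score_timepoints reproduces hand-scored patients and the derived family", {
  co <- make_tiny_cohort()
  sc <- score_cohort(co)
  a <- sc[sc$patient_id == "A", ]
  expect_identical(c(a$initial, a$delta, a$highest), c(0L, 0L, 0L))
  # patient B hand-scored: T0 resp 3 (worst ratio 80), coag 3 (40), liver 3
  # (7.0), cardio 4 (norepinephrine 0.2), cns 3 (GCS 6), renal 3 (creatinine
  # 3.8, urine 300); normal at 48 h
  b <- sc[sc$patient_id == "B", ]
  expect_identical(b$t0_total, 19L)
  expect_identical(b$at48, 0L)
  expect_equal(b$mean_score, 9.5)
  expect_identical(b$highest, 19L)
  expect_identical(b$delta, -19L)
  expect_identical(b$total_sum, 19L)
  # patient C exercises the platelet gap imputation: (160 + 90)/2 = 125 -> 1
  cc <- sc[sc$patient_id == "C", ]
  expect_identical(cc$t0_coagulation, 1L)
  expect_identical(cc$t0_total, 1L)
  expect_identical(cc$t48_total, 12L)
})

test_that("extreme synthetic timepoints force the stated derived-family values", {
  worst <- data.frame(patient_id = "X", time_h = c(2, 30),
                      spo2 = c(50, 97), pao2 = NA,
                      device = c("ventilator", "room_air"),
                      flow = NA, fio2 = c(1, NA),
                      map = c(40, 85), gcs = c(3, 15),
                      platelets = c(10, 250), bilirubin = c(15, 0.5),
                      creatinine = c(6, 0.8), urine_output = c(100, 2000),
                      dopamine = c(20, 0), dobutamine = 0,
                      norepinephrine = c(0.5, 0), stringsAsFactors = FALSE)
  sc <- score_timepoints(worst)
  expect_identical(sc$initial, 24L)
  expect_identical(sc$at48, 0L)
  expect_equal(sc$mean_score, 12)
  expect_identical(sc$highest, 24L)
  expect_identical(sc$delta, -24L)
  expect_identical(sc$total_sum, 24L)
})

test_that("missing organs score zero with flags, or drop the patient in strict mode", {
  co <- make_tiny_cohort()
  # remove all GCS for patient A -> CNS unscorable at both timepoints
  co$observations$gcs[co$observations$patient_id == "A"] <- NA
  sc <- score_cohort(co)
  a <- sc[sc$patient_id == "A", ]
  expect_identical(a$t0_cns, NA_integer_)
  expect_identical(a$t0_n_missing, 1L)
  expect_identical(a$t48_n_missing, 1L)
  sc_strict <- score_cohort(co, strict_missing = TRUE)
  expect_false("A" %in% sc_strict$patient_id)
  expect_identical(attr(sc_strict, "dropped")$reason, "missing_component")
})

test_that("a patient with an empty window is flagged unscorable and dropped", {
  co <- make_tiny_cohort()
  co$observations <- co$observations[!(co$observations$patient_id == "A" &
                                         co$observations$time_h >= 24), ]
  sc <- score_cohort(co)
  expect_false("A" %in% sc$patient_id)
  dropped <- attr(sc, "dropped")
  expect_identical(dropped$reason[dropped$patient_id == "A"], "empty_window")
})
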