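# brute-force all-pairs concordance, the independent oracle for the AUROC
auc_bruteforce <- function(scores, outcomes) {
  x <- scores[outcomes == 1]; y <- scores[outcomes == 0]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

test_that("empirical AUROC equals the all-pairs concordance on worked examples", {
  expect_equal(empirical_auroc(c(3, 5, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(empirical_auroc(rep(2, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(empirical_auroc(c(2, 1, 1, 3), c(1, 1, 0, 0)), 0.375)
  expect_error(empirical_auroc(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("empirical AUROC matches brute force on random cohorts", {
  set.seed(201)
  for (rep in 1:100) {
    n <- sample(4:60, 1)
    o <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    expect_equal(empirical_auroc(s, o), auc_bruteforce(s, o))
  }
})

test_that("AUROC is invariant under strictly increasing score transforms", {
  set.seed(202)
  for (rep in 1:50) {
    n <- 40
    o <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- rnorm(n)
    a0 <- empirical_auroc(s, o)
    expect_equal(empirical_auroc(exp(s), o), a0)
    expect_equal(empirical_auroc(rank(s, ties.method = "min"), o), a0)
    expect_equal(empirical_auroc(2 * s + 7, o), a0)
  }
})

test_that("DeLong CI agrees with the reference implementation and behaves at edges", {
  set.seed(203)
  for (rep in 1:20) {
    n <- sample(c(30, 80, 118), 1)
    o <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.45))
    s <- rnorm(n) + 0.8 * o
    ci <- delong_ci(s, o)
    r <- pROC::roc(o, s, quiet = TRUE, direction = "<")
    ref <- as.numeric(pROC::ci.auc(r, method = "delong"))
    expect_equal(ci$auc, as.numeric(pROC::auc(r)))
    expect_equal(ci$ci_low, max(0, ref[1]))
    expect_equal(ci$ci_high, min(1, ref[3]))
    expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
  }
  # perfect separation: upper bound clips to 1
  o <- rep(0:1, each = 50)
  s <- c(rnorm(50), rnorm(50) + 100)
  ci <- delong_ci(s, o)
  expect_equal(ci$auc, 1)
  expect_equal(ci$ci_high, 1)
  # no signal: CI contains 0.5
  s0 <- rep(1:50, 2)
  ci0 <- delong_ci(s0, o)
  expect_true(ci0$ci_low <= 0.5 && 0.5 <= ci0$ci_high)
  expect_error(delong_ci(c(1, 2, 3), c(1, 0, 0)), ">= 2")
})

test_that("DeLong CI width shrinks with n at fixed signal", {
  set.seed(204)
  width <- vapply(c(50, 200, 800), function(n) {
    w <- vapply(1:20, function(i) {
      o <- rep(0:1, length.out = n)
      s <- rnorm(n) + 0.9 * o
      ci <- delong_ci(s, o)
      ci$ci_high - ci$ci_low
    }, numeric(1))
    mean(w)
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("bootstrap CI method is available and brackets the point estimate", {
  set.seed(205)
  o <- rep(0:1, each = 40)
  s <- rnorm(80) + 0.7 * o
  ci <- delong_ci(s, o, method = "bootstrap", boot_reps = 400)
  expect_identical(ci$method, "bootstrap")
  expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
})

test_that("paired DeLong test matches the reference and handles identity", {
  set.seed(206)
  o <- c(rep(1, 25), rep(0, 35))
  a <- rnorm(60) + o
  expect_equal(delong_paired_test(a, a, o)$p_value, 1)
  b <- rnorm(60) + 0.4 * o
  got <- delong_paired_test(a, b, o)
  ref <- pROC::roc.test(pROC::roc(o, a, quiet = TRUE, direction = "<"),
                        pROC::roc(o, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(got$p_value, ref$p.value)
  expect_equal(got$difference, as.numeric(ref$estimate[1] - ref$estimate[2]))
  expect_error(delong_paired_test(a[-1], b, o), "same length")
})

test_that("paired DeLong test has power against a real AUC difference at n = 118", {
  set.seed(207)
  o <- rep(0:1, length.out = 118)
  perfect <- o + seq(0, 0.5, length.out = 118)  # outcome-perfect score
  noise <- rnorm(118)
  expect_lt(delong_paired_test(perfect, noise, o)$p_value, 0.05)
})

test_that("continuous comparisons reproduce nulls, separation, and method choice", {
  g <- rep(c("s", "d"), each = 10)
  same <- rep(1:10, 2)
  expect_equal(group_compare_continuous(same, g, method = "t")$p_value, 1)
  sep <- c(rep(0, 10), rep(10, 10))
  cc <- group_compare_continuous(sep, g, method = "t")
  expect_lt(cc$p_value, 1e-10)
  expect_equal(cc$groups$s[["mean"]] - cc$groups$d[["mean"]], -10)
  # auto falls back to Mann-Whitney for clearly non-normal data
  set.seed(208)
  skewed <- c(rexp(40)^3, rexp(40)^3 + 2)
  cc2 <- group_compare_continuous(skewed, rep(c("s", "d"), each = 40))
  expect_identical(cc2$test, "mann_whitney")
  expect_true(all(cc2$normality_p < 0.05))
  # and stays with t for normal data
  cc3 <- group_compare_continuous(c(rnorm(40), rnorm(40)),
                                  rep(c("s", "d"), each = 40))
  expect_identical(cc3$test, "t")
  expect_error(group_compare_continuous(1:5, rep("s", 5)), "two groups")
})

test_that("categorical comparison gives Pearson chi-square on printed tables", {
  null_tab <- matrix(10, 2, 2)
  cc <- group_compare_categorical(null_tab)
  expect_equal(cc$statistic, 0)
  expect_equal(cc$p_value, 1)
  # mechanical-ventilation table: ventilated 47/53, not ventilated 16/2
  vent <- matrix(c(47, 16, 53, 2), 2)
  ccv <- group_compare_categorical(vent)
  # hand Pearson: sum (O-E)^2/E
  E <- outer(rowSums(vent), colSums(vent)) / sum(vent)
  expect_equal(ccv$statistic, sum((vent - E)^2 / E))
  expect_lt(ccv$p_value, 0.05)
  expect_warning(cc3 <- group_compare_categorical(matrix(c(5, 5, 0, 0, 3, 7), 2)),
                 "empty")
  expect_equal(cc3$df, 1, ignore_attr = TRUE)
  expect_error(group_compare_categorical(matrix(0, 2, 2)), "all-zero")
})

test_that("contingency odds ratio matches hand arithmetic with Woolf intervals", {
  or <- contingency_odds_ratio(matrix(c(24, 31, 4, 59), 2))
  expect_equal(or$odds_ratio, (24 * 59) / (4 * 31))  # ~ 11.42
  expect_equal(round(or$odds_ratio, 2), 11.42)
  expect_false(or$corrected)
  expect_true(or$ci_low <= or$odds_ratio && or$odds_ratio <= or$ci_high)
  expect_equal(contingency_odds_ratio(matrix(1, 2, 2))$odds_ratio, 1)
  z <- contingency_odds_ratio(matrix(c(5, 3, 0, 7), 2))
  expect_true(z$corrected)
  expect_true(is.finite(z$odds_ratio))
})

test_that("logistic fit recovers truth, matches the 2x2 odds ratio, flags separation", {
  set.seed(209)
  n <- 10000
  x <- rnorm(n)
  # null: outcome independent of covariate
  y0 <- rbinom(n, 1, 0.4)
  f0 <- fit_logistic(y0, data.frame(x = x))
  expect_lt(abs(f0$table$estimate[f0$table$term == "x"]), 0.1)
  # recovery: intercept -1, slope 0.8
  y1 <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  f1 <- fit_logistic(y1, data.frame(x = x))
  expect_lt(abs(f1$table$estimate[1] - (-1)), 0.1)
  expect_lt(abs(f1$table$estimate[2] - 0.8), 0.1)
  expect_true(f1$converged)
  expect_true(all(f1$table$ci_low <= f1$table$odds_ratio &
                    f1$table$odds_ratio <= f1$table$ci_high))
  # equivalence with the contingency odds ratio on a binary covariate
  xb <- rbinom(200, 1, 0.5)
  yb <- rbinom(200, 1, plogis(-0.5 + 1 * xb))
  tab <- table(factor(xb, 1:0), factor(yb, 1:0))  # exposure rows, outcome cols
  fb <- fit_logistic(yb, data.frame(x = xb))
  or <- contingency_odds_ratio(tab)
  expect_equal(exp(fb$table$estimate[fb$table$term == "x"]), or$odds_ratio,
               tolerance = 1e-6)
  # separation
  ys <- as.integer(x > 0)
  fs <- fit_logistic(ys, data.frame(x = x))
  expect_true(fs$separation)
  expect_true(all(is.na(fs$table$p_value)))
  # guards
  expect_error(fit_logistic(y0, data.frame(k = rep(1, n))), "constant")
  expect_error(fit_logistic(y0, data.frame(x = x, x2 = 2 * x)), "collinear")
})
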