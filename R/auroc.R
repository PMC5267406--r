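check_binary_outcome <- function(outcomes) {
  o <- as.integer(outcomes)
  if (!all(o %in% c(0L, 1L))) stop("outcomes must be binary (0/1)")
  if (length(unique(o)) < 2)
    stop("both outcome classes must be present")
  o
}

#' Empirical AUROC (Mann-Whitney concordance)
#'
#' The area under the empirical ROC curve equals the probability that a
#' randomly chosen positive (died) outscores a randomly chosen negative
#' (survived), ties counting one half. Computed via midranks, which is
#' algebraically identical to the all-pairs average.
#'
#' @param scores numeric predictor, higher = more likely positive.
#' @param outcomes binary vector (1/TRUE = positive class, i.e. died).
#' @return AUC in `[0, 1]`.
#' @examples
#' empirical_auroc(c(3, 5, 1, 2), c(1, 1, 0, 0))  # 1
#' @export
empirical_auroc <- function(scores, outcomes) {
  o <- check_binary_outcome(outcomes)
  stopifnot(length(scores) == length(o), !anyNA(scores))
  r <- rank(scores)
  m <- sum(o == 1L); n <- sum(o == 0L)
  (sum(r[o == 1L]) - m * (m + 1) / 2) / (m * n)
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties half), and vice versa. The basis of the DeLong variance estimator.
placement_values <- function(scores, o) {
  x <- scores[o == 1L]; y <- scores[o == 0L]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' AUC confidence interval (DeLong or stratified bootstrap)
#'
#' The default variance is the DeLong structural-components estimator:
#' `var(AUC) = S10/m + S01/n`, with `S10`, `S01` the sample variances of the
#' positive- and negative-class placement values, giving a normal-theory
#' interval clipped to `[0, 1]`. `method = "bootstrap"` resamples patients
#' within outcome strata instead and takes percentile bounds.
#'
#' @param scores numeric predictor.
#' @param outcomes binary outcome (1 = died).
#' @param level confidence level (default 0.95).
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param boot_reps bootstrap replicates (default 2000).
#' @return An object of class `msofa_auc`: list with `auc`, `ci_low`,
#'   `ci_high`, `se`, `level`, `method`, `m` (positives), `n` (negatives).
#' @export
delong_ci <- function(scores, outcomes, level = 0.95,
                      method = c("delong", "bootstrap"), boot_reps = 2000) {
  method <- match.arg(method)
  o <- check_binary_outcome(outcomes)
  m <- sum(o == 1L); n <- sum(o == 0L)
  if (m < 2 || n < 2)
    stop("each outcome class needs >= 2 members; consider a bootstrap over a",
         " larger cohort")
  if (method == "delong") {
    pv <- placement_values(scores, o)
    v <- stats::var(pv$v10) / m + stats::var(pv$v01) / n
    se <- sqrt(v)
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(pv$auc - z * se, pv$auc + z * se)
    auc <- pv$auc
  } else {
    auc <- empirical_auroc(scores, o)
    ipos <- which(o == 1L); ineg <- which(o == 0L)
    reps <- vapply(seq_len(boot_reps), function(b) {
      idx <- c(sample(ipos, m, replace = TRUE), sample(ineg, n, replace = TRUE))
      empirical_auroc(scores[idx], o[idx])
    }, numeric(1))
    se <- stats::sd(reps)
    ci <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
  }
  structure(list(auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[2]),
                 se = se, level = level, method = method, m = m, n = n),
            class = "msofa_auc")
}

#' @export
print.msofa_auc <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%d%% CI %.3f-%.3f, %s; %d died / %d survived)\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high, x$method,
              x$m, x$n))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score variants measured on the same patients,
#' using the covariance of their placement values: the variance of the AUC
#' difference is `(S10_aa + S10_bb - 2 S10_ab)/m + (S01_aa + S01_bb -
#' 2 S01_ab)/n`, and the two-sided p-value comes from the normal reference.
#'
#' @param scores_a,scores_b the two score vectors (same patients, same order).
#' @param outcomes binary outcome (1 = died).
#' @return A list with `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, outcomes) {
  o <- check_binary_outcome(outcomes)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(o))
    stop("scores_a, scores_b and outcomes must have the same length")
  m <- sum(o == 1L); n <- sum(o == 0L)
  pa <- placement_values(scores_a, o)
  pb <- placement_values(scores_b, o)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    z <- if (abs(d) < .Machine$double.eps) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  p <- 2 * stats::pnorm(-abs(z))
  list(auc_a = pa$auc, auc_b = pb$auc, difference = d,
       se = sqrt(max(v, 0)), z = z, p_value = p)
}

#' Empirical ROC curve coordinates
#'
#' Sensitivity/specificity pairs at every distinct threshold, for plotting or
#' export.
#'
#' @param scores numeric predictor.
#' @param outcomes binary outcome (1 = died).
#' @return Data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_coordinates <- function(scores, outcomes) {
  o <- check_binary_outcome(outcomes)
  th <- c(-Inf, sort(unique(scores)), Inf)
  data.frame(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(scores[o == 1L] >= t), numeric(1)),
    specificity = vapply(th, function(t) mean(scores[o == 0L] < t), numeric(1)))
}
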