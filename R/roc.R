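# ROC analysis with DeLong variance, plus the validation-side metric
# helpers built on it.

# Placement values of the DeLong estimator. For each case, the fraction
# of controls it outranks (ties at half); symmetrically for controls.
delong_components <- function(scores, case) {
  x <- scores[case]
  y <- scores[!case]
  m <- length(x); n <- length(y)
  if (!m || !n) {
    abort("Both classes must be present.", class = "uripanel_validation_error")
  }
  r_all <- rank(c(x, y))
  r_x <- rank(x)
  r_y <- rank(y)
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  auc <- mean(v10)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC curve with DeLong variance
#'
#' Full ROC curve over all distinct score thresholds (positive call:
#' score >= threshold), with the tie-aware AUC (Mann-Whitney U over
#' n_case * n_control, equal to the trapezoidal area of the stored
#' curve) and the DeLong variance estimator with a normal-approximation
#' confidence interval clipped to \[0, 1\].
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param outcomes factor/character with positive level `"sig"`.
#' @param level confidence level for the AUC interval (default 0.95).
#' @return A `roc_result`: list with `curve` (tibble `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `auc_var`, `ci_lo`, `ci_hi`.
#' @export
roc_curve <- function(scores, outcomes, level = 0.95) {
  case <- outcomes == "sig"
  comp <- delong_components(scores, case)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[case] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!case] < t), numeric(1))
  v <- var(comp$v10) / comp$m + var(comp$v01) / comp$n
  if (!is.finite(v)) v <- 0
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(
    curve = tibble::tibble(threshold = thr, sensitivity = sens,
                           specificity = spec),
    auc = comp$auc, auc_var = v,
    ci_lo = max(0, comp$auc - z * sqrt(v)),
    ci_hi = min(1, comp$auc + z * sqrt(v)),
    level = level, n_case = comp$m, n_control = comp$n
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%.0f%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, 100 * x$level, x$ci_lo, x$ci_hi, x$n_case, x$n_control))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_var = x$auc_var, ci_lo = x$ci_lo,
                 ci_hi = x$ci_hi, level = x$level,
                 n_case = x$n_case, n_control = x$n_control)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.2f (%.0f%% CI %.2f-%.2f)", object$auc,
                      100 * object$level, object$ci_lo, object$ci_hi)
    ) +
    ggplot2::theme_minimal()
}

#' Sensitivity and specificity at a cutoff
#'
#' Confusion counts at "positive iff score >= cutoff" with Clopper-
#' Pearson (exact binomial) confidence intervals.
#'
#' @param scored a `scored_cohort` from [score_samples()], or any data
#'   frame with `score` and `outcome` columns.
#' @param cutoff decision threshold; defaults to the scored cohort's own.
#' @param level confidence level.
#' @return Tibble with one row per metric (`sensitivity`,
#'   `specificity`): `k`, `n`, `estimate`, `lo`, `hi`; the confusion
#'   counts are attached as attribute `"confusion"`.
#' @export
sens_spec_at_cutoff <- function(scored, cutoff = attr(scored, "cutoff"),
                                level = 0.95) {
  if (is.null(cutoff)) abort("No cutoff given or attached to `scored`.")
  case <- scored$outcome == "sig"
  pos <- scored$score >= cutoff
  tp <- sum(pos & case); fn <- sum(!pos & case)
  tn <- sum(!pos & !case); fp <- sum(pos & !case)
  if (tp + fn == 0 || tn + fp == 0) {
    abort("Both classes must be present.", class = "uripanel_validation_error")
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(clopper_pearson(tp, tp + fn, level), metric = "sensitivity"),
    dplyr::mutate(clopper_pearson(tn, tn + fp, level), metric = "specificity")
  )
  out <- dplyr::relocate(out, "metric")
  attr(out, "confusion") <- tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn)
  out
}

#' DeLong test for two correlated AUCs
#'
#' Paired nonparametric comparison of two classifiers scored on the same
#' samples, via the covariance of their placement-value (DeLong) AUC
#' estimators. A degenerate zero-variance difference (e.g. comparing a
#' score with itself) returns p = 1 by convention.
#'
#' @param scores_a,scores_b paired score vectors over identical samples.
#' @param outcomes outcome factor with positive level `"sig"`.
#' @return Tibble with `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, outcomes) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(outcomes)) {
    abort("scores_a, scores_b and outcomes must have equal length.",
          class = "uripanel_validation_error")
  }
  case <- outcomes == "sig"
  a <- delong_components(scores_a, case)
  b <- delong_components(scores_b, case)
  var_diff <- (var(a$v10) + var(b$v10) - 2 * cov(a$v10, b$v10)) / a$m +
    (var(a$v01) + var(b$v01) - 2 * cov(a$v01, b$v01)) / a$n
  delta <- a$auc - b$auc
  if (!is.finite(var_diff) || var_diff <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_diff)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  tibble::tibble(auc_a = a$auc, auc_b = b$auc, delta = delta, z = z,
                 p_value = p)
}

#' @importFrom stats cov
NULL
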