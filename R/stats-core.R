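# Rank-based and exact-binomial statistical engines shared by the
# discovery and evaluation stages.

# Left-censoring convention: a value of exactly 0 in a log-scale matrix
# encodes "not detected" and enters rank statistics tied below every
# detected value.
censor_to_rankable <- function(x) {
  x[x == 0] <- -Inf
  x
}

# Tie-corrected normal deviate of the two-sample rank-sum statistic.
# U counts pairs (x over y) with ties at half weight.
wilcoxon_core <- function(x, y, continuity = TRUE) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(r)
  tie_sum <- sum(ties^3 - ties)
  sigma2 <- n * m / 12 * ((N + 1) - tie_sum / (N * (N - 1)))
  mu <- n * m / 2
  if (sigma2 <= 0) return(list(U = U, z = 0, sigma2 = 0))
  cc <- if (continuity) sign(U - mu) * 0.5 else 0
  z <- (U - mu - cc) / sqrt(sigma2)
  list(U = U, z = z, sigma2 = sigma2)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' The per-peptide test of the discovery stage. With no ties and a
#' combined sample size at or below `exact_threshold`, the two-sided p
#' comes from the exact null distribution of the Mann-Whitney U
#' statistic (doubled smaller tail, capped at 1); otherwise from the
#' normal approximation with tie correction and continuity correction.
#' Values of exactly 0 are treated as left-censored non-detects tied
#' below all detected values.
#'
#' @param x,y numeric values of the two groups (each non-empty).
#' @param exact_threshold largest combined sample size for the exact
#'   path (default 12).
#' @param censored_zero treat exact zeros as left-censored non-detects.
#' @return `wilcoxon_rank_sum()` returns the two-sided p-value;
#'   `mann_whitney_u()` returns a list with `U` (pairs where `x` exceeds
#'   `y`, ties at half weight) and `p`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)) # exact: 0.1
wilcoxon_rank_sum <- function(x, y, exact_threshold = 12,
                              censored_zero = TRUE) {
  mann_whitney_u(x, y, exact_threshold, censored_zero)$p
}

#' @rdname wilcoxon_rank_sum
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 12,
                           censored_zero = TRUE) {
  if (!length(x) || !length(y)) {
    abort("Both groups must be non-empty.", class = "uripanel_validation_error")
  }
  if (censored_zero) {
    x <- censor_to_rankable(x)
    y <- censor_to_rankable(y)
  }
  n <- length(x); m <- length(y); N <- n + m
  core <- wilcoxon_core(x, y)
  no_ties <- !anyDuplicated(c(x, y))
  if (no_ties && N <= exact_threshold) {
    U <- core$U
    p <- min(1, 2 * min(pwilcox(U, n, m), 1 - pwilcox(U - 1, n, m)))
  } else if (core$sigma2 == 0) {
    p <- 1
  } else {
    p <- min(1, 2 * pnorm(-abs(core$z)))
  }
  list(U = core$U, p = max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: the i-th smallest p becomes
#' min over j >= i of p_(j) * m / j, capped at 1; input order is
#' preserved.
#'
#' @param pvals raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1].", class = "uripanel_validation_error")
  }
  p.adjust(pvals, method = "BH")
}

#' Clopper-Pearson exact binomial interval
#'
#' Exact (beta-quantile) two-sided confidence interval for a proportion,
#' the convention behind "exact binomial" sensitivity/specificity CIs.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return Tibble with `k`, `n`, `estimate`, `lo`, `hi`, `level`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (any(n < 1) || any(k < 0) || any(k > n) ||
      any(k %% 1 != 0) || any(n %% 1 != 0)) {
    abort("Need integers 0 <= k <= n with n >= 1.",
          class = "uripanel_validation_error")
  }
  alpha <- 1 - level
  lo <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble::tibble(k = k, n = n, estimate = k / n, lo = lo, hi = hi,
                 level = level)
}

#' Kruskal-Wallis rank-sum test across strata
#'
#' Tie-corrected H statistic with a chi-squared reference on k - 1
#' degrees of freedom; used to compare classifier scores across Gleason
#' strata. With all observations equal the tie correction degenerates
#' and p is 1 by convention.
#'
#' @param values numeric observations.
#' @param groups grouping vector, at least two non-empty groups.
#' @return Tibble with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) {
    abort("Need at least two non-empty groups.",
          class = "uripanel_validation_error")
  }
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1, p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Pearson chi-squared test for an r x k count table
#'
#' Without continuity correction by default; `yates = TRUE` enables the
#' Yates correction for 2 x 2 tables. Used for the categorical rows of
#' cohort summary tables.
#'
#' @param counts matrix of non-negative integer counts.
#' @param yates apply the continuity correction (2 x 2 only).
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
chi_squared_2xk <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts %% 1 != 0)) {
    abort("Counts must be non-negative integers.",
          class = "uripanel_validation_error")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Degenerate margin: a row or column of the table is all zero.",
          class = "uripanel_validation_error")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = yates))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}
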