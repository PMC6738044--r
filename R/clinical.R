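#' Logistic regression of clinical predictors
#'
#' Maximum-likelihood logistic regression of the binary outcome
#' (significant PCa) on a chosen set of predictors, reporting per-unit
#' odds ratios and Wald p-values. Rows with missing predictor values are
#' dropped (complete-case) and the retained n is reported. Perfect
#' separation is flagged with a warning rather than an error; rank
#' deficiency is an error naming the collinear predictors.
#'
#' @param data data frame holding the outcome and predictors (e.g. a
#'   sample table joined with classifier scores).
#' @param predictors character vector of predictor column names.
#' @param outcome name of the binary outcome column (default
#'   `"outcome"`, positive level `"sig"`).
#' @return A `logistic_fit`: list with the `glm` object, `n_used`,
#'   `n_dropped`, `separation` flag.
#' @export
fit_logistic <- function(data, predictors, outcome = "outcome") {
  missing_cols <- setdiff(c(predictors, outcome), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  y <- data[[outcome]]
  y01 <- if (is.factor(y) || is.character(y)) as.integer(y == "sig") else as.integer(y)
  if (length(unique(y01)) < 2) {
    abort("Outcome is degenerate (one class).",
          class = "uripanel_validation_error")
  }
  df <- data[, predictors, drop = FALSE]
  df$.outcome <- y01
  keep <- complete.cases(df)
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  form <- stats::as.formula(paste(".outcome ~",
                                  paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- suppressWarnings(glm(form, family = binomial(), data = df,
                              control = list(maxit = 100)))
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    abort(paste0("Rank-deficient fit; collinear predictor(s): ",
                 paste(names(coef(fit))[aliased], collapse = ", ")),
          class = "uripanel_validation_error")
  }
  probs <- stats::fitted(fit)
  separation <- any(probs > 1 - 1e-8) || any(probs < 1e-8) ||
    any(abs(coef(fit)[-1]) > 15)
  if (separation) {
    warn("Possible perfect separation: coefficients are unreliable.")
  }
  structure(list(glm = fit, n_used = nrow(df), n_dropped = dropped,
                 predictors = predictors, separation = separation,
                 converged = fit$converged),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %s ~ %s  (n = %d, %d dropped)%s\n",
              "outcome", paste(x$predictors, collapse = " + "),
              x$n_used, x$n_dropped,
              if (x$separation) "  [separation flagged]" else ""))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  sm <- summary(x$glm)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    odds_ratio = exp(sm[, "Estimate"]),
    p_value = sm[, "Pr(>|z|)"]
  )
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_dropped = x$n_dropped,
                 converged = x$converged, separation = x$separation,
                 deviance = x$glm$deviance, aic = x$glm$aic)
}

#' Nomogram: combined risk from a logistic fit
#'
#' Wraps a converged [fit_logistic()] (conventionally on biomarker
#' score, PSA and age) as a risk function: the inverse logit of the
#' fitted linear predictor, with an exportable coefficient table.
#'
#' @param fit a converged `logistic_fit`.
#' @return A `nomogram` with elements `coefficients` (tibble) and
#'   `risk`, a function mapping a data frame of predictors to
#'   probabilities in (0, 1).
#' @export
build_nomogram <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) {
    abort("Logistic fit did not converge; refusing to build a nomogram.")
  }
  coefs <- tidy(fit)
  glm_fit <- fit$glm
  structure(list(
    coefficients = coefs,
    predictors = fit$predictors,
    risk = function(newdata) {
      unname(predict(glm_fit, newdata = newdata, type = "response"))
    }
  ), class = "nomogram")
}

#' @export
print.nomogram <- function(x, ...) {
  cat("<nomogram> risk = inverse-logit of:\n")
  print(x$coefficients[, c("term", "estimate", "odds_ratio", "p_value")])
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit of acting (biopsying) when a model's predicted risk
#' meets the threshold p_t: NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t),
#' evaluated over a threshold grid, alongside the treat-all and
#' treat-none reference strategies. Thresholds must stay strictly below
#' 1 (the odds weight diverges there); the default grid spans the
#' clinically relevant low range.
#'
#' @param data data frame with one probability column per model and the
#'   outcome column.
#' @param models character vector naming the probability columns.
#' @param outcome outcome column name (positive level `"sig"`).
#' @param thresholds risk-threshold grid in (0, 1) (default 0.01-0.50
#'   by 0.01).
#' @return A `net_benefit` tibble: `model`, `threshold`, `net_benefit`,
#'   including rows for `treat_all` and `treat_none`.
#' @export
decision_curve <- function(data, models, outcome = "outcome",
                           thresholds = seq(0.01, 0.50, by = 0.01)) {
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    abort("Thresholds must lie strictly inside (0, 1).",
          class = "uripanel_validation_error")
  }
  missing_cols <- setdiff(c(models, outcome), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  y <- data[[outcome]] == "sig"
  n <- length(y)
  prevalence <- mean(y)
  nb_model <- function(p) {
    vapply(thresholds, function(pt) {
      treat <- p >= pt
      tp <- sum(treat & y)
      fp <- sum(treat & !y)
      tp / n - fp / n * pt / (1 - pt)
    }, numeric(1))
  }
  rows <- purrr::map_dfr(models, function(m) {
    p <- data[[m]]
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      abort(sprintf("Column '%s' must hold probabilities in [0, 1].", m),
            class = "uripanel_validation_error")
    }
    tibble::tibble(model = m, threshold = thresholds, net_benefit = nb_model(p))
  })
  refs <- dplyr::bind_rows(
    tibble::tibble(model = "treat_all", threshold = thresholds,
                   net_benefit = prevalence - (1 - prevalence) *
                     thresholds / (1 - thresholds)),
    tibble::tibble(model = "treat_none", threshold = thresholds,
                   net_benefit = 0)
  )
  out <- dplyr::bind_rows(rows, refs)
  structure(out, class = c("net_benefit", class(out)),
            prevalence = prevalence, n = n)
}

#' @export
autoplot.net_benefit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = .data$net_benefit,
                                       colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.02, attr(object, "prevalence") * 1.2)) +
    ggplot2::labs(x = "Risk threshold", y = "Net benefit") +
    ggplot2::theme_minimal()
}

#' Compare risk models on a common sample set
#'
#' Pairwise DeLong comparisons, per-model ROC summaries and a joint
#' decision-curve table for any set of score columns evaluated on the
#' same samples. When `"psa"` is among the models, samples on
#' 5-alpha-reductase inhibitors are excluded from every comparison
#' involving PSA (the drug halves measured PSA), and the reduced n is
#' reported.
#'
#' @param data data frame with one column per model plus `outcome` and,
#'   if present, `fivear_inhibitor`.
#' @param models named character vector or character vector of score
#'   column names.
#' @param probability_models subset of `models` whose columns are
#'   probabilities usable for decision curves (default: those with all
#'   values in \[0, 1\]).
#' @param thresholds DCA grid.
#' @return A `model_comparison`: list with `aucs` (per-model tibble),
#'   `pairs` (pairwise DeLong tibble, with `n` per pair), and
#'   `decision_curves` (a [decision_curve()] result or `NULL`).
#' @export
compare_models <- function(data, models,
                           probability_models = NULL,
                           thresholds = seq(0.01, 0.50, by = 0.01)) {
  missing_cols <- setdiff(models, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing model column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  has_5ari <- "fivear_inhibitor" %in% names(data)
  psa_like <- models[models %in% c("psa", "psa_prob")]
  restrict <- function(m1, m2 = NULL) {
    keep <- rep(TRUE, nrow(data))
    if (has_5ari && length(psa_like) &&
        any(c(m1, m2) %in% psa_like)) {
      keep <- !data$fivear_inhibitor
    }
    keep <- keep & !is.na(data[[m1]]) &
      (if (is.null(m2)) TRUE else !is.na(data[[m2]]))
    keep
  }
  aucs <- purrr::map_dfr(models, function(m) {
    keep <- restrict(m)
    r <- roc_curve(data[[m]][keep], data$outcome[keep])
    tibble::tibble(model = m, auc = r$auc, ci_lo = r$ci_lo, ci_hi = r$ci_hi,
                   n = sum(keep))
  })
  pairs <- tidyr::expand_grid(a = models, b = models) |>
    dplyr::filter(.data$a < .data$b)
  pair_res <- purrr::pmap_dfr(pairs, function(a, b) {
    keep <- restrict(a, b)
    dt <- delong_test(data[[a]][keep], data[[b]][keep], data$outcome[keep])
    dplyr::mutate(dt, model_a = a, model_b = b, n = sum(keep),
                  .before = 1)
  })
  if (is.null(probability_models)) {
    probability_models <- models[purrr::map_lgl(models, function(m) {
      v <- data[[m]]
      all(is.finite(v[!is.na(v)]) & v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1)
    })]
  }
  dca <- NULL
  if (length(probability_models)) {
    keep <- Reduce(`&`, purrr::map(probability_models, restrict))
    dca <- decision_curve(data[keep, , drop = FALSE], probability_models,
                          thresholds = thresholds)
  }
  structure(list(aucs = aucs, pairs = pair_res, decision_curves = dca),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\nAUCs:\n")
  print(x$aucs)
  cat("Pairwise DeLong tests:\n")
  print(x$pairs)
  invisible(x)
}
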