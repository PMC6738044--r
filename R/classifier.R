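#' Train the SVM panel classifier
#'
#' Combines the panel peptides into a support-vector-machine classifier,
#' each peptide one dimension of the feature space. The feature pipeline
#' is frozen on the discovery set only: censored zeros (non-detects)
#' enter as that peptide's minimum detected discovery log-intensity minus
#' `zero_offset`; features are then centred and scaled by
#' discovery-set constants. Scores are oriented so that higher means more
#' likely significant PCa. A Platt-type logistic map fitted on discovery
#' scores supplies calibrated probabilities, and the decision cutoff is
#' established on the discovery set via [select_cutoff()].
#'
#' @param matrix log-scale [peptide_matrix()] holding all samples.
#' @param samples validated sample table.
#' @param split a [stratified_split()] or character vector of discovery
#'   sample ids; only these samples influence the model.
#' @param panel a [discover_panel()] result (or tibble with
#'   `peptide_id`); must be non-empty.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF kernel width; default `1 / n_panel`.
#' @param zero_offset log-units subtracted below the discovery minimum
#'   for censored zeros (default 1).
#' @param cutoff_criterion,target passed to [select_cutoff()].
#' @return An `svm_panel_model`.
#' @export
train_svm <- function(matrix, samples, split, panel,
                      kernel = c("radial", "linear"),
                      cost = 1, gamma = NULL, zero_offset = 1,
                      cutoff_criterion = c("youden", "target_sensitivity"),
                      target = NULL) {
  kernel <- match.arg(kernel)
  cutoff_criterion <- match.arg(cutoff_criterion)
  if (!nrow(panel)) {
    abort("Cannot train on an empty panel.", class = "uripanel_validation_error")
  }
  if (matrix$scale != "log") {
    abort("train_svm expects a log-scale matrix.", class = "uripanel_scale_error")
  }
  discovery_ids <- if (inherits(split, "split_assignment")) {
    split_ids(split, "discovery")
  } else {
    as.character(split)
  }
  feature_ids <- panel$peptide_id
  missing_cols <- setdiff(feature_ids, matrix$features$peptide_id)
  if (length(missing_cols)) {
    abort(paste0("Panel peptide(s) absent from the matrix: ",
                 paste(missing_cols, collapse = ", ")),
          class = "uripanel_validation_error")
  }
  disc <- subset_samples(matrix, discovery_ids)
  X <- disc$intensity[, feature_ids, drop = FALSE]
  det_min <- apply(X, 2, function(v) if (any(v > 0)) min(v[v > 0]) else NA_real_)
  fallback <- if (all(is.na(det_min))) 0 else min(det_min, na.rm = TRUE)
  det_min[is.na(det_min)] <- fallback
  floors <- det_min - zero_offset

  outcome <- samples$outcome[match(discovery_ids, samples$sample_id)]
  if (nlevels(droplevels(outcome)) < 2) {
    abort("Discovery set must contain both outcome classes.",
          class = "uripanel_validation_error")
  }
  Z <- floor_and_scale(X, floors, center = NULL, scale = NULL)
  center <- colMeans(Z)
  scl <- apply(Z, 2, sd)
  scl[scl == 0] <- 1
  Z <- scale(Z, center = center, scale = scl)

  if (is.null(gamma)) gamma <- 1 / length(feature_ids)
  fit <- e1071::svm(x = Z, y = outcome, kernel = kernel, cost = cost,
                    gamma = gamma, scale = FALSE)
  dv <- as.numeric(attr(predict(fit, Z, decision.values = TRUE),
                        "decision.values"))
  orientation <- if (mean(dv[outcome == "sig"]) >= mean(dv[outcome == "nonsig"])) 1 else -1
  score <- orientation * dv

  # near-separable discovery scores push the Platt slope to its limit;
  # the map stays monotone, so convergence warnings are not informative
  cal <- suppressWarnings(glm(I(outcome == "sig") ~ score, family = binomial()))
  cutoff <- select_cutoff(score, outcome, criterion = cutoff_criterion,
                          target = target)

  structure(list(
    svm = fit, feature_ids = feature_ids,
    panel = tibble::as_tibble(panel),
    floors = floors, center = center, scale = scl,
    orientation = orientation,
    calibration = coef(cal),
    cutoff = cutoff,
    kernel = kernel, cost = cost, gamma = gamma,
    zero_offset = zero_offset,
    cutoff_criterion = cutoff_criterion,
    discovery_ids = discovery_ids
  ), class = "svm_panel_model")
}

# Replace censored zeros by per-feature floors; optionally standardise.
floor_and_scale <- function(X, floors, center, scale) {
  for (j in seq_len(ncol(X))) {
    X[X[, j] == 0, j] <- floors[j]
  }
  if (!is.null(center)) X <- base::scale(X, center = center, scale = scale)
  X
}

#' @export
print.svm_panel_model <- function(x, ...) {
  cat(sprintf(
    "<svm_panel_model> %d-peptide panel, %s kernel (C = %g, gamma = %g), cutoff = %.4f (%s)\n",
    length(x$feature_ids), x$kernel, x$cost, x$gamma, x$cutoff,
    x$cutoff_criterion
  ))
  invisible(x)
}

#' Score samples with a trained panel model
#'
#' Applies the frozen feature pipeline and decision function to any
#' sample set. Validation samples never influence the model: floors,
#' standardisation constants, calibration and cutoff all come from the
#' discovery set at training time.
#'
#' @param model an `svm_panel_model`.
#' @param matrix log-scale [peptide_matrix()] containing every panel
#'   peptide as a column (non-detection is fine; a missing column is an
#'   error).
#' @param samples validated sample table (supplies outcome and Gleason
#'   stratum).
#' @param sample_ids samples to score (default: all rows of `matrix`).
#' @return A `scored_cohort` tibble: `sample_id`, `score`,
#'   `probability`, `predicted` (`"sig"` iff score >= cutoff),
#'   `outcome`, `gleason_stratum`.
#' @export
score_samples <- function(model, matrix, samples, sample_ids = NULL) {
  stopifnot(inherits(model, "svm_panel_model"))
  if (is.null(sample_ids)) sample_ids <- matrix$sample_ids
  missing_cols <- setdiff(model$feature_ids, matrix$features$peptide_id)
  if (length(missing_cols)) {
    abort(paste0("Matrix lacks panel peptide column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "uripanel_validation_error")
  }
  sub <- subset_samples(matrix, sample_ids)
  X <- sub$intensity[, model$feature_ids, drop = FALSE]
  Z <- floor_and_scale(X, model$floors, model$center, model$scale)
  dv <- as.numeric(attr(predict(model$svm, Z, decision.values = TRUE),
                        "decision.values"))
  score <- model$orientation * dv
  prob <- stats::plogis(model$calibration[1] + model$calibration[2] * score)
  idx <- match(sample_ids, samples$sample_id)
  out <- tibble::tibble(
    sample_id = sample_ids,
    score = score,
    probability = unname(prob),
    predicted = factor(ifelse(score >= model$cutoff, "sig", "nonsig"),
                       levels = c("nonsig", "sig")),
    outcome = samples$outcome[idx],
    gleason_stratum = samples$gleason_stratum[idx]
  )
  structure(out, class = c("scored_cohort", class(out)), cutoff = model$cutoff)
}

#' Establish the decision cutoff on discovery scores
#'
#' `"youden"` (default) maximises sensitivity + specificity - 1 over
#' candidate cutoffs (midpoints between adjacent distinct scores plus
#' one candidate below and above all scores), breaking ties toward the
#' lower cutoff, i.e. favouring sensitivity. `"target_sensitivity"`
#' returns the largest observed-score cutoff whose discovery sensitivity
#' is at least `target`.
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param outcomes factor/character with levels `nonsig`/`sig`.
#' @param criterion `"youden"` or `"target_sensitivity"`.
#' @param target required sensitivity for `"target_sensitivity"`.
#' @return The cutoff (positive call: score >= cutoff).
#' @export
select_cutoff <- function(scores, outcomes,
                          criterion = c("youden", "target_sensitivity"),
                          target = NULL) {
  criterion <- match.arg(criterion)
  case <- outcomes == "sig"
  if (!any(case) || all(case)) {
    abort("Both classes must be present among the scored samples.",
          class = "uripanel_validation_error")
  }
  if (criterion == "youden") {
    s <- sort(unique(scores))
    cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
              s[length(s)] + 1)
    j <- vapply(cand, function(ct) {
      mean(scores[case] >= ct) + mean(scores[!case] < ct) - 1
    }, numeric(1))
    cand[which.max(j)]   # which.max takes the first, i.e. the lower cutoff
  } else {
    if (is.null(target) || target < 0 || target > 1) {
      abort("target sensitivity must lie in [0, 1].")
    }
    cand <- sort(unique(scores), decreasing = TRUE)
    for (ct in cand) {
      if (mean(scores[case] >= ct) >= target) return(ct)
    }
    abort("Target sensitivity unattainable on these scores.",
          class = "uripanel_validation_error")
  }
}

#' @export
tidy.svm_panel_model <- function(x, ...) {
  tibble::tibble(
    peptide_id = x$feature_ids,
    direction = if ("direction" %in% names(x$panel)) x$panel$direction else NA,
    floor_log = unname(x$floors),
    center = unname(x$center),
    scale = unname(x$scale)
  )
}

#' @export
glance.svm_panel_model <- function(x, ...) {
  tibble::tibble(
    n_panel = length(x$feature_ids),
    kernel = x$kernel, cost = x$cost, gamma = x$gamma,
    cutoff = x$cutoff, cutoff_criterion = x$cutoff_criterion,
    n_support_vectors = nrow(x$svm$SV),
    calibration_intercept = unname(x$calibration[1]),
    calibration_slope = unname(x$calibration[2]),
    n_discovery = length(x$discovery_ids)
  )
}
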