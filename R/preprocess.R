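#' Internal-standard normalisation
#'
#' CE-MS signal intensities vary multiplicatively between runs. A set of
#' endogenous peptides assumed disease-invariant (collagen fragments,
#' conventionally 29 of them) serves as internal standards: each
#' standard's reference level is its median detected intensity across
#' samples, and each sample's scale factor is the median, over the
#' standards detected in that sample, of reference / observed. Applying
#' the model multiplies every detected intensity in a sample by its
#' factor; non-detects stay 0.
#'
#' With a data-derived reference the normalised scale carries a global
#' indeterminacy (re-deriving references from already-normalised data
#' shifts them slightly), so the reference can also be supplied: fitting
#' against a fixed reference is exactly idempotent and cancels any
#' per-sample multiplicative distortion.
#'
#' @param matrix a raw [peptide_matrix()] containing at least one
#'   internal-standard peptide.
#' @param reference optional named vector (or the `reference` tibble of
#'   a previous model) fixing each standard's reference level; default:
#'   median detected intensity across the samples of `matrix`.
#' @return `fit_normalisation()` returns a `normalisation_model`: a list
#'   with `reference` (tibble peptide_id/reference level) and `factors`
#'   (tibble sample_id/factor).
#' @export
fit_normalisation <- function(matrix, reference = NULL) {
  stopifnot(inherits(matrix, "peptide_matrix"))
  std <- matrix$features$is_internal_standard
  if (!any(std)) abort("No internal-standard peptides in the matrix.")
  S <- matrix$intensity[, std, drop = FALSE]
  if (is.null(reference)) {
    reference <- apply(S, 2, function(v) median(v[v > 0]))
  } else {
    if (is.data.frame(reference)) {
      reference <- setNames(reference$reference, reference$peptide_id)
    }
    if (!all(colnames(S) %in% names(reference))) {
      abort("`reference` must cover every internal standard.")
    }
    reference <- reference[colnames(S)]
  }
  if (anyNA(reference)) {
    abort("Internal standard(s) never detected; cannot set a reference level.")
  }
  factors <- vapply(seq_len(nrow(S)), function(i) {
    obs <- S[i, ]
    det <- obs > 0
    if (!any(det)) {
      abort(sprintf("Sample '%s' has no detected internal standard.",
                    matrix$sample_ids[i]),
            class = "uripanel_validation_error")
    }
    median(reference[det] / obs[det])
  }, numeric(1))
  structure(list(
    reference = tibble::tibble(peptide_id = colnames(S), reference = reference),
    factors = tibble::tibble(sample_id = matrix$sample_ids, factor = factors)
  ), class = "normalisation_model")
}

#' @rdname fit_normalisation
#' @param model a `normalisation_model` from `fit_normalisation()`.
#' @return `apply_normalisation()` returns the matrix with every nonzero
#'   intensity scaled by its sample factor and `scale = "normalised"`.
#' @export
apply_normalisation <- function(matrix, model) {
  stopifnot(inherits(matrix, "peptide_matrix"),
            inherits(model, "normalisation_model"))
  if (matrix$scale != "raw") {
    abort(sprintf("Expected a raw matrix, got scale '%s'.", matrix$scale),
          class = "uripanel_scale_error")
  }
  fac <- model$factors$factor[match(matrix$sample_ids, model$factors$sample_id)]
  if (anyNA(fac)) abort("Normalisation model does not cover every sample.")
  out <- sweep(matrix$intensity, 1, fac, `*`)
  peptide_matrix(out, matrix$features, matrix$sample_ids, scale = "normalised")
}

#' Natural-log transform of a normalised matrix
#'
#' Detected intensities are replaced by their natural log; zeros keep
#' encoding "not detected" and are treated by every rank-based statistic
#' downstream as left-censored values tied below all detected values.
#' A detected normalised intensity at or below 1 AU would collide with
#' the non-detect code after the transform, so that case triggers a
#' warning (it does not arise at realistic AU scales).
#'
#' @param matrix a normalised [peptide_matrix()].
#' @return The matrix with `scale = "log"`.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "peptide_matrix"))
  if (matrix$scale != "normalised") {
    abort(sprintf("Expected a normalised matrix, got scale '%s'.", matrix$scale),
          class = "uripanel_scale_error")
  }
  x <- matrix$intensity
  det <- x > 0
  if (any(x[det] <= 1)) {
    warn("Detected intensities <= 1 AU log-transform to values <= 0 and may collide with the non-detect code 0.")
  }
  x[det] <- log(x[det])
  peptide_matrix(x, matrix$features, matrix$sample_ids, scale = "log")
}

#' Per-group detection frequencies
#'
#' Fraction of samples per outcome group in which each peptide is
#' detected (intensity > 0). Feeds the 70% frequency filter of the
#' discovery stage.
#'
#' @param matrix a [peptide_matrix()] at any scale.
#' @param samples validated sample table covering the matrix samples.
#' @return Tibble with `peptide_id`, `case_freq`, `control_freq`.
#' @export
detection_frequencies <- function(matrix, samples) {
  stopifnot(inherits(matrix, "peptide_matrix"))
  idx <- match(matrix$sample_ids, samples$sample_id)
  if (anyNA(idx)) abort("Sample table does not cover every matrix sample.")
  outcome <- samples$outcome[idx]
  case <- outcome == "sig"
  if (!any(case) || all(case)) {
    abort("Both outcome groups must be non-empty.",
          class = "uripanel_validation_error")
  }
  det <- matrix$intensity > 0
  tibble::tibble(
    peptide_id = matrix$features$peptide_id,
    case_freq = unname(colMeans(det[case, , drop = FALSE])),
    control_freq = unname(colMeans(det[!case, , drop = FALSE]))
  )
}

#' Stratified discovery/validation split
#'
#' Random allocation of samples to a discovery (training) and validation
#' set following the 2/3-1/3 rule, stratified by outcome so each class is
#' represented proportionally: per class, round(fraction * n) samples
#' (half rounded away from zero) are drawn without replacement into
#' discovery. Deterministic given `seed`.
#'
#' @param samples validated sample table.
#' @param discovery_fraction fraction allocated to discovery (default 2/3).
#' @param seed integer seed.
#' @return A tibble (`sample_id`, `set` = "discovery"/"validation") of
#'   class `split_assignment`, with the seed and fraction as attributes.
#' @export
stratified_split <- function(samples, discovery_fraction = 2 / 3, seed = 1) {
  if (discovery_fraction <= 0 || discovery_fraction >= 1) {
    abort("discovery_fraction must lie strictly between 0 and 1.")
  }
  classes <- split(samples$sample_id, samples$outcome)
  if (any(lengths(classes) == 0)) {
    abort("Both outcome classes must be non-empty.",
          class = "uripanel_validation_error")
  }
  assignment <- with_seed(derive_seed(seed, "split"), {
    purrr::map(classes, function(ids) {
      k <- as.integer(round_half_away(discovery_fraction * length(ids)))
      if (k >= length(ids)) {
        abort("A class is too small for a non-empty validation set.",
              class = "uripanel_validation_error")
      }
      sample(ids, k)
    })
  })
  disc <- unlist(assignment, use.names = FALSE)
  out <- tibble::tibble(
    sample_id = samples$sample_id,
    set = ifelse(samples$sample_id %in% disc, "discovery", "validation")
  )
  structure(out, class = c("split_assignment", class(out)),
            seed = seed, discovery_fraction = discovery_fraction)
}

#' @rdname stratified_split
#' @param split a `split_assignment`.
#' @param which `"discovery"` or `"validation"`.
#' @return `split_ids()` returns the sample ids in the requested set.
#' @export
split_ids <- function(split, which = c("discovery", "validation")) {
  which <- match.arg(which)
  split$sample_id[split$set == which]
}

# Row-subset a peptide matrix by sample ids (order preserved as given).
subset_samples <- function(matrix, sample_ids) {
  idx <- match(sample_ids, matrix$sample_ids)
  if (anyNA(idx)) abort("Unknown sample id(s) in subset.")
  peptide_matrix(matrix$intensity[idx, , drop = FALSE], matrix$features,
                 sample_ids, scale = matrix$scale)
}
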