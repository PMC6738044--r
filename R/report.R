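#' Write machine- and human-readable reports
#'
#' Writes each result type as a tab-separated table (machine-readable)
#' plus, where useful, a short plain-text summary. Output is
#' deterministic: identical inputs produce byte-identical files.
#'
#' @param x a result object (`biomarker_panel`, `roc_result`,
#'   `scored_cohort`, `cohort_summary`, `net_benefit`, or any data
#'   frame).
#' @param path output file path (for multi-file reports this is the main
#'   TSV; companions share its stem).
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, ...) UseMethod("write_report")

#' @export
write_report.default <- function(x, path, ...) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @export
write_report.biomarker_panel <- function(x, path, ...) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  runs <- attr(x, "runs")
  readr::write_tsv(runs, companion_path(path, "runs"), progress = FALSE)
  readr::write_tsv(glance(x), companion_path(path, "meta"), progress = FALSE)
  invisible(path)
}

#' @export
write_report.roc_result <- function(x, path, ...) {
  readr::write_tsv(x$curve, path, progress = FALSE)
  readr::write_tsv(glance(x), companion_path(path, "auc"), progress = FALSE)
  invisible(path)
}

#' @export
write_report.cohort_summary <- function(x, path, ...) {
  readr::write_tsv(x$summary, path, progress = FALSE)
  readr::write_tsv(x$tests, companion_path(path, "tests"), progress = FALSE)
  invisible(path)
}

companion_path <- function(path, tag) {
  sub("(\\.[^.]+)?$", paste0("_", tag, "\\1"), path)
}

#' Pipeline configuration
#'
#' Central defaults for every tunable of the pipeline, overridable from
#' a YAML file. Unknown keys are rejected so typos fail loudly.
#'
#' @param ... overrides of individual defaults.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    discovery_fraction = 2 / 3,
    alpha = 0.05,
    n_runs = 5L,
    exclude_fraction = 0.30,
    freq_threshold = 0.70,
    use_adjusted = TRUE,
    kernel = "radial",
    cost = 1,
    gamma = NULL,
    zero_offset = 1,
    cutoff_criterion = "youden",
    target = NULL
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  modifyList(defaults, overrides, keep.null = TRUE)
}

#' @rdname pipeline_config
#' @param path YAML file of overrides.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_msg <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
}

#' Run the full biomarker pipeline
#'
#' Chains every stage on a raw peptide matrix and sample table:
#' internal-standard normalisation, log transform, stratified 2/3-1/3
#' split, stability-filtered biomarker discovery, SVM training with a
#' discovery-set cutoff, and validation-set scoring with ROC and
#' sensitivity/specificity at the cutoff.
#'
#' @param matrix raw [peptide_matrix()].
#' @param samples validated sample table.
#' @param config [pipeline_config()] list.
#' @param seed integer seed driving the split and the stability runs.
#' @param verbose log progress with timestamps.
#' @return A `panel_pipeline` list: `split`, `panel`, `model`,
#'   `scored_validation`, `roc`, `metrics` (sens/spec tibble),
#'   `log_matrix`.
#' @export
run_panel_pipeline <- function(matrix, samples, config = pipeline_config(),
                               seed = 1, verbose = FALSE) {
  log_msg(verbose, "seed = %d; normalising on internal standards", seed)
  norm <- fit_normalisation(matrix)
  lmat <- log_transform(apply_normalisation(matrix, norm))
  split <- stratified_split(samples, config$discovery_fraction, seed = seed)
  log_msg(verbose, "split: %d discovery / %d validation",
          sum(split$set == "discovery"), sum(split$set == "validation"))
  panel <- discover_panel(lmat, samples, split,
                          alpha = config$alpha, n_runs = config$n_runs,
                          exclude_fraction = config$exclude_fraction,
                          freq_threshold = config$freq_threshold,
                          seed = seed, use_adjusted = config$use_adjusted)
  log_msg(verbose, "panel: %d peptide(s)", nrow(panel))
  if (!nrow(panel)) {
    return(structure(list(split = split, panel = panel, model = NULL,
                          scored_validation = NULL, roc = NULL,
                          metrics = NULL, log_matrix = lmat,
                          normalisation = norm, seed = seed),
                     class = "panel_pipeline"))
  }
  model <- train_svm(lmat, samples, split, panel,
                     kernel = config$kernel, cost = config$cost,
                     gamma = config$gamma, zero_offset = config$zero_offset,
                     cutoff_criterion = config$cutoff_criterion,
                     target = config$target)
  scored <- score_samples(model, lmat, samples,
                          sample_ids = split_ids(split, "validation"))
  roc <- roc_curve(scored$score, scored$outcome)
  metrics <- sens_spec_at_cutoff(scored)
  log_msg(verbose, "validation AUC = %.3f", roc$auc)
  structure(list(split = split, panel = panel, model = model,
                 scored_validation = scored, roc = roc, metrics = metrics,
                 log_matrix = lmat, normalisation = norm, seed = seed),
            class = "panel_pipeline")
}

#' @export
print.panel_pipeline <- function(x, ...) {
  cat(sprintf("<panel_pipeline> seed %d, panel of %d peptide(s)\n",
              x$seed, nrow(x$panel)))
  if (!is.null(x$roc)) {
    cat(sprintf("  validation AUC %.3f (95%% CI %.3f-%.3f)\n",
                x$roc$auc, x$roc$ci_lo, x$roc$ci_hi))
    sens <- x$metrics[x$metrics$metric == "sensitivity", ]
    spec <- x$metrics[x$metrics$metric == "specificity", ]
    cat(sprintf("  at cutoff %.3f: sensitivity %.0f%% (%.0f-%.0f), specificity %.0f%% (%.0f-%.0f)\n",
                x$model$cutoff, 100 * sens$estimate, 100 * sens$lo,
                100 * sens$hi, 100 * spec$estimate, 100 * spec$lo,
                100 * spec$hi))
  }
  invisible(x)
}

#' @export
glance.panel_pipeline <- function(x, ...) {
  if (is.null(x$roc)) {
    return(tibble::tibble(seed = x$seed, n_panel = nrow(x$panel),
                          auc = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, cutoff = NA_real_))
  }
  tibble::tibble(
    seed = x$seed,
    n_panel = nrow(x$panel),
    auc = x$roc$auc,
    auc_lo = x$roc$ci_lo, auc_hi = x$roc$ci_hi,
    sensitivity = x$metrics$estimate[x$metrics$metric == "sensitivity"],
    specificity = x$metrics$estimate[x$metrics$metric == "specificity"],
    cutoff = x$model$cutoff
  )
}

#' @export
autoplot.scored_cohort <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gleason_stratum,
                                       y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Gleason stratum", y = "Classifier score") +
    ggplot2::theme_minimal()
}
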