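#' Frequency filter
#'
#' Retains peptides detected in at least `threshold` of samples in at
#' least one of the two outcome groups (boundary inclusive). Sporadically
#' detected peptides carry little rank information and inflate the
#' multiple-testing family.
#'
#' @param freq frequency tibble from [detection_frequencies()].
#' @param threshold detection-frequency threshold (default 0.70).
#' @return Character vector of retained peptide ids.
#' @export
frequency_filter <- function(freq, threshold = 0.70) {
  freq$peptide_id[freq$case_freq >= threshold | freq$control_freq >= threshold]
}

# Full per-peptide differential analysis of one sample set: frequency
# filter, Wilcoxon rank-sum per retained peptide (censored zeros tied at
# the bottom), BH adjustment within the retained family, regulation
# direction from censored medians (ties break to "up_in_sig").
peptide_test_table <- function(matrix, samples, freq_threshold = 0.70) {
  freq <- detection_frequencies(matrix, samples)
  keep <- frequency_filter(freq, freq_threshold)
  freq <- freq[freq$peptide_id %in% keep, , drop = FALSE]
  if (!nrow(freq)) {
    return(tibble::tibble(
      peptide_id = character(), case_freq = numeric(),
      control_freq = numeric(), raw_p = numeric(), adjusted_p = numeric(),
      direction = character()
    ))
  }
  outcome <- samples$outcome[match(matrix$sample_ids, samples$sample_id)]
  case <- outcome == "sig"
  X <- matrix$intensity[, freq$peptide_id, drop = FALSE]
  stats_per <- purrr::map(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    p <- wilcoxon_rank_sum(v[case], v[!case])
    det <- v[v > 0]
    floorv <- if (length(det)) min(det) - 1 else -1
    vv <- ifelse(v > 0, v, floorv)
    d <- median(vv[case]) - median(vv[!case])
    list(p = p, direction = if (d >= 0) "up_in_sig" else "down_in_sig")
  })
  freq$raw_p <- purrr::map_dbl(stats_per, "p")
  freq$adjusted_p <- benjamini_hochberg(freq$raw_p)
  freq$direction <- purrr::map_chr(stats_per, "direction")
  freq
}

#' Stability analysis by repeated subsampling
#'
#' Repeats the full discovery analysis on random stratified subsamples:
#' in each run a fraction `exclude_fraction` of the discovery samples is
#' excluded (per outcome class, so neither class can collapse), and the
#' frequency filter, Wilcoxon tests and BH adjustment are recomputed on
#' the retained samples. Only peptides significant in every run survive
#' into the panel, which guards the selection against a handful of
#' influential samples.
#'
#' @param matrix log-scale [peptide_matrix()].
#' @param samples validated sample table.
#' @param discovery_ids sample ids of the discovery set.
#' @param n_runs number of subsampling runs (default 5).
#' @param exclude_fraction fraction excluded per run (default 0.30).
#' @param freq_threshold detection-frequency threshold within each run.
#' @param seed integer seed; runs use derived per-run streams.
#' @return Long tibble of per-run test results with a `run` column.
#' @export
stability_runs <- function(matrix, samples, discovery_ids,
                           n_runs = 5, exclude_fraction = 0.30,
                           freq_threshold = 0.70, seed = 1) {
  if (exclude_fraction < 0 || exclude_fraction >= 1) {
    abort("exclude_fraction must lie in [0, 1).")
  }
  samp <- samples[match(discovery_ids, samples$sample_id), , drop = FALSE]
  classes <- split(samp$sample_id, samp$outcome)
  purrr::map_dfr(seq_len(n_runs), function(r) {
    retained <- with_seed(derive_seed(seed, "run") + r, {
      unlist(purrr::map(classes, function(ids) {
        k <- as.integer(round_half_away((1 - exclude_fraction) * length(ids)))
        if (k < 1) {
          abort("A subsample run would lose an entire outcome class.",
                class = "uripanel_validation_error")
        }
        sample(ids, k)
      }), use.names = FALSE)
    })
    res <- peptide_test_table(subset_samples(matrix, retained), samp,
                              freq_threshold)
    res$run <- r
    res
  })
}

#' Discover a biomarker panel
#'
#' The full discovery stage: differential analysis of the discovery set
#' (frequency filter, per-peptide Wilcoxon, BH adjustment) plus the
#' subsampling stability analysis. The panel keeps the peptides that pass
#' the frequency filter on the full discovery set and are significant
#' (by default BH-adjusted p < `alpha`; set `use_adjusted = FALSE` for
#' raw p) in **all** stability runs. Regulation directions and the
#' reported statistics come from the full discovery set.
#'
#' @inheritParams stability_runs
#' @param split a [stratified_split()] assignment (its discovery ids are
#'   used), or a character vector of discovery sample ids.
#' @param alpha significance level within each run (default 0.05).
#' @param use_adjusted judge significance on BH-adjusted p (default) or
#'   raw p.
#' @return A `biomarker_panel`: tibble of selected peptides
#'   (`peptide_id`, `mass_kda`, `migration_min`, `direction`,
#'   `case_freq`, `control_freq`, `raw_p`, `adjusted_p`) with selection
#'   metadata and the per-run audit trail as attributes. An empty panel
#'   is returned with a warning, not an error.
#' @export
discover_panel <- function(matrix, samples, split, alpha = 0.05,
                           n_runs = 5, exclude_fraction = 0.30,
                           freq_threshold = 0.70, seed = 1,
                           use_adjusted = TRUE) {
  discovery_ids <- if (inherits(split, "split_assignment")) {
    split_ids(split, "discovery")
  } else {
    as.character(split)
  }
  disc_matrix <- subset_samples(matrix, discovery_ids)
  full <- peptide_test_table(disc_matrix, samples, freq_threshold)
  runs <- stability_runs(matrix, samples, discovery_ids, n_runs,
                         exclude_fraction, freq_threshold, seed)
  pcol <- if (use_adjusted) "adjusted_p" else "raw_p"
  per_run_sig <- runs |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::summarise(
      n_sig_runs = sum(.data[[pcol]] < alpha),
      .groups = "drop"
    )
  unanimous <- per_run_sig$peptide_id[per_run_sig$n_sig_runs == n_runs]
  panel <- full[full$peptide_id %in% unanimous, , drop = FALSE]
  panel <- dplyr::left_join(
    panel,
    matrix$features[, c("peptide_id", "mass_kda", "migration_min")],
    by = "peptide_id"
  )
  panel <- panel[order(panel$adjusted_p, panel$peptide_id), , drop = FALSE]
  panel <- panel[, c("peptide_id", "mass_kda", "migration_min", "direction",
                     "case_freq", "control_freq", "raw_p", "adjusted_p")]
  if (!nrow(panel)) {
    warn("No peptide was significant in all stability runs: the panel is empty.")
  }
  structure(panel,
            class = c("biomarker_panel", class(panel)),
            alpha = alpha, n_runs = n_runs,
            exclude_fraction = exclude_fraction,
            freq_threshold = freq_threshold, seed = seed,
            use_adjusted = use_adjusted,
            runs = runs, full_results = full,
            n_discovery = length(discovery_ids))
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf(
    "<biomarker_panel> %d peptide(s); alpha = %g on %s p, %d stability runs (%.0f%% exclusion), frequency >= %.0f%%\n",
    nrow(x), attr(x, "alpha"),
    if (attr(x, "use_adjusted")) "BH-adjusted" else "raw",
    attr(x, "n_runs"), 100 * attr(x, "exclude_fraction"),
    100 * attr(x, "freq_threshold")
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
tidy.biomarker_panel <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.biomarker_panel <- function(x, ...) {
  tibble::tibble(
    n_panel = nrow(x),
    n_tested = nrow(attr(x, "full_results")),
    alpha = attr(x, "alpha"),
    n_runs = attr(x, "n_runs"),
    exclude_fraction = attr(x, "exclude_fraction"),
    freq_threshold = attr(x, "freq_threshold"),
    use_adjusted = attr(x, "use_adjusted"),
    seed = attr(x, "seed"),
    n_discovery = attr(x, "n_discovery")
  )
}
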