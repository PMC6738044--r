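#' Table-style cohort summary
#'
#' Baseline-characteristics machinery: per group, medians and
#' interquartile ranges with Mann-Whitney p-values for continuous
#' variables; counts and percentages with chi-squared p-values for
#' categorical ones. Prostate volume (and the PSA density derived from
#' it) is summarised pairwise-complete with the available n reported.
#' Gleason strata are summarised with percentages relative to the
#' samples of the same outcome within each group, the convention of
#' clinical baseline tables.
#'
#' @param samples validated sample table; needs a `set` column when
#'   `group = "set"`.
#' @param group `"outcome"` (cases vs controls) or `"set"`
#'   (discovery vs validation).
#' @param yates use Yates continuity correction in 2 x 2 chi-squared
#'   tests (default off).
#' @return A `cohort_summary`: list with `summary` (tibble `variable`,
#'   `level`, `group`, `n`, `pct`, `median`, `iqr`, `n_obs`) and
#'   `tests` (tibble `variable`, `test`, `p_value`).
#' @export
cohort_summary <- function(samples, group = c("outcome", "set"),
                           yates = FALSE) {
  group <- match.arg(group)
  if (group == "set" && !"set" %in% names(samples)) {
    abort("Grouping by split requires a `set` column (see stratified_split).")
  }
  g <- as.factor(samples[[group]])
  if (any(table(g) == 0) || nlevels(droplevels(g)) < 2) {
    abort("Both groups must be non-empty.", class = "uripanel_validation_error")
  }
  samples$psa_density <- samples$psa / samples$prostate_volume_ml
  samples$any_prior_biopsy <- ifelse(samples$prior_biopsy_count > 0, "yes", "no")

  cont_vars <- c("age", "psa", "prior_biopsy_count", "prostate_volume_ml",
                 "psa_density", "urinary_creatinine")
  cat_vars <- c("dre_positive", "any_prior_biopsy", "fivear_inhibitor")
  if (group == "set") cat_vars <- c("outcome", cat_vars)

  rows <- list(); tests <- list()
  lv <- levels(g)

  rows$samples <- tibble::tibble(
    variable = "samples", level = NA_character_, group = lv,
    n = as.integer(table(g)[lv]),
    pct = 100 * as.integer(table(g)[lv]) / length(g),
    median = NA_real_, iqr = NA_real_, n_obs = as.integer(table(g)[lv])
  )

  for (v in cont_vars) {
    vals <- samples[[v]]
    per <- purrr::map_dfr(lv, function(l) {
      x <- vals[g == l & !is.na(vals)]
      tibble::tibble(variable = v, level = NA_character_, group = l,
                     n = NA_integer_, pct = NA_real_,
                     median = median(x),
                     iqr = unname(diff(quantile(x, c(0.25, 0.75)))),
                     n_obs = length(x))
    })
    rows[[v]] <- per
    x1 <- vals[g == lv[1] & !is.na(vals)]
    x2 <- vals[g == lv[2] & !is.na(vals)]
    tests[[v]] <- tibble::tibble(
      variable = v, test = "mann_whitney",
      p_value = if (length(unique(c(x1, x2))) == 1L) 1 else
        mann_whitney_u(x1, x2, censored_zero = FALSE)$p
    )
  }

  for (v in cat_vars) {
    vals <- as.character(samples[[v]])
    tab <- table(vals, g)[, lv, drop = FALSE]
    per <- purrr::map_dfr(rownames(tab), function(l) {
      tibble::tibble(variable = v, level = l, group = lv,
                     n = as.integer(tab[l, ]),
                     pct = 100 * as.integer(tab[l, ]) / as.integer(colSums(tab)),
                     median = NA_real_, iqr = NA_real_,
                     n_obs = as.integer(colSums(tab)))
    })
    rows[[v]] <- per
    tests[[v]] <- tibble::tibble(
      variable = v, test = "chi_squared",
      p_value = if (nrow(tab) < 2) 1 else
        chi_squared_2xk(unclass(tab), yates = yates)$p_value
    )
  }

  # Gleason strata, percentages within the same outcome inside each group
  gs <- purrr::map_dfr(lv, function(l) {
    sub <- samples[g == l, , drop = FALSE]
    purrr::map_dfr(gleason_levels(), function(st) {
      same_outcome <- sub$outcome == derive_outcome(st)
      tibble::tibble(variable = "gleason_stratum", level = st, group = l,
                     n = sum(sub$gleason_stratum == st),
                     pct = 100 * sum(sub$gleason_stratum == st) /
                       max(1L, sum(same_outcome)),
                     median = NA_real_, iqr = NA_real_,
                     n_obs = sum(same_outcome))
    })
  })
  rows$gleason <- gs

  structure(list(
    summary = dplyr::bind_rows(rows),
    tests = dplyr::bind_rows(tests),
    grouping = group
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> grouped by %s\n", x$grouping))
  print(x$summary, n = 30)
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$summary

#' @export
glance.cohort_summary <- function(x, ...) x$tests

#' Reconstruct a cohort table from printed marginal counts
#'
#' Builds a synthetic per-sample table whose marginal counts match a
#' published baseline-characteristics table: per split (discovery /
#' validation) and Gleason stratum cell counts, plus prior-biopsy counts
#' per outcome group. Continuous covariates are filled with fixed
#' representative values; the object reproduces every count-derived
#' percentage of the source table exactly but carries no real patient
#' data (it is a bookkeeping fixture, not a cohort).
#'
#' The default counts describe a 823-patient biopsy cohort: 543
#' discovery (98 significant-PCa cases, 445 controls) and 280 validation
#' (48 cases, 232 controls), with discovery cases split 63/20/9/6 across
#' Gleason 3+4 / 4+3 / 8 / >=9 and validation cases 32/9/5/2; 21 of the
#' 146 cases and 197 of the 677 controls had prior biopsies. (The
#' published group-level prior-biopsy cells sum to 667, not 677; the
#' group totals and the no-prior-biopsy percentages are taken as
#' authoritative.)
#'
#' @param counts named list as produced by [example_cohort_counts()].
#' @return A validated sample tibble with an extra `set` column.
#' @export
cohort_from_counts <- function(counts = example_cohort_counts()) {
  cells <- counts$strata_by_set
  recs <- purrr::pmap_dfr(cells, function(set, gleason_stratum, n) {
    tibble::tibble(set = set, gleason_stratum = gleason_stratum,
                   idx = seq_len(n))
  })
  recs$sample_id <- sprintf("T%04d", seq_len(nrow(recs)))
  recs$outcome_chr <- derive_outcome(recs$gleason_stratum)

  # prior biopsies allocated deterministically within outcome groups
  recs$prior_biopsy_count <- 0L
  for (oc in c("sig", "nonsig")) {
    k <- if (oc == "sig") counts$prior_biopsy_cases else counts$prior_biopsy_controls
    idx <- which(recs$outcome_chr == oc)
    recs$prior_biopsy_count[idx[seq_len(k)]] <- 1L
  }

  out <- tibble::tibble(
    sample_id = recs$sample_id,
    gleason_stratum = recs$gleason_stratum,
    age = ifelse(recs$outcome_chr == "sig", 68, 63),
    psa = ifelse(recs$outcome_chr == "sig", 6.1, 5.1),
    dre_positive = FALSE,
    prior_biopsy_count = recs$prior_biopsy_count,
    prostate_volume_ml = ifelse(recs$outcome_chr == "sig", 28, 37.4),
    fivear_inhibitor = FALSE,
    urinary_creatinine = 7.8
  )
  out <- validate_sample_table(out)
  out$set <- recs$set
  out
}

#' @rdname cohort_from_counts
#' @export
example_cohort_counts <- function() {
  list(
    strata_by_set = tibble::tribble(
      ~set,         ~gleason_stratum, ~n,
      "discovery",  "GS3+4",          63L,
      "discovery",  "GS4+3",          20L,
      "discovery",  "GS8",             9L,
      "discovery",  "GS>=9",           6L,
      "discovery",  "GS6",            99L,
      "discovery",  "benign",        346L,
      "validation", "GS3+4",          32L,
      "validation", "GS4+3",           9L,
      "validation", "GS8",             5L,
      "validation", "GS>=9",           2L,
      "validation", "GS6",            32L,
      "validation", "benign",        200L
    ),
    prior_biopsy_cases = 21L,
    prior_biopsy_controls = 197L
  )
}
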