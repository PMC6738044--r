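#' Clinical sample tables
#'
#' The per-sample clinical annotation is a plain tibble with one row per
#' patient. The binary outcome dichotomises the biopsy Gleason score:
#' `"sig"` (significant prostate cancer, Gleason >= 7, the positive class)
#' for strata `GS3+4`, `GS4+3`, `GS8`, `GS>=9`, otherwise `"nonsig"`
#' (benign/atypical conditions and Gleason 6). Samples with PSA >= 15
#' ng/ml violate the cohort inclusion criterion and are rejected.
#'
#' Expected columns: `sample_id`, `gleason_stratum` (one of `benign`,
#' `GS6`, `GS3+4`, `GS4+3`, `GS8`, `GS>=9`), `age` (years), `psa` (ng/ml),
#' `dre_positive` (logical), `prior_biopsy_count` (non-negative integer),
#' `prostate_volume_ml` (positive or `NA`), `fivear_inhibitor` (logical),
#' `urinary_creatinine` (mmol/L). Optional: `outcome` (checked against the
#' stratum if present), `external_risk` (probability in \[0, 1\] or `NA`,
#' the slot for an external risk-calculator score).
#'
#' @param data data frame of per-sample records.
#' @return A validated tibble with `outcome` as a factor
#'   (`nonsig` < `sig`) and `gleason_stratum` as an ordered factor.
#' @export
validate_sample_table <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("sample_id", "gleason_stratum", "age", "psa", "dre_positive",
              "prior_biopsy_count", "fivear_inhibitor", "urinary_creatinine")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Sample table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "uripanel_format_error")
  }
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) {
    abort("Duplicate sample_id in sample table.",
          class = "uripanel_validation_error")
  }
  strata <- gleason_levels()
  data$gleason_stratum <- as.character(data$gleason_stratum)
  bad <- setdiff(unique(data$gleason_stratum), strata)
  if (length(bad)) {
    abort(paste0("Unknown gleason_stratum value(s): ",
                 paste(bad, collapse = ", ")),
          class = "uripanel_validation_error")
  }
  derived <- derive_outcome(data$gleason_stratum)
  if ("outcome" %in% names(data)) {
    given <- as.character(data$outcome)
    clash <- which(given != derived)
    if (length(clash)) {
      abort(sprintf(
        "outcome contradicts gleason_stratum for sample(s): %s",
        paste(head(data$sample_id[clash], 5), collapse = ", ")
      ), class = "uripanel_validation_error")
    }
  }
  data$outcome <- factor(derived, levels = c("nonsig", "sig"))
  data$gleason_stratum <- factor(data$gleason_stratum, levels = strata,
                                 ordered = TRUE)
  if (any(!is.finite(data$psa)) || any(data$psa < 0)) {
    abort("psa must be non-negative and finite.",
          class = "uripanel_validation_error")
  }
  over <- data$sample_id[data$psa >= 15]
  if (length(over)) {
    abort(sprintf(
      "%d sample(s) violate the inclusion criterion PSA < 15 ng/ml: %s",
      length(over), paste(head(over, 5), collapse = ", ")
    ), class = "uripanel_validation_error")
  }
  if (any(data$prior_biopsy_count < 0 | data$prior_biopsy_count %% 1 != 0)) {
    abort("prior_biopsy_count must be a non-negative integer.",
          class = "uripanel_validation_error")
  }
  if (!"prostate_volume_ml" %in% names(data)) data$prostate_volume_ml <- NA_real_
  vol <- data$prostate_volume_ml
  if (any(!is.na(vol) & vol <= 0)) {
    abort("prostate_volume_ml must be positive or NA.",
          class = "uripanel_validation_error")
  }
  if (!"external_risk" %in% names(data)) data$external_risk <- NA_real_
  er <- data$external_risk
  if (any(!is.na(er) & (er < 0 | er > 1))) {
    abort("external_risk must lie in [0, 1] or be NA.",
          class = "uripanel_validation_error")
  }
  data
}

gleason_levels <- function() c("benign", "GS6", "GS3+4", "GS4+3", "GS8", "GS>=9")

sig_strata <- function() c("GS3+4", "GS4+3", "GS8", "GS>=9")

derive_outcome <- function(stratum) {
  ifelse(stratum %in% sig_strata(), "sig", "nonsig")
}

#' @rdname validate_sample_table
#' @param path file path to a tab-separated sample table.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  for (col in c("dre_positive", "fivear_inhibitor")) {
    if (col %in% names(raw) && !is.logical(raw[[col]])) {
      raw[[col]] <- tolower(as.character(raw[[col]])) %in% c("true", "1", "yes")
    }
  }
  for (col in c("prostate_volume_ml", "external_risk")) {
    if (col %in% names(raw)) raw[[col]] <- as.numeric(raw[[col]])
  }
  validate_sample_table(raw)
}

#' @rdname validate_sample_table
#' @param x a validated sample table.
#' @export
write_sample_table <- function(x, path) {
  out <- dplyr::mutate(
    x,
    outcome = as.character(.data$outcome),
    gleason_stratum = as.character(.data$gleason_stratum)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
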