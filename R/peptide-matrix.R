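#' Peptide intensity matrices
#'
#' A `peptide_matrix` holds a CE-MS-style peak-list dataset: one row per
#' sample, one column per deconvolved peptide, intensities in arbitrary
#' units (AU) with `0` meaning "not detected". Peptide metadata (mass in
#' kDa, normalised migration time in minutes, internal-standard flag)
#' travels with the matrix. A `scale` tag records where the matrix sits in
#' the processing chain and may only move `raw -> normalised -> log`.
#'
#' @param intensity numeric matrix, rows = samples, columns = peptides,
#'   all values >= 0; `0` encodes non-detection.
#' @param features data frame with columns `peptide_id`, `mass_kda`,
#'   `migration_min`, `is_internal_standard`, one row per matrix column.
#' @param sample_ids character vector naming the matrix rows.
#' @param scale one of `"raw"`, `"normalised"`, `"log"`.
#'
#' @return A `peptide_matrix` object.
#' @export
#' @examples
#' m <- peptide_matrix(
#'   matrix(c(10, 0, 5, 8, 2, 0), nrow = 2),
#'   features = tibble::tibble(
#'     peptide_id = c("p1", "p2", "p3"),
#'     mass_kda = c(1.2, 2.5, 0.9),
#'     migration_min = c(22, 31, 19),
#'     is_internal_standard = c(FALSE, TRUE, FALSE)
#'   ),
#'   sample_ids = c("s1", "s2")
#' )
#' dim(m)
peptide_matrix <- function(intensity, features, sample_ids,
                           scale = c("raw", "normalised", "log")) {
  scale <- match.arg(scale)
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("`intensity` must be a numeric matrix (rows = samples).")
  }
  features <- tibble::as_tibble(features)
  needed <- c("peptide_id", "mass_kda", "migration_min", "is_internal_standard")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols)) {
    abort(paste0("`features` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  features$peptide_id <- as.character(features$peptide_id)
  if (anyDuplicated(features$peptide_id)) {
    dup <- unique(features$peptide_id[duplicated(features$peptide_id)])
    abort(paste0("Duplicate peptide_id: ", paste(dup, collapse = ", ")),
          class = "uripanel_format_error")
  }
  if (any(!is.finite(features$mass_kda)) || any(features$mass_kda <= 0) ||
      any(!is.finite(features$migration_min)) || any(features$migration_min <= 0)) {
    abort("Peptide mass_kda and migration_min must be positive and finite.",
          class = "uripanel_validation_error")
  }
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    abort("Duplicate sample ids.", class = "uripanel_validation_error")
  }
  if (nrow(intensity) != length(sample_ids) || ncol(intensity) != nrow(features)) {
    abort(sprintf(
      "Shape mismatch: intensity is %d x %d but there are %d samples and %d peptides.",
      nrow(intensity), ncol(intensity), length(sample_ids), nrow(features)
    ), class = "uripanel_validation_error")
  }
  if (anyNA(intensity) || any(intensity < 0)) {
    abort("Intensities must be non-negative and non-missing (0 = not detected).",
          class = "uripanel_validation_error")
  }
  dimnames(intensity) <- list(sample_ids, features$peptide_id)
  structure(
    list(intensity = intensity, features = features,
         sample_ids = sample_ids, scale = scale),
    class = "peptide_matrix"
  )
}

#' @export
dim.peptide_matrix <- function(x) dim(x$intensity)

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf(
    "<peptide_matrix> %d samples x %d peptides [%s scale], %d internal standards\n",
    nrow(x$intensity), ncol(x$intensity), x$scale,
    sum(x$features$is_internal_standard)
  ))
  invisible(x)
}

#' Long-format view of a peptide matrix
#'
#' One row per (sample, peptide) cell, carrying peptide metadata.
#'
#' @param x a `peptide_matrix`.
#' @param ... unused.
#' @importFrom tibble as_tibble
#' @method as_tibble peptide_matrix
#' @export
as_tibble.peptide_matrix <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(x$sample_ids, times = ncol(x$intensity)),
    peptide_id = rep(x$features$peptide_id, each = nrow(x$intensity)),
    intensity = as.vector(x$intensity)
  )
  dplyr::left_join(long, x$features, by = "peptide_id")
}

#' Read and write peptide matrices as wide TSV
#'
#' On disk peptides are rows and samples are columns (peptide counts dwarf
#' sample counts), with leading metadata columns
#' `peptide_id  mass_kda  migration_min  is_internal_standard` followed by
#' one column per sample. UTF-8, tab-separated, `.` decimal. Empty
#' intensity cells are read as 0 ("not detected"). In memory the matrix is
#' transposed so samples are rows, which is what the statistics expect.
#'
#' @param path file path.
#' @param scale scale tag to stamp on the matrix (`"raw"` for fresh peak
#'   lists).
#' @return `read_peptide_matrix()` returns a [peptide_matrix()];
#'   `write_peptide_matrix()` returns `path` invisibly.
#' @export
read_peptide_matrix <- function(path, scale = "raw") {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  meta_cols <- c("peptide_id", "mass_kda", "migration_min", "is_internal_standard")
  missing_cols <- setdiff(meta_cols, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Peptide matrix file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "uripanel_format_error")
  }
  sample_cols <- setdiff(names(raw), meta_cols)
  if (!length(sample_cols)) abort("No sample columns found.",
                                  class = "uripanel_format_error")
  parse_num <- function(values, column) {
    values[is.na(values) | values == ""] <- "0"
    out <- suppressWarnings(as.numeric(values))
    if (anyNA(out)) {
      bad <- which(is.na(out))[1]
      abort(sprintf("Non-numeric value '%s' at row %d, column '%s'.",
                    values[bad], bad, column),
            class = "uripanel_parse_error")
    }
    out
  }
  intensity_by_peptide <- vapply(sample_cols, function(cn) parse_num(raw[[cn]], cn),
                                 numeric(nrow(raw)))
  if (nrow(raw) == 1L) intensity_by_peptide <- matrix(intensity_by_peptide, nrow = 1L)
  features <- tibble::tibble(
    peptide_id = raw$peptide_id,
    mass_kda = parse_num(raw$mass_kda, "mass_kda"),
    migration_min = parse_num(raw$migration_min, "migration_min"),
    is_internal_standard = tolower(raw$is_internal_standard) %in% c("true", "1", "yes")
  )
  # rows were peptides on disk; transpose to samples x peptides
  intensity <- t(intensity_by_peptide)
  rownames(intensity) <- sample_cols
  peptide_matrix(intensity, features, sample_ids = sample_cols, scale = scale)
}

#' @rdname read_peptide_matrix
#' @param x a `peptide_matrix`.
#' @export
write_peptide_matrix <- function(x, path) {
  stopifnot(inherits(x, "peptide_matrix"))
  wide <- dplyr::bind_cols(
    x$features,
    tibble::as_tibble(t(x$intensity), .name_repair = "minimal")
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
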