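# Small fixtures built in code; no files on disk.

# A hand-sized peptide matrix: `n` samples, peptides given as columns of
# a plain matrix; standards flagged by name prefix "istd".
make_matrix <- function(intensity, ids = NULL, scale = "raw") {
  p <- ncol(intensity)
  if (is.null(ids)) ids <- sprintf("pep%02d", seq_len(p))
  peptide_matrix(
    intensity,
    features = tibble::tibble(
      peptide_id = ids,
      mass_kda = seq(1, 2, length.out = p),
      migration_min = seq(20, 40, length.out = p),
      is_internal_standard = startsWith(ids, "istd")
    ),
    sample_ids = sprintf("s%03d", seq_len(nrow(intensity))),
    scale = scale
  )
}

# Minimal valid clinical rows; override columns as needed.
make_samples <- function(n, stratum = rep("benign", n), psa = rep(5, n)) {
  validate_sample_table(tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    gleason_stratum = stratum,
    age = rep(65, n),
    psa = psa,
    dre_positive = rep(FALSE, n),
    prior_biopsy_count = rep(0L, n),
    prostate_volume_ml = rep(35, n),
    fivear_inhibitor = rep(FALSE, n),
    urinary_creatinine = rep(7.8, n)
  ))
}

# Two-group cohort (cases first) with log-scale values supplied directly.
make_log_cohort <- function(case_mat, control_mat, ids = NULL) {
  X <- rbind(case_mat, control_mat)
  m <- make_matrix(X, ids = ids, scale = "log")
  n_case <- nrow(case_mat)
  samples <- make_samples(
    nrow(X),
    stratum = c(rep("GS3+4", n_case), rep("benign", nrow(control_mat)))
  )
  list(matrix = m, samples = samples)
}

# Exhaustive two-sided permutation p-value for the rank-sum U statistic,
# independent of the implementation under test (combn enumeration).
perm_wilcoxon_p <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  idx <- utils::combn(n + m, n)
  r <- rank(vals)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
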