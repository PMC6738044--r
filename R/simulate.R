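#' Simulation configuration for synthetic CE-MS cohorts
#'
#' Builds the parameter block consumed by [simulate_cohort()]. Defaults
#' describe a mid-sized biopsy cohort with log-normal detected peptide
#' intensities, per-peptide detection probabilities, a block of
#' disease-invariant internal-standard peptides, a planted marker subset
#' with additive log-scale case effects, and clinical covariates whose
#' group differences mirror a typical significant-vs-non-significant
#' prostate cancer cohort (older cases, higher PSA, fewer prior
#' biopsies, smaller prostate volume).
#'
#' @param n_cases,n_controls group sizes (cases = significant PCa).
#' @param n_peptides total number of peptide features.
#' @param n_internal_standards number of disease-invariant standards
#'   (default 29, the usual collagen-fragment reference set size).
#' @param n_true_markers number of peptides with a planted group effect
#'   (default 19).
#' @param effect_sizes signed per-marker shift of mean log-intensity in
#'   log-AU (positive = up in significant PCa). A single number is
#'   recycled, with roughly one marker in six flipped to down-regulation
#'   so both directions are exercised.
#' @param base_log_mean,base_log_sd mean and within-peptide SD of detected
#'   log-intensities (log-AU).
#' @param peptide_log_sd between-peptide SD of baseline log-intensity.
#' @param detection_prob_range range of per-peptide detection
#'   probabilities for background peptides.
#' @param marker_detection detection probability of planted markers.
#' @param detection_effect additive change in marker detection probability
#'   for cases (clipped to (0, 1]).
#' @param intensity_linked_detection if `TRUE`, detection is Bernoulli
#'   with probability logistic in the latent log-intensity instead of
#'   independent of it.
#' @param sample_scale_sd SD (log units) of the per-sample multiplicative
#'   acquisition factor that internal-standard normalisation removes.
#' @param covariate_model named list of covariate parameters; see
#'   defaults in the function body. Set `external_risk_auc = NULL` to
#'   leave the external risk-calculator column `NA`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 50, n_controls = 150,
                       n_peptides = 300,
                       n_internal_standards = 29,
                       n_true_markers = 19,
                       effect_sizes = 1.0,
                       base_log_mean = 9, base_log_sd = 1,
                       peptide_log_sd = 1,
                       detection_prob_range = c(0.4, 0.98),
                       marker_detection = 0.95,
                       detection_effect = 0,
                       intensity_linked_detection = FALSE,
                       sample_scale_sd = 0.25,
                       covariate_model = list()) {
  if (n_true_markers + n_internal_standards > n_peptides) {
    abort("n_true_markers + n_internal_standards must not exceed n_peptides.")
  }
  if (any(detection_prob_range <= 0) || any(detection_prob_range > 1)) {
    abort("detection_prob_range must lie in (0, 1].")
  }
  if (n_true_markers > 0) {
    if (length(effect_sizes) == 1L) {
      sgn <- rep(1, n_true_markers)
      if (n_true_markers >= 6) {
        sgn[seq(6, n_true_markers, by = 6)] <- -1
      }
      effect_sizes <- abs(effect_sizes) * sgn
    }
    if (length(effect_sizes) != n_true_markers) {
      abort("effect_sizes must have length 1 or n_true_markers.")
    }
  } else {
    effect_sizes <- numeric(0)
  }
  cov_defaults <- list(
    age_case = c(mean = 68, sd = 7.6), age_control = c(mean = 63, sd = 8.5),
    psa_case = c(meanlog = log(6.1), sdlog = 0.49),
    psa_control = c(meanlog = log(5.1), sdlog = 0.47),
    dre_pos_case = 0.342, dre_pos_control = 0.139,
    prior_biopsy_case = 0.144, prior_biopsy_control = 0.291,
    extra_biopsies_rate = 0.3,
    volume_case = c(meanlog = log(28), sdlog = 0.47),
    volume_control = c(meanlog = log(37.4), sdlog = 0.45),
    volume_missing = 0.124,
    fivear_case = 0.014, fivear_control = 0.032,
    creatinine = c(meanlog = log(7.8), sdlog = 0.44),
    external_risk_auc = 0.69
  )
  covariate_model <- modifyList(cov_defaults, covariate_model)
  structure(list(
    n_cases = n_cases, n_controls = n_controls, n_peptides = n_peptides,
    n_internal_standards = n_internal_standards,
    n_true_markers = n_true_markers, effect_sizes = effect_sizes,
    base_log_mean = base_log_mean, base_log_sd = base_log_sd,
    peptide_log_sd = peptide_log_sd,
    detection_prob_range = detection_prob_range,
    marker_detection = marker_detection,
    detection_effect = detection_effect,
    intensity_linked_detection = intensity_linked_detection,
    sample_scale_sd = sample_scale_sd,
    covariate_model = covariate_model
  ), class = "sim_config")
}

#' Simulate a synthetic CE-MS peptidomics cohort
#'
#' Draws a raw peptide intensity matrix, a clinical sample table and the
#' simulation ground truth. Detected log-intensities are normal around a
#' per-peptide baseline, shifted by the planted effect in cases for marker
#' peptides; each cell is independently censored to 0 (not detected) with
#' one minus its detection probability; a per-sample multiplicative
#' acquisition factor (removed later by internal-standard normalisation)
#' scales all raw intensities of a sample. Internal standards have no
#' group effect and detection probability >= 0.99.
#'
#' Each sub-generator (intensities, detection, covariates) draws from its
#' own stream derived from `seed`, so the cohort is reproducible and
#' extending one generator does not perturb the others.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list with elements `matrix` (a raw [peptide_matrix()]),
#'   `samples` (validated sample tibble) and `truth` (list with
#'   `markers` tibble of `peptide_id`/`effect`, `internal_standard_ids`,
#'   and the per-sample latent `group`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cases + config$n_controls
  p <- config$n_peptides
  is_case <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  sample_ids <- sprintf("S%04d", seq_len(n))

  marker_idx <- seq_len(config$n_true_markers)
  standard_idx <- config$n_true_markers + seq_len(config$n_internal_standards)
  peptide_ids <- sprintf("pep%05d", seq_len(p))
  peptide_ids[marker_idx] <- sprintf("mark%03d", marker_idx)
  peptide_ids[standard_idx] <- sprintf("istd%03d", seq_along(standard_idx))

  effects <- numeric(p)
  effects[marker_idx] <- config$effect_sizes

  lat <- with_seed(derive_seed(seed, "intensity"), {
    baseline <- rnorm(p, config$base_log_mean, config$peptide_log_sd)
    mass <- exp(rnorm(p, log(2), 0.8))            # kDa, roughly 0.1-12
    migration <- runif(p, 15, 55)                 # min
    noise <- matrix(rnorm(n * p, 0, config$base_log_sd), n, p)
    loglat <- sweep(noise, 2, baseline, `+`) + outer(is_case, effects)
    sample_factor <- exp(rnorm(n, 0, config$sample_scale_sd))
    list(loglat = loglat, mass = mass, migration = migration,
         sample_factor = sample_factor)
  })

  detected <- with_seed(derive_seed(seed, "detection"), {
    pdet <- runif(p, config$detection_prob_range[1], config$detection_prob_range[2])
    pdet[marker_idx] <- config$marker_detection
    pdet[standard_idx] <- 0.995
    pmat <- matrix(rep(pdet, each = n), n, p)
    if (config$detection_effect != 0 && length(marker_idx)) {
      pmat[is_case == 1L, marker_idx] <-
        pmin(1, pmax(1e-3, pmat[is_case == 1L, marker_idx] + config$detection_effect))
    }
    if (config$intensity_linked_detection) {
      # steeper detection for brighter peptides, centred on each peptide's mean
      centred <- sweep(lat$loglat, 2, colMeans(lat$loglat))
      pmat <- stats::plogis(stats::qlogis(pmat) + centred)
    }
    matrix(rbinom(n * p, 1L, as.vector(pmat)), n, p)
  })

  intensity <- exp(lat$loglat) * lat$sample_factor * detected
  features <- tibble::tibble(
    peptide_id = peptide_ids,
    mass_kda = lat$mass,
    migration_min = lat$migration,
    is_internal_standard = seq_len(p) %in% standard_idx
  )
  mat <- peptide_matrix(intensity, features, sample_ids, scale = "raw")

  samples <- with_seed(derive_seed(seed, "covariates"),
                       simulate_covariates(sample_ids, is_case, config$covariate_model))

  truth <- list(
    markers = tibble::tibble(peptide_id = peptide_ids[marker_idx],
                             effect = effects[marker_idx]),
    internal_standard_ids = peptide_ids[standard_idx],
    group = tibble::tibble(sample_id = sample_ids, is_case = is_case)
  )
  list(matrix = mat, samples = samples, truth = truth)
}

# Clinical covariates with group differences in the usual directions:
# cases older, higher PSA, fewer prior biopsies, smaller prostates.
simulate_covariates <- function(sample_ids, is_case, cm) {
  n <- length(sample_ids)
  case <- is_case == 1L
  draw2 <- function(fun, parc, parn) {
    out <- numeric(n)
    out[case] <- do.call(fun, c(list(sum(case)), as.list(unname(parc))))
    out[!case] <- do.call(fun, c(list(sum(!case)), as.list(unname(parn))))
    out
  }
  age <- round(draw2(rnorm, cm$age_case, cm$age_control))
  age <- pmin(pmax(age, 40), 90)
  psa <- draw2(rlnorm, cm$psa_case, cm$psa_control)
  # inclusion criterion: PSA < 15 ng/ml; redraw the tail by reflection
  while (any(psa >= 15)) {
    idx <- which(psa >= 15)
    psa[idx] <- draw2(rlnorm, cm$psa_case, cm$psa_control)[idx]
  }
  dre <- rbinom(n, 1, ifelse(case, cm$dre_pos_case, cm$dre_pos_control)) == 1
  any_biopsy <- rbinom(n, 1, ifelse(case, cm$prior_biopsy_case,
                                    cm$prior_biopsy_control))
  n_biopsy <- any_biopsy * (1L + rpois(n, cm$extra_biopsies_rate))
  vol <- draw2(rlnorm, cm$volume_case, cm$volume_control)
  vol[rbinom(n, 1, cm$volume_missing) == 1] <- NA_real_
  fivear <- rbinom(n, 1, ifelse(case, cm$fivear_case, cm$fivear_control)) == 1
  crea <- rlnorm(n, cm$creatinine[["meanlog"]], cm$creatinine[["sdlog"]])
  external <- rep(NA_real_, n)
  if (!is.null(cm$external_risk_auc)) {
    delta <- sqrt(2) * qnorm(cm$external_risk_auc)
    external <- stats::plogis(-1.5 + delta * case + rnorm(n))
  }
  # cases carry Gleason >= 7 strata in realistic proportions;
  # controls split between benign aetiologies and Gleason 6
  stratum <- character(n)
  stratum[case] <- sample(sig_strata(), sum(case), replace = TRUE,
                          prob = c(0.651, 0.199, 0.096, 0.054))
  stratum[!case] <- sample(c("benign", "GS6"), sum(!case), replace = TRUE,
                           prob = c(0.806, 0.194))
  validate_sample_table(tibble::tibble(
    sample_id = sample_ids,
    gleason_stratum = stratum,
    age = age, psa = psa, dre_positive = dre,
    prior_biopsy_count = as.integer(n_biopsy),
    prostate_volume_ml = vol,
    fivear_inhibitor = fivear,
    urinary_creatinine = crea,
    external_risk = external
  ))
}

#' Study-scale cohort preset
#'
#' Convenience preset at the scale of a large single-centre biopsy
#' cohort: 823 samples (146 significant-PCa cases, 677 controls), 19
#' planted markers at 1.5 log-AU with high detection, 29 internal
#' standards, 1000 peptide features. A stratified 2/3-1/3 split of this
#' cohort yields roughly 97/451 discovery and 49/226 validation samples.
#'
#' @param seed integer seed.
#' @param n_peptides number of peptide features (default 1000).
#' @param effect_size planted marker effect magnitude in log-AU.
#' @return As [simulate_cohort()].
#' @export
simulate_study_scale <- function(seed = 1, n_peptides = 1000,
                                 effect_size = 1.5) {
  cfg <- sim_config(
    n_cases = 146, n_controls = 677,
    n_peptides = n_peptides,
    n_internal_standards = 29,
    n_true_markers = 19,
    effect_sizes = effect_size,
    marker_detection = 0.95
  )
  simulate_cohort(cfg, seed = seed)
}
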