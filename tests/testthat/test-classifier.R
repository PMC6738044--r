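# A deterministic separable toy cohort: one informative peptide.
toy_cohort <- function(n = 12, gap = 4) {
  case <- matrix(rnorm(n * 2, c(8, 5), 0.3), n, 2, byrow = TRUE)
  ctrl <- matrix(rnorm(n * 2, c(8 - gap, 5), 0.3), n, 2, byrow = TRUE)
  make_log_cohort(case, ctrl)
}

toy_panel <- function(ids, directions = rep("up_in_sig", length(ids))) {
  tibble::tibble(peptide_id = ids, direction = directions)
}

test_that("a separable toy problem is classified perfectly on discovery", {
  set.seed(1)
  co <- toy_cohort()
  model <- train_svm(co$matrix, co$samples, co$samples$sample_id,
                     toy_panel("pep01"), kernel = "linear")
  scored <- score_samples(model, co$matrix, co$samples)
  expect_true(all(scored$predicted == scored$outcome))
  # perfectly separated: the youden cutoff is the midpoint of the gap
  s_case <- scored$score[scored$outcome == "sig"]
  s_ctrl <- scored$score[scored$outcome == "nonsig"]
  expect_equal(model$cutoff, (min(s_case) + max(s_ctrl)) / 2, tolerance = 1e-9)
})

test_that("training and scoring are deterministic and self-consistent", {
  set.seed(2)
  co <- toy_cohort(gap = 1.5)
  sp <- stratified_split(co$samples, seed = 4)
  m1 <- train_svm(co$matrix, co$samples, sp, toy_panel(c("pep01", "pep02")))
  m2 <- train_svm(co$matrix, co$samples, sp, toy_panel(c("pep01", "pep02")))
  s1 <- score_samples(m1, co$matrix, co$samples)
  s2 <- score_samples(m2, co$matrix, co$samples)
  expect_equal(s1$score, s2$score, tolerance = 1e-9)
  expect_identical(m1$cutoff, m2$cutoff)
  # scoring the discovery set reproduces training-time decision values
  disc_ids <- split_ids(sp, "discovery")
  again <- score_samples(m1, co$matrix, co$samples, sample_ids = disc_ids)
  expect_equal(again$score, s1$score[match(disc_ids, s1$sample_id)],
               tolerance = 1e-12)
})

test_that("censored zeros score as the floor feature vector", {
  set.seed(3)
  co <- toy_cohort(gap = 2)
  model <- train_svm(co$matrix, co$samples, co$samples$sample_id,
                     toy_panel(c("pep01", "pep02")))
  X0 <- co$matrix$intensity
  X0[1, ] <- 0  # all panel peptides undetected in sample 1
  m0 <- peptide_matrix(X0, co$matrix$features, co$matrix$sample_ids, "log")
  scored <- score_samples(model, m0, co$samples)
  Xf <- co$matrix$intensity
  Xf[1, c("pep01", "pep02")] <- model$floors
  mf <- peptide_matrix(Xf, co$matrix$features, co$matrix$sample_ids, "log")
  scored_f <- score_samples(model, mf, co$samples)
  expect_equal(scored$score[1], scored_f$score[1], tolerance = 1e-12)
})

test_that("linear-kernel scores are monotone along the learned weight sign", {
  set.seed(4)
  co <- toy_cohort(gap = 2)
  model <- train_svm(co$matrix, co$samples, co$samples$sample_id,
                     toy_panel(c("pep01", "pep02")), kernel = "linear")
  w <- model$orientation *
    as.numeric(t(model$svm$coefs) %*% model$svm$SV)
  expect_gt(w[1], 0)  # pep01 is up in cases
  bump <- co$matrix$intensity
  bump[, "pep01"] <- bump[, "pep01"] + 0.5
  mb <- peptide_matrix(bump, co$matrix$features, co$matrix$sample_ids, "log")
  s0 <- score_samples(model, co$matrix, co$samples)$score
  s1 <- score_samples(model, mb, co$samples)$score
  expect_true(all(s1 >= s0 - 1e-9))

  # flipping the feature flips the learned weight
  flip <- co$matrix$intensity
  flip[, "pep01"] <- -flip[, "pep01"]
  mflip <- peptide_matrix(flip - min(flip) + 1, co$matrix$features,
                          co$matrix$sample_ids, "log")
  model_f <- train_svm(mflip, co$samples, co$samples$sample_id,
                       toy_panel(c("pep01", "pep02")), kernel = "linear")
  w_f <- model_f$orientation *
    as.numeric(t(model_f$svm$coefs) %*% model_f$svm$SV)
  expect_lt(w_f[1] * w[1], 0)
})

test_that("cutoff selection matches a brute-force scan and honours targets", {
  set.seed(5)
  scores <- rnorm(60)
  outcomes <- factor(rep(c("sig", "nonsig"), 30), levels = c("nonsig", "sig"))
  got <- select_cutoff(scores, outcomes, "youden")
  grid <- sort(unique(c(scores - 1e-6, scores + 1e-6)))
  j <- vapply(grid, function(ct) {
    mean(scores[outcomes == "sig"] >= ct) +
      mean(scores[outcomes == "nonsig"] < ct) - 1
  }, numeric(1))
  j_got <- mean(scores[outcomes == "sig"] >= got) +
    mean(scores[outcomes == "nonsig"] < got) - 1
  expect_equal(j_got, max(j), tolerance = 1e-12)

  ct <- select_cutoff(scores, outcomes, "target_sensitivity", target = 1)
  expect_lte(ct, min(scores[outcomes == "sig"]))
  expect_error(select_cutoff(scores, outcomes, "target_sensitivity",
                             target = 1.2), "\\[0, 1\\]")
})

test_that("probability calibration is monotone in the score", {
  set.seed(6)
  co <- toy_cohort(gap = 1)
  model <- train_svm(co$matrix, co$samples, co$samples$sample_id,
                     toy_panel(c("pep01", "pep02")))
  scored <- score_samples(model, co$matrix, co$samples)
  ord <- order(scored$score)
  expect_true(all(diff(scored$probability[ord]) >= -1e-12))
  expect_true(all(scored$probability >= 0 & scored$probability <= 1))
})

test_that("scoring refuses a matrix lacking panel columns", {
  set.seed(7)
  co <- toy_cohort()
  model <- train_svm(co$matrix, co$samples, co$samples$sample_id,
                     toy_panel(c("pep01", "pep02")))
  keep <- co$matrix$features$peptide_id != "pep02"
  m_missing <- peptide_matrix(co$matrix$intensity[, keep, drop = FALSE],
                              co$matrix$features[keep, ],
                              co$matrix$sample_ids, "log")
  expect_error(score_samples(model, m_missing, co$samples), "pep02",
               class = "uripanel_validation_error")
  expect_error(train_svm(co$matrix, co$samples, co$samples$sample_id,
                         toy_panel(character(0))),
               "empty panel", class = "uripanel_validation_error")
})
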