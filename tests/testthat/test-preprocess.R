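test_that("normalisation factors follow the median-ratio definition", {
  # standards constant across samples: every factor is exactly 1
  X <- cbind(matrix(runif(12, 10, 100), 4, 3),
             matrix(rep(c(50, 80), each = 4), 4, 2))
  m <- make_matrix(X, ids = c("pep01", "pep02", "pep03", "istd01", "istd02"))
  norm <- fit_normalisation(m)
  expect_equal(norm$factors$factor, rep(1, 4))

  # one sample with all standards at half reference -> factor 2
  X2 <- X
  X2[2, 4:5] <- X2[2, 4:5] / 2
  m2 <- make_matrix(X2, ids = c("pep01", "pep02", "pep03", "istd01", "istd02"))
  norm2 <- fit_normalisation(m2)
  expect_equal(norm2$factors$factor[2], 2)

  # a sample with no detected standard is an error naming the sample
  X3 <- X
  X3[3, 4:5] <- 0
  m3 <- make_matrix(X3, ids = c("pep01", "pep02", "pep03", "istd01", "istd02"))
  expect_error(fit_normalisation(m3), "s003",
               class = "uripanel_validation_error")
})

test_that("applying normalisation scales rows, keeps zeros, and is idempotent", {
  set.seed(3)
  X <- matrix(rlnorm(80, 4, 1), 8, 10)
  X[sample(length(X), 10)] <- 0
  X[, 9:10] <- matrix(rlnorm(16, 5, 0.3), 8, 2)  # standards always detected
  ids <- c(sprintf("pep%02d", 1:8), "istd01", "istd02")
  m <- make_matrix(X, ids = ids)
  norm <- fit_normalisation(m)
  nm <- apply_normalisation(m, norm)
  expect_identical(nm$scale, "normalised")
  expect_true(all((nm$intensity == 0) == (X == 0)))
  fac <- norm$factors$factor
  expect_equal(unname(nm$intensity[4, ]), X[4, ] * fac[4])

  # post-condition by direct recomputation: in every sample the median
  # ratio of reference to normalised standard intensity is exactly 1
  ref <- setNames(norm$reference$reference, norm$reference$peptide_id)
  for (i in 1:8) {
    obs <- nm$intensity[i, names(ref)]
    det <- obs > 0
    expect_equal(median(ref[det] / obs[det]), 1, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  # refitting against the model's own reference is exactly idempotent
  nm_raw <- peptide_matrix(nm$intensity, nm$features, nm$sample_ids, "raw")
  refit <- fit_normalisation(nm_raw, reference = norm$reference)
  expect_equal(refit$factors$factor, rep(1, 8), tolerance = 1e-12)

  expect_error(apply_normalisation(nm, norm), "raw",
               class = "uripanel_scale_error")
})

test_that("log transform maps detected values and preserves rank order", {
  X <- matrix(c(exp(1), 0, 20, 7, 3, 150), 2, 3)
  m <- make_matrix(X, scale = "normalised")
  lm <- log_transform(m)
  expect_equal(lm$intensity[1, 1], 1.0)
  expect_identical(lm$intensity[2, 1], 0)
  expect_identical(lm$scale, "log")

  set.seed(8)
  Y <- matrix(rlnorm(60, 5, 2) + 1, 6, 10)
  my <- make_matrix(Y, scale = "normalised")
  ly <- log_transform(my)
  for (j in 1:10) {
    expect_identical(order(ly$intensity[, j]), order(Y[, j]))
  }
  # an intensity of exactly 1 logs to 0 and collides with the
  # non-detect code; that is warned about
  expect_warning(log_transform(make_matrix(matrix(c(1, 5), 1, 2),
                                           scale = "normalised")),
                 "collide")
  expect_error(log_transform(make_matrix(Y, scale = "raw")),
               class = "uripanel_scale_error")
})

test_that("detection frequencies match a brute-force loop", {
  set.seed(13)
  X <- matrix(rbinom(200, 1, 0.6) * rlnorm(200, 4, 1), 20, 10)
  m <- make_matrix(X)
  samples <- make_samples(20, stratum = c(rep("GS8", 7), rep("benign", 13)))
  freq <- detection_frequencies(m, samples)
  for (j in seq_len(10)) {
    n_case <- 0; n_ctrl <- 0
    for (i in seq_len(20)) {
      if (X[i, j] > 0) {
        if (i <= 7) n_case <- n_case + 1 else n_ctrl <- n_ctrl + 1
      }
    }
    expect_equal(freq$case_freq[j], n_case / 7)
    expect_equal(freq$control_freq[j], n_ctrl / 13)
  }
  # a never-detected peptide scores 0 in both groups
  X2 <- X; X2[, 1] <- 0
  freq2 <- detection_frequencies(make_matrix(X2), samples)
  expect_equal(freq2$case_freq[1], 0)
  expect_equal(freq2$control_freq[1], 0)
})

test_that("stratified split follows the rounding rule and is reproducible", {
  s <- make_samples(146 + 677,
                    stratum = c(rep("GS3+4", 146), rep("benign", 677)))
  sp <- stratified_split(s, 2 / 3, seed = 10)
  disc <- sp[sp$set == "discovery", ]
  # round(146 * 2/3) = round(97.33) = 97; round(677 * 2/3) = 451
  expect_equal(sum(s$outcome[match(disc$sample_id, s$sample_id)] == "sig"), 97)
  expect_equal(sum(s$outcome[match(disc$sample_id, s$sample_id)] == "nonsig"), 451)

  s2 <- make_samples(18, stratum = rep(c("GS8", "benign"), each = 9))
  sp2 <- stratified_split(s2, 2 / 3, seed = 1)
  tab <- table(sp2$set, s2$outcome[match(sp2$sample_id, s2$sample_id)])
  expect_equal(unname(tab["discovery", c("sig", "nonsig")]), c(6, 6))

  expect_identical(stratified_split(s2, 2 / 3, seed = 5),
                   stratified_split(s2, 2 / 3, seed = 5))
  expect_false(identical(stratified_split(s2, 2 / 3, seed = 5)$set,
                         stratified_split(s2, 2 / 3, seed = 6)$set))
})

test_that("split invariants hold on random draws", {
  set.seed(99)
  for (rep in 1:20) {
    n_sig <- sample(5:40, 1)
    n_non <- sample(5:80, 1)
    frac <- runif(1, 0.4, 0.8)
    s <- make_samples(n_sig + n_non,
                      stratum = c(rep("GS4+3", n_sig), rep("GS6", n_non)))
    sp <- stratified_split(s, frac, seed = rep)
    expect_setequal(sp$sample_id, s$sample_id)
    expect_equal(sum(sp$set == "discovery") + sum(sp$set == "validation"),
                 n_sig + n_non)
    oc <- s$outcome[match(sp$sample_id, s$sample_id)]
    for (cls in c("sig", "nonsig")) {
      n_cls <- sum(oc == cls)
      got <- sum(sp$set == "discovery" & oc == cls)
      expect_lte(abs(got - frac * n_cls), 1)
    }
  }
  expect_error(stratified_split(make_samples(4, stratum = c("GS8", rep("benign", 3))),
                                0.9, seed = 1),
               "too small", class = "uripanel_validation_error")
})

test_that("normalisation commutes with log-scale shifts", {
  set.seed(7)
  X <- matrix(rlnorm(60, 6, 1), 6, 10)
  ids <- c(sprintf("pep%02d", 1:7), sprintf("istd%02d", 1:3))
  m <- make_matrix(X, ids = ids)
  norm <- fit_normalisation(m)
  l1 <- log_transform(apply_normalisation(m, norm))
  # scaling a sample's AU by c shifts its raw log by log(c); against a
  # fixed reference the normalised log matrix is unchanged
  X2 <- X; X2[3, ] <- X2[3, ] * 4.7
  m2 <- make_matrix(X2, ids = ids)
  l2 <- log_transform(apply_normalisation(m2,
                                          fit_normalisation(m2, norm$reference)))
  expect_equal(l2$intensity, l1$intensity, tolerance = 1e-12)
})
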