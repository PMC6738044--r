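test_that("ROC handles the degenerate extremes", {
  out <- rep(c("sig", "nonsig"), each = 5)
  r <- roc_curve(c(rep(2, 5), rep(1, 5)), out)
  expect_equal(r$auc, 1)
  r2 <- roc_curve(rep(1, 10), out)
  expect_equal(r2$auc, 0.5)
  expect_error(roc_curve(1:5, rep("sig", 5)),
               class = "uripanel_validation_error")
})

test_that("AUC equals the tie-aware pair-counting oracle and its own trapezoid", {
  set.seed(30)
  for (i in 1:30) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    scores <- c(round(rnorm(n1, 0.5), 1), round(rnorm(n0), 1))  # many ties
    out <- rep(c("sig", "nonsig"), c(n1, n0))
    r <- roc_curve(scores, out)
    x <- scores[seq_len(n1)]; y <- scores[n1 + seq_len(n0)]
    conc <- 0
    for (a in x) for (b in y) conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(r$auc, conc / (n1 * n0), tolerance = 1e-12)
    # trapezoid over the stored curve
    fpr <- 1 - r$curve$specificity
    tpr <- r$curve$sensitivity
    area <- -sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(r$auc, area, tolerance = 1e-12)
    expect_true(all(diff(r$curve$sensitivity) <= 1e-12))
    expect_gte(r$auc, r$ci_lo); expect_lte(r$auc, r$ci_hi)
  }
})

test_that("DeLong variance and test agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(31)
  out <- rep(c("sig", "nonsig"), c(40, 60))
  a <- rnorm(100) + (out == "sig") * 0.8
  b <- rnorm(100) + (out == "sig") * 0.4 + 0.3 * a
  r <- roc_curve(a, out)
  pr <- pROC::roc(response = out, predictor = a, levels = c("nonsig", "sig"),
                  direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(sqrt(r$auc_var), sqrt(pROC::var(pr)), tolerance = 1e-9)

  ours <- delong_test(a, b, out)
  prb <- pROC::roc(response = out, predictor = b, levels = c("nonsig", "sig"),
                   direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(pr, prb, method = "delong")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$z, unname(ref$statistic), tolerance = 1e-9)
})

test_that("self-comparison and hand-sized DeLong cases behave", {
  set.seed(32)
  out <- rep(c("sig", "nonsig"), each = 10)
  s <- rnorm(20)
  self <- delong_test(s, s, out)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)

  out6 <- c("sig", "sig", "sig", "nonsig", "nonsig", "nonsig")
  a <- c(3, 4, 5, 0, 1, 2)   # perfectly separating
  b <- -a                    # anti-separating
  dt <- delong_test(a, b, out6)
  expect_equal(dt$auc_a, 1)
  expect_equal(dt$auc_b, 0)
  expect_equal(dt$delta, 1)
  expect_error(delong_test(a, b[-1], out6),
               class = "uripanel_validation_error")
})

test_that("sensitivity/specificity at a cutoff match explicit bookkeeping", {
  set.seed(33)
  scored <- tibble::tibble(
    score = rnorm(50),
    outcome = factor(sample(c("sig", "nonsig"), 50, TRUE),
                     levels = c("nonsig", "sig"))
  )
  cut <- 0.2
  res <- sens_spec_at_cutoff(scored, cutoff = cut)
  tp <- fp <- tn <- fn <- 0
  for (i in 1:50) {
    pos <- scored$score[i] >= cut
    if (pos && scored$outcome[i] == "sig") tp <- tp + 1
    if (pos && scored$outcome[i] == "nonsig") fp <- fp + 1
    if (!pos && scored$outcome[i] == "nonsig") tn <- tn + 1
    if (!pos && scored$outcome[i] == "sig") fn <- fn + 1
  }
  sens <- res[res$metric == "sensitivity", ]
  spec <- res[res$metric == "specificity", ]
  expect_equal(sens$estimate, tp / (tp + fn))
  expect_equal(spec$estimate, tn / (tn + fp))
  expect_equal(as.list(attr(res, "confusion")),
               list(tp = tp, fp = fp, tn = tn, fn = fn))
  # extremes
  lo <- sens_spec_at_cutoff(scored, cutoff = min(scored$score) - 1)
  expect_equal(lo$estimate, c(1, 0))
  hi <- sens_spec_at_cutoff(scored, cutoff = max(scored$score) + 1)
  expect_equal(hi$estimate, c(0, 1))
  # Clopper-Pearson intervals bracket the estimates
  expect_true(all(res$lo <= res$estimate & res$estimate <= res$hi))
})

test_that("cohort summaries are self-consistent and handle degenerate input", {
  sim <- simulate_cohort(sim_config(n_cases = 40, n_controls = 80,
                                    n_peptides = 30, n_true_markers = 0),
                         seed = 12)
  cs <- cohort_summary(sim$samples, group = "outcome")
  tab <- cs$summary
  cat_rows <- tab[!is.na(tab$level) & tab$variable != "gleason_stratum", ]
  expect_equal(cat_rows$pct, 100 * cat_rows$n / cat_rows$n_obs)
  expect_true(all(cs$tests$p_value >= 0 & cs$tests$p_value <= 1))
  counts <- tab[tab$variable == "samples", ]
  expect_equal(sum(counts$n), nrow(sim$samples))

  flat <- sim$samples
  flat$age <- 65
  p_age <- glance(cohort_summary(flat, "outcome"))
  expect_equal(p_age$p_value[p_age$variable == "age"], 1)
  iqr_age <- tidy(cohort_summary(flat, "outcome"))
  expect_equal(iqr_age$iqr[iqr_age$variable == "age"], c(0, 0))
})

test_that("kruskal-wallis separates classifier scores across Gleason strata", {
  set.seed(44)
  sim <- simulate_cohort(sim_config(n_cases = 60, n_controls = 120,
                                    n_peptides = 80, n_true_markers = 10,
                                    effect_sizes = 2), seed = 44)
  res <- run_panel_pipeline(sim$matrix, sim$samples, seed = 44)
  scored <- res$scored_validation
  kw <- kruskal_wallis(scored$score, as.character(scored$gleason_stratum))
  expect_lt(kw$p_value, 0.05)
  # two-group comparison of scores: cases score higher
  expect_gt(median(scored$score[scored$outcome == "sig"]),
            median(scored$score[scored$outcome == "nonsig"]))
})
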