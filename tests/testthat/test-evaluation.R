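test_that("trapezoidal AUC equals the brute-force pairwise oracle on random instances", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5) # both classes present
    scores <- round(rnorm(n), sample(0:2, 1))    # rounding induces ties
    got <- roc_auc(scores, labels, direction = "lower")
    expect_equal(got$auc, brute_force_auc(scores, labels),
                 tolerance = 1e-12)
    # ROC is a valid monotone curve from (0,0) to (1,1)
    expect_equal(got$roc$fpr[1], 0)
    expect_equal(got$roc$tpr[1], 0)
    expect_equal(got$roc$fpr[nrow(got$roc)], 1)
    expect_equal(got$roc$tpr[nrow(got$roc)], 1)
    expect_true(all(diff(got$roc$fpr) >= 0))
    expect_true(all(diff(got$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:5) {
    scores <- rnorm(60)
    labels <- runif(60) < 0.4
    if (!any(labels) || all(labels)) next
    ours <- roc_auc(scores, labels, direction = "lower")$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, direction = ">",
      quiet = TRUE)))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("AUC edge cases: separation, all ties, monotone-transform invariance", {
  expect_equal(roc_auc(c(-3, -2, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                       "lower")$auc, 1.0)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5),
                       "lower")$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
  set.seed(22)
  scores <- rnorm(40); labels <- runif(40) < 0.5
  labels[1:2] <- c(TRUE, FALSE)
  a1 <- roc_auc(scores, labels, "lower")$auc
  a2 <- roc_auc(exp(scores), labels, "lower")$auc   # strictly monotone
  a3 <- roc_auc(scores^3 + 5 * scores, labels, "lower")$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
  # spec example: pos = {-2,-1,0}, neg = {-1.5, 0.5, 1, 2}
  sc <- c(-2, -1, 0, -1.5, 0.5, 1, 2)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(sc, lb, "lower")$auc, brute_force_auc(sc, lb))
})

test_that("parametric 95%-specificity cutoff is the -1.645 normal quantile", {
  set.seed(31)
  ref <- rnorm(5000)
  cut <- cutoff_for_specificity(ref, 0.95, "parametric")
  expect_equal(cut, qnorm(0.05) * sd(ref) + mean(ref))
  expect_equal(cut, -1.645, tolerance = 0.05)
  expect_error(cutoff_for_specificity(ref, 1.2), "between 0 and 1")
})

test_that("empirical cutoff leaves at most the allowed fraction of references below", {
  ref <- c(-3, -2, -1, 0:16) # 20 values
  cut <- suppressWarnings(
    cutoff_for_specificity(ref, 0.95, "empirical"))
  expect_gt(cut, -3); expect_lt(cut, -2)
  expect_equal(sum(ref < cut), 1) # exactly one reference below
  # target 0.5 on a symmetric reference ~ the median
  set.seed(32)
  sym <- rnorm(1001)
  cut50 <- cutoff_for_specificity(sym, 0.5, "empirical")
  expect_lt(abs(cut50 - median(sym)), 0.02)
})

test_that("optimal cutoff maximizes (sens+spec)/2 against an exhaustive scan", {
  # separated classes: perfect operating point inside the gap
  opt <- optimal_cutoff(c(-3, -2, -1, 0, 1),
                        c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_gt(opt$cutoff, -2); expect_lte(opt$cutoff, -1)
  expect_equal(opt$youden_mean, 1)
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)
  # random overlapping instances match the dense-grid oracle
  set.seed(33)
  for (i in 1:10) {
    scores <- rnorm(30)
    labels <- c(TRUE, FALSE, runif(28) < 0.5)
    opt <- optimal_cutoff(scores, labels)
    expect_equal(opt$youden_mean, brute_force_optimal(scores, labels),
                 tolerance = 1e-9)
    expect_gte(opt$youden_mean, 0.5)
  }
  # identical distributions still achieve >= 0.5 (degenerate cutoffs)
  opt0 <- optimal_cutoff(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_gte(opt0$youden_mean, 0.5)
})

test_that("likelihood-ratio identities and undefined poles", {
  lr <- likelihood_ratios(0.59, 0.95)
  expect_equal(lr$lr_pos, 11.8)
  expect_equal(lr$lr_neg, 0.4315789, tolerance = 1e-6)
  expect_equal(likelihood_ratios(0.82, 0.80)$lr_pos, 4.1)
  expect_equal(likelihood_ratios(1.0, 0.5)$lr_neg, 0)
  expect_true(is.na(likelihood_ratios(0.5, 1)$lr_pos))
  expect_true(is.na(likelihood_ratios(0.5, 0)$lr_neg))
  expect_error(likelihood_ratios(1.2, 0.5), "\\[0, 1\\]")
  # identities hold at every operating point of a ROC curve
  set.seed(34)
  z <- rnorm(50); labels <- c(TRUE, FALSE, runif(48) < 0.4)
  rc <- roc_auc(z, labels, "lower")$roc
  for (j in seq_len(nrow(rc))) {
    sens <- rc$tpr[j]; spec <- 1 - rc$fpr[j]
    lr <- likelihood_ratios(sens, spec)
    if (!is.na(lr$lr_pos)) {
      expect_equal(lr$lr_pos, sens / (1 - spec), tolerance = 1e-12)
    }
    if (!is.na(lr$lr_neg)) {
      expect_equal(lr$lr_neg, (1 - sens) / spec, tolerance = 1e-12)
    }
  }
})

test_that("cross-validation partitions the cohort, is seed-reproducible, and pools held-out scores", {
  cfg <- simulation_config(preset = "small")
  co <- generate_cohort(cfg, seed = 10)
  cv1 <- crossvalidate(co, "API", k = 5, seed = 17)
  cv2 <- crossvalidate(co, "API", k = 5, seed = 17)
  cv3 <- crossvalidate(co, "API", k = 5, seed = 18)
  # every subject in exactly one test fold
  expect_setequal(cv1$scores$subject_id, co$subjects$subject_id)
  expect_true(all(cv1$scores$fold %in% 1:5))
  expect_true(all(table(cv1$scores$fold) > 0))
  # determinism in folds and metrics
  expect_equal(cv1$scores, cv2$scores)
  expect_equal(cv1$report$auc, cv2$report$auc)
  expect_false(identical(cv1$scores$fold, cv3$scores$fold))
  # pooled CV AUC close to train-on-all AUC on this synthetic cohort
  fit_all <- fit_index(co, "API")
  sc <- predict(fit_all, co)
  auc_all <- roc_auc(sc$z, diagnosis_in(co, "FTD"), "lower")$auc
  expect_lt(abs(cv1$report$auc - auc_all), 0.1)
})

test_that("cross-validation never lets test subjects touch training parameters", {
  cfg <- simulation_config(preset = "small")
  co <- generate_cohort(cfg, seed = 11)
  # reproduce the fold assignment used internally
  k <- 5; seed <- 23
  fold <- integer(nrow(co$subjects))
  set.seed(seed)
  for (dx in unique(co$subjects$diagnosis)) {
    idx <- which(co$subjects$diagnosis == dx)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  # poison fold 1's volumes: training on folds 2..k must be unchanged
  poisoned <- co
  poisoned$volumes[fold == 1, ] <- poisoned$volumes[fold == 1, ] * 50
  m_clean <- fit_index(subset_cohort(co, fold != 1), "API")
  m_poison <- fit_index(subset_cohort(poisoned, fold != 1), "API")
  expect_equal(m_poison$weights, m_clean$weights)
  expect_equal(m_poison$mu, m_clean$mu)
  expect_equal(m_poison$sigma, m_clean$sigma)
  expect_equal(m_poison$normalization$age_coef,
               m_clean$normalization$age_coef)
  expect_equal(m_poison$normalization$reference_tiv,
               m_clean$normalization$reference_tiv)
})

test_that("age stratification splits strictly below vs at/above the threshold", {
  v <- matrix(runif(3 * 8, 2, 8), nrow = 3)
  co <- tiny_cohort(v, c("AD", "SCD", "FTD"), age = c(60, 70, 80))
  strata <- stratify_age(co, 70)
  expect_equal(strata$below$subjects$age, 60)
  expect_equal(strata$at_or_above$subjects$age, c(70, 80))
  expect_equal(nrow(strata$below$subjects) +
                 nrow(strata$at_or_above$subjects), 3)
  expect_warning(s2 <- stratify_age(co, 10), "empty stratum")
  expect_null(s2$below)
})
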