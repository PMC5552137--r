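test_that("confusion matrix counts the four outcomes", {
  cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cm[c("TP", "FN", "FP", "TN")],
                   list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  all_ok <- confusion_matrix(c(1, 0, 1), c(1, 0, 1))
  expect_identical(all_ok$FN + all_ok$FP, 0L)
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(1, 0), c(1)), "length")
})

test_that("metric formulas reproduce the published confusion-matrix values", {
  m <- classification_metrics(list(TP = 11461, FN = 12, FP = 0, TN = 11988))
  expect_equal(truncate_decimal(m$Sn), 0.9989)
  expect_equal(m$Sp, 1)
  expect_equal(truncate_decimal(m$Acc), 0.9994)
  expect_equal(truncate_decimal(m$MCC), 0.9989)
  expect_identical(m$undefined, character(0))
})

test_that("metric edge cases: chance, perfection, undefined denominators", {
  m <- classification_metrics(list(TP = 25, FN = 25, FP = 25, TN = 25))
  expect_equal(m$Acc, 0.5)
  expect_equal(m$MCC, 0)
  mp <- classification_metrics(list(TP = 10, FN = 0, FP = 0, TN = 7))
  expect_equal(mp$MCC, 1)
  mu <- classification_metrics(list(TP = 0, FN = 0, FP = 2, TN = 3))
  expect_true(is.na(mu$Sn))
  expect_true(all(c("Sn", "MCC") %in% mu$undefined))
})

test_that("truncation (not rounding) matches the printing convention", {
  expect_equal(truncate_decimal(0.99949), 0.9994)
  expect_equal(truncate_decimal(0.99999), 0.9999)
  expect_equal(truncate_decimal(99.948, 1), 99.9)
})

test_that("ROC sweep: envelope, monotonicity, extremes", {
  r <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(roc_curve(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  expect_error(roc_curve(c(0.4, 0.6), c(1, 1)), "positive and")
})

test_that("AUC equals the rank-statistic oracle, and pROC agrees", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)   # force some ties
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.6)
  labels <- c(0, 0, 1, 1, 0, 1)
  expect_equal(roc_curve(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("fold plans are balanced partitions, reproducible by seed", {
  for (case in list(c(10, 10), c(23, 5), c(101, 10))) {
    n <- case[1]; k <- case[2]
    f <- kfold_split(n, k, seed = 3)
    expect_length(f, k)
    expect_identical(sort(unlist(f)), 1:n)            # union = S
    expect_identical(anyDuplicated(unlist(f)), 0L)    # pairwise disjoint
    expect_lte(diff(range(lengths(f))), 1L)           # |Si| ~ |Sj|
  }
  expect_identical(kfold_split(30, 4, seed = 5), kfold_split(30, 4, seed = 5))
  expect_false(identical(kfold_split(30, 4, seed = 5),
                         kfold_split(30, 4, seed = 6)))
  expect_error(kfold_split(5, 6), "folds")
  expect_error(kfold_split(5, 1), "at least 2")
})

test_that("stratified folds balance both classes and the total", {
  strata <- rep(c(0, 1), c(30, 33))
  f <- kfold_split(63, 10, seed = 2, strata = strata)
  expect_identical(sort(unlist(f)), 1:63)
  expect_lte(diff(range(lengths(f))), 1L)
  per_class <- sapply(f, function(ix) sum(strata[ix] == 1))
  expect_lte(diff(range(per_class)), 1L)
})

test_that("cross-validation reports per-fold and mean accuracies", {
  d <- quick_dataset(15)                       # 30 windows
  cv <- cross_validate(d, k = 3, quick_config())
  expect_identical(nrow(cv$per_fold), 3L)
  expect_equal(cv$Ra, mean(cv$per_fold$accuracy))
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 1))
  # fold plan covers the dataset
  expect_identical(sort(unlist(cv$folds)), seq_len(nrow(d)))
})

test_that("self-consistency trains and tests on the same data", {
  d <- quick_dataset(15)
  sc <- self_consistency(d, quick_config())
  with(sc$confusion, expect_identical(TP + FN + FP + TN, nrow(d)))
  expect_s3_class(sc$roc, "nglyc_roc")
  # deterministic given the seed
  sc2 <- self_consistency(d, quick_config())
  expect_identical(sc$scores, sc2$scores)
})

test_that("resubstitution is at least as optimistic as cross-validation", {
  d <- generate_dataset(sim_config(40, 40, sequon_prob_pos = 1,
                                   sequon_prob_neg = 0, seed = 9))
  cfg <- train_config(hidden = 10, max_epochs = 150, seed = 6)
  sc <- self_consistency(d, cfg)
  cv <- cross_validate(d, k = 4, cfg)
  expect_gte(sc$metrics$Acc, cv$Ra)
})

test_that("jackknife is the mean of leave-one-out indicator outcomes", {
  d <- quick_dataset(6)                        # 12 windows
  jk <- jackknife(d, subsample_size = 12, quick_config())
  expect_length(jk$outcomes, 12L)
  expect_true(all(jk$outcomes %in% 0:1))
  expect_equal(jk$A_star, mean(jk$outcomes))
  expect_identical(jk$indices, 1:12)           # full LOO, no subsampling
  sub <- jackknife(d, subsample_size = 5, quick_config(), seed = 11)
  expect_length(sub$outcomes, 5L)
  expect_equal(sub$A_star, mean(sub$outcomes))
  expect_error(jackknife(d, 13, quick_config()), "larger")
})
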