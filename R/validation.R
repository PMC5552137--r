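#' Confusion matrix of a binary prediction
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels, same length.
#' @return List of class `nglyc_confusion` with integer counts `TP`,
#'   `FN`, `FP`, `TN`.
#' @export
confusion_matrix <- function(labels, predictions) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length")
  }
  stopifnot(all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  structure(list(
    TP = sum(labels == 1 & predictions == 1),
    FN = sum(labels == 1 & predictions == 0),
    FP = sum(labels == 0 & predictions == 1),
    TN = sum(labels == 0 & predictions == 0)),
    class = "nglyc_confusion")
}

#' @export
print.nglyc_confusion <- function(x, ...) {
  cat(sprintf("        predicted+  predicted-\nactual+ %10d  %10d\nactual- %10d  %10d\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(FP+TN)`,
#' `Acc = (TP+TN)/(TP+TN+FP+FN)` and
#' `MCC = (TN*TP - FN*FP) / sqrt((FP+TP)(FP+TN)(FN+TP)(FN+TN))`.
#' A metric whose denominator is zero is reported as `NA` and named in
#' the `undefined` field rather than silently zeroed.
#'
#' @param cm An `nglyc_confusion`, or a list/vector with elements
#'   `TP`, `FN`, `FP`, `TN`.
#' @return List with `Sn`, `Sp`, `Acc`, `MCC` and a character vector
#'   `undefined`.
#' @examples
#' classification_metrics(list(TP = 11461, FN = 12, FP = 0, TN = 11988))
#' @export
classification_metrics <- function(cm) {
  cm <- as.list(cm)
  tp <- as.numeric(cm$TP); fn <- as.numeric(cm$FN)
  fp <- as.numeric(cm$FP); tn <- as.numeric(cm$TN)
  undef <- character(0)
  sn <- if (tp + fn > 0) tp / (tp + fn) else {undef <- c(undef, "Sn"); NA_real_}
  sp <- if (fp + tn > 0) tn / (fp + tn) else {undef <- c(undef, "Sp"); NA_real_}
  tot <- tp + tn + fp + fn
  acc <- if (tot > 0) (tp + tn) / tot else {undef <- c(undef, "Acc"); NA_real_}
  den <- (fp + tp) * (fp + tn) * (fn + tp) * (fn + tn)
  mcc <- if (den > 0) (tn * tp - fn * fp) / sqrt(den) else {
    undef <- c(undef, "MCC"); NA_real_
  }
  list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc, undefined = undef)
}

#' Truncate (not round) to a fixed number of decimals
#'
#' Printed performance figures in the glycosylation-prediction
#' literature are typically truncated (0.99949 is reported as 0.9994);
#' this helper reproduces that convention.
#'
#' @param x Numeric vector.
#' @param digits Decimal places kept (default 4).
#' @return Truncated values.
#' @export
truncate_decimal <- function(x, digits = 4L) {
  trunc(x * 10^digits) / 10^digits
}

#' ROC curve by descending-threshold sweep, with trapezoidal AUC
#'
#' Sweeps the decision threshold across the unique scores from high to
#' low; each threshold contributes one (FPR, TPR) point.  The curve
#' starts at (0, 0) and ends at (1, 1) and is monotone in both
#' coordinates.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels True 0/1 labels.
#' @return List of class `nglyc_roc`: `points` (data frame with
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1), 0) / n_pos
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0), 0) / n_neg
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "nglyc_roc")
}

#' @export
print.nglyc_roc <- function(x, ...) {
  cat(sprintf("<nglyc_roc> %d points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Partition sample indices into k folds
#'
#' Folds are pairwise disjoint, cover `1..n`, and have sizes differing
#' by at most one.  With `strata` given, the partition is additionally
#' balanced within every stratum (indices are shuffled within class
#' and dealt round-robin in one continuous stream, so both the overall
#' and the per-class fold sizes differ by at most one).
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed RNG seed; the plan is reproducible from it.
#' @param strata Optional vector of length `n` (e.g. class labels).
#' @return List of class `nglyc_folds`: `k` integer index vectors.
#' @export
kfold_split <- function(n, k, seed = 1L, strata = NULL) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("cannot make ", k, " folds from ", n, " samples")
  order_idx <- with_seed(seed, {
    if (is.null(strata)) {
      sample.int(n)
    } else {
      stopifnot(length(strata) == n)
      unlist(lapply(split(seq_len(n), strata),
                    function(ix) ix[sample.int(length(ix))]),
             use.names = FALSE)
    }
  })
  fold_of <- rep_len(seq_len(k), n)
  folds <- split(order_idx, fold_of)
  names(folds) <- NULL
  structure(lapply(folds, sort), class = "nglyc_folds")
}

#' Self-consistency (resubstitution) test
#'
#' Trains on the full labelled dataset and evaluates on the same data
#' — the most optimistic protocol, reported alongside cross-validation.
#'
#' @param windows Labelled window table.
#' @param config An `nglyc_config`.
#' @return List with the fitted `model`, `confusion`, `metrics`,
#'   `roc` and the raw `scores`.
#' @export
self_consistency <- function(windows, config = train_config()) {
  model <- nglyc_fit(windows, config)
  scores <- predict(model, windows, type = "score")
  preds <- as.integer(scores >= config$threshold)
  cm <- confusion_matrix(windows$label, preds)
  list(model = model, confusion = cm,
       metrics = classification_metrics(cm),
       roc = roc_curve(scores, windows$label),
       scores = scores)
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into `k` label-stratified folds; each iteration
#' trains on the other `k - 1` folds (feature standardiser refitted
#' inside the training split — no test-fold leakage) and evaluates the
#' held-out fold.  Reports the per-fold accuracies, their mean `Ra`,
#' and per-class (positive-site / negative-site) accuracies per fold.
#'
#' @param windows Labelled window table.
#' @param k Number of folds (default 10).
#' @param config An `nglyc_config`.
#' @param seed Seed for the fold plan (default: `config$seed`).
#' @return List with `folds`, data frame `per_fold` (`accuracy`,
#'   `acc_pos`, `acc_neg`), `Ra` (mean fold accuracy), and
#'   `Ra_pos`/`Ra_neg` (mean per-class accuracies).
#' @export
cross_validate <- function(windows, k = 10L, config = train_config(),
                           seed = config$seed) {
  stopifnot(is.data.frame(windows), !anyNA(windows$label))
  n <- nrow(windows)
  folds <- kfold_split(n, k, seed = seed, strata = windows$label)
  per <- lapply(folds, function(test_idx) {
    train <- windows[-test_idx, , drop = FALSE]
    test <- windows[test_idx, , drop = FALSE]
    model <- nglyc_fit(train, config)
    pred <- predict(model, test, type = "class")
    ok <- pred == test$label
    c(accuracy = mean(ok),
      acc_pos = if (any(test$label == 1)) mean(ok[test$label == 1]) else NA,
      acc_neg = if (any(test$label == 0)) mean(ok[test$label == 0]) else NA)
  })
  per <- as.data.frame(do.call(rbind, per))
  per$fold <- seq_len(k)
  list(folds = folds,
       per_fold = per[, c("fold", "accuracy", "acc_pos", "acc_neg")],
       Ra = mean(per$accuracy),
       Ra_pos = mean(per$acc_pos, na.rm = TRUE),
       Ra_neg = mean(per$acc_neg, na.rm = TRUE))
}

#' Jackknife (leave-one-out) accuracy estimate
#'
#' For each selected sample, the model is trained on all remaining
#' samples and the left-out sample is predicted; the estimate `A*` is
#' the mean of the per-iteration 0/1 outcomes.  Full leave-one-out is
#' quadratic in training runs, so a random subsample (default 100, the
#' usual estimation size) can be evaluated instead; `subsample_size =
#' nrow(windows)` gives exact leave-one-out.
#'
#' @param windows Labelled window table.
#' @param subsample_size Number of left-out samples to evaluate.
#' @param config An `nglyc_config`.
#' @param seed Seed for the subsample draw.
#' @return List with `indices`, per-iteration 0/1 `outcomes`,
#'   `A_star`, and per-class means `A_pos`/`A_neg`.
#' @export
jackknife <- function(windows, subsample_size = 100L,
                      config = train_config(), seed = config$seed) {
  stopifnot(is.data.frame(windows), !anyNA(windows$label))
  n <- nrow(windows)
  subsample_size <- as.integer(subsample_size)
  if (subsample_size > n) {
    stop("subsample (", subsample_size, ") larger than dataset (", n, ")")
  }
  idx <- if (subsample_size == n) seq_len(n) else
    with_seed(seed, sort(sample.int(n, subsample_size)))
  outcomes <- vapply(idx, function(i) {
    model <- nglyc_fit(windows[-i, , drop = FALSE], config)
    as.integer(predict(model, windows[i, , drop = FALSE],
                       type = "class") == windows$label[i])
  }, integer(1))
  lab <- windows$label[idx]
  list(indices = idx, outcomes = outcomes, A_star = mean(outcomes),
       A_pos = if (any(lab == 1)) mean(outcomes[lab == 1]) else NA_real_,
       A_neg = if (any(lab == 0)) mean(outcomes[lab == 0]) else NA_real_)
}
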