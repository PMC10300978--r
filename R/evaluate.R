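#' Confusion counts
#' @param y_true,y_pred equal-length binary vectors.
#' @return a `confusion_counts` list: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (any(!y_true %in% c(0, 1)) || any(!y_pred %in% c(0, 1))) {
    stop("inputs must be binary")
  }
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0),
                 tn = sum(y_true == 0 & y_pred == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN);
#' F1 = 2 x precision x recall / (precision + recall);
#' accuracy = (TP+TN)/total. A zero denominator yields `NA` (undefined),
#' never 0, so stratified summaries are not biased by empty cells.
#'
#' @param c a `confusion_counts`, or a list/vector with tp, fp, fn, tn.
#' @param stratum optional stratum label carried into the report.
#' @param auc optional AUC to attach.
#' @return a `metrics_report` list: `precision`, `recall`, `f1`,
#'   `accuracy` (also `accuracy_pct`), `auc`, `counts`, `stratum`, `n`.
#' @export
metrics_from_counts <- function(c, stratum = "all", auc = NA_real_) {
  c <- as.list(c)
  tp <- c$tp; fp <- c$fp; fn <- c$fn; tn <- c$tn
  total <- tp + fp + fn + tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- safe_div(tp + tn, total)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, accuracy_pct = 100 * accuracy,
                 auc = auc,
                 counts = structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
                                    class = "confusion_counts"),
                 stratum = stratum, n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> [%s] n=%s acc=%.3f prec=%.3f rec=%.3f f1=%.3f auc=%s\n",
              x$stratum, format(x$n), x$accuracy, x$precision, x$recall, x$f1,
              if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' The curve sweeps every distinct score threshold; the AUC is the
#' trapezoidal integral, which equals the probability that a random
#' positive outscores a random negative (ties counted 1/2).
#'
#' @param y_true binary labels (both classes must be present).
#' @param scores classifier scores, higher = more positive.
#' @return list with `curve` (data.frame fpr/tpr/threshold) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE) # last point of each tie block
  tpr <- cumsum(y == 1)[keep] / n_pos
  fpr <- cumsum(y == 0)[keep] / n_neg
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, s[keep]))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Evaluate a classifier on a split defined by subject sets
#' @noRd
eval_split <- function(clf, set, train_subjects, test_subjects,
                       stratum = "fold", threshold = 0.5) {
  tr_idx <- which(set$subject %in% train_subjects)
  te_idx <- which(set$subject %in% test_subjects)
  if (length(intersect(tr_idx, te_idx)) > 0) stop("split is not disjoint")
  train_raw <- subset_set(set, tr_idx)
  test_raw <- subset_set(set, te_idx)
  np <- fit_normalization(train_raw)
  train <- apply_normalization(train_raw, np)
  test <- apply_normalization(test_raw, np)
  rm(train_raw, test_raw) # keep per-fold peak memory down
  fit <- train_classifier(clf, train)
  prob <- predict_proba(fit, test)
  pred <- as.integer(prob >= threshold)
  auc <- if (length(unique(test$label)) == 2) roc_auc(test$label, prob)$auc else NA_real_
  report <- metrics_from_counts(confusion(test$label, pred),
                                stratum = stratum, auc = auc)
  list(report = report,
       predictions = data.frame(index = te_idx, subject = test$subject,
                                day = if (is.null(test$day)) NA else test$day,
                                label = test$label, prob = prob, pred = pred,
                                stringsAsFactors = FALSE),
       norm = np, fit = fit)
}

#' Leave-one-category-out cross-validation
#'
#' Subjects are grouped into categories (in the study, impairment-level
#' bands of the Fugl-Meyer Upper Extremity score); each category is held
#' out in turn while the classifier trains on all other categories'
#' subjects, so no subject ever appears on both sides of a split.
#' Normalization is refitted on each training side.
#'
#' @param set a raw `spectrogram_set`.
#' @param grouping named character vector mapping subject -> category.
#' @param clf an unfitted `wf_classifier` template.
#' @param threshold decision threshold (default 0.5).
#' @return list of per-category results, each with `report` and
#'   `predictions`.
#' @export
loocv_by_category <- function(set, grouping, clf = build_cnn(),
                              threshold = 0.5) {
  subjects <- unique(set$subject)
  if (!all(subjects %in% names(grouping))) {
    stop("every subject needs a category in `grouping`")
  }
  cats <- unique(grouping[subjects])
  if (length(cats) < 2) stop("need at least 2 categories")
  out <- list()
  for (cat in cats) {
    test_sub <- subjects[grouping[subjects] == cat]
    train_sub <- setdiff(subjects, test_sub)
    if (length(train_sub) == 0) stop("one category holds all subjects")
    res <- eval_split(clf, set, train_sub, test_sub,
                      stratum = paste0("category:", cat), threshold = threshold)
    out[[cat]] <- res[c("report", "predictions")]
  }
  out
}

#' Random subject-grouped 5-fold cross-validation
#'
#' Each iteration draws a fresh random subject-level 80/20 split (one fold
#' of a grouped 5-fold): 80% of subjects train, 20% test, and a subject's
#' windows never straddle the split. Repeated `iterations` times with
#' fresh splits; returns one report per iteration plus their mean.
#'
#' @param set a raw `spectrogram_set`.
#' @param clf an unfitted `wf_classifier` template.
#' @param k number of folds defining the test fraction 1/k (default 5).
#' @param iterations number of repeated random splits (default 6).
#' @param seed RNG seed for the splits.
#' @param threshold decision threshold (default 0.5).
#' @return list with `reports` (per iteration), `mean` (named vector of
#'   mean accuracy/precision/recall/f1/auc), and `predictions` (row-bound
#'   held-out predictions with an `iteration` column).
#' @export
grouped_kfold <- function(set, clf = build_cnn(), k = 5L, iterations = 6L,
                          seed = 1L, threshold = 0.5) {
  subjects <- unique(set$subject)
  if (k > length(subjects)) stop("k exceeds the number of subjects")
  n_test <- max(1L, round(length(subjects) / k))
  reports <- list()
  preds <- list()
  for (it in seq_len(iterations)) {
    test_sub <- with_seed(seed + it,
                          sample(subjects, n_test))
    train_sub <- setdiff(subjects, test_sub)
    res <- eval_split(clf, set, train_sub, test_sub,
                      stratum = sprintf("iteration:%d", it),
                      threshold = threshold)
    reports[[it]] <- res$report
    p <- res$predictions
    p$iteration <- it
    preds[[it]] <- p
  }
  grab <- function(f) vapply(reports, `[[`, numeric(1), f)
  list(reports = reports,
       mean = c(accuracy = mean(grab("accuracy"), na.rm = TRUE),
                precision = mean(grab("precision"), na.rm = TRUE),
                recall = mean(grab("recall"), na.rm = TRUE),
                f1 = mean(grab("f1"), na.rm = TRUE),
                auc = mean(grab("auc"), na.rm = TRUE)),
       predictions = do.call(rbind, preds))
}

#' Aggregate positive decisions into daily movement counts
#'
#' One positive 50-sample decision slot counts as one movement.
#'
#' @param pred binary window predictions.
#' @param subject,day per-window subject and day identifiers.
#' @return data.frame with `subject`, `day`, `count`.
#' @export
daily_counts <- function(pred, subject, day) {
  if (length(pred) != length(subject) || length(pred) != length(day)) {
    stop("pred, subject, day must have equal length")
  }
  agg <- stats::aggregate(list(count = as.integer(pred)),
                          by = list(subject = subject, day = day), FUN = sum)
  agg[order(agg$subject, agg$day), , drop = FALSE]
}

#' Pearson correlation between two count vectors
#'
#' @param counts_a,counts_b paired per-subject-day counts.
#' @return list with `r`, `r_squared`, `p_value` (two-sided, t-transform
#'   with n-2 degrees of freedom), `n`.
#' @export
correlate_counts <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) stop("length mismatch")
  if (length(counts_a) < 3) stop("need at least 3 paired counts")
  ct <- stats::cor.test(counts_a, counts_b, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = length(counts_a))
}

#' Speed-stratified, class-balanced metrics
#'
#' Windows are binned by mean linear-acceleration amplitude (a movement
#' speed proxy). Within each bin the confusion matrix is class-balanced to
#' average out skewness: the positive-class row is scaled by 1/(actual
#' positives), the negative row by 1/(actual negatives), then the matrix
#' is renormalized to the bin size. With equally many positives and
#' negatives, the weighting is a no-op. Raw per-bin sample counts and
#' false-positive/false-negative rates are reported alongside.
#'
#' @param mean_acc per-window mean acceleration amplitude (G).
#' @param y_true,y_pred per-window labels and predictions.
#' @param bin_edges strictly increasing bin edges in G; default 10
#'   equal-width bins over the observed range.
#' @return list of per-bin entries: `report` (weighted), `n`, `n_pos`,
#'   `n_neg`, `fpr`, `fnr`, `lo`, `hi`; empty bins are reported as missing
#'   (`NULL` report).
#' @export
speed_stratified_metrics <- function(mean_acc, y_true, y_pred,
                                     bin_edges = NULL) {
  if (is.null(bin_edges)) {
    bin_edges <- seq(min(mean_acc), max(mean_acc), length.out = 11)
  }
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  bins <- cut(mean_acc, bin_edges, include.lowest = TRUE)
  out <- list()
  for (b in seq_along(levels(bins))) {
    sel <- which(as.integer(bins) == b)
    entry <- list(lo = bin_edges[b], hi = bin_edges[b + 1],
                  n = length(sel), n_pos = sum(y_true[sel] == 1),
                  n_neg = sum(y_true[sel] == 0))
    if (length(sel) == 0) {
      entry$report <- NULL
      entry$fpr <- NA_real_
      entry$fnr <- NA_real_
    } else {
      cc <- confusion(y_true[sel], y_pred[sel])
      entry$fpr <- if (entry$n_neg > 0) cc$fp / entry$n_neg else NA_real_
      entry$fnr <- if (entry$n_pos > 0) cc$fn / entry$n_pos else NA_real_
      P <- entry$n_pos; N <- entry$n_neg
      if (P > 0 && N > 0) {
        scale <- entry$n / 2
        w <- list(tp = cc$tp / P * scale, fn = cc$fn / P * scale,
                  fp = cc$fp / N * scale, tn = cc$tn / N * scale)
      } else {
        w <- cc # one-class bin: weighting undefined, keep raw counts
      }
      entry$report <- metrics_from_counts(w, stratum = sprintf("speed_bin:%d", b))
    }
    out[[b]] <- entry
  }
  out
}

#' Accuracy bounds under a noisy labeler (Bayes' theorem)
#'
#' When a classifier is scored against an imperfect reference labeler, the
#' observed agreement rate only brackets the true accuracy:
#' P(correct) = P(agree | labeler correct) P(labeler correct) +
#' q (1 - P(labeler correct)), with q = P(correct | labeler incorrect)
#' unknown in \[0, 1\]. The lower bound takes q = 0, the upper q = 1; the
#' band width is exactly 1 - P(labeler correct).
#'
#' @param p_match observed agreement rate with the labeler, in \[0, 1\].
#' @param p_hand accuracy of the labeler itself, in \[0, 1\].
#' @return a `bayes_bound` list: `p_match`, `p_hand`, `lower`, `upper`,
#'   and integer-percent forms `lower_pct`, `upper_pct`.
#' @export
bayes_accuracy_bounds <- function(p_match, p_hand) {
  if (!is.numeric(p_match) || p_match < 0 || p_match > 1 ||
      !is.numeric(p_hand) || p_hand < 0 || p_hand > 1) {
    stop("p_match and p_hand must be probabilities in [0, 1]")
  }
  lower <- min(1, max(0, p_match * p_hand))
  upper <- min(1, max(0, p_match * p_hand + (1 - p_hand)))
  structure(list(p_match = p_match, p_hand = p_hand,
                 lower = lower, upper = upper,
                 lower_pct = round(100 * lower), upper_pct = round(100 * upper)),
            class = "bayes_bound")
}

#' @export
print.bayes_bound <- function(x, ...) {
  cat(sprintf("<bayes_bound> true accuracy in [%.3f, %.3f] (%d-%d%%) given agreement %.2f with a labeler of accuracy %.2f\n",
              x$lower, x$upper, x$lower_pct, x$upper_pct, x$p_match, x$p_hand))
  invisible(x)
}
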