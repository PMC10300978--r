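test_that("confusion counts match brute-force pair enumeration", {
  y_true <- c(1, 1, 0, 0, 1, 0, 1, 0, 1, 0)
  y_pred <- c(1, 0, 0, 1, 1, 0, 0, 0, 1, 0)
  cc <- confusion(y_true, y_pred)
  expect_equal(unclass(cc), list(tp = 3, fp = 1, fn = 2, tn = 4))

  # perfect agreement and complement symmetry
  expect_equal(confusion(y_true, y_true)$fp + confusion(y_true, y_true)$fn, 0)
  cc2 <- confusion(y_true, 1 - y_pred)
  expect_equal(cc2$tp, cc$fn)
  expect_equal(cc2$tn, cc$fp)

  set.seed(1)
  for (i in 1:20) {
    yt <- rbinom(40, 1, 0.4); yp <- rbinom(40, 1, 0.5)
    cc <- confusion(yt, yp)
    expect_equal(cc$tp, sum(mapply(function(a, b) a == 1 && b == 1, yt, yp)))
    expect_equal(cc$tn, sum(mapply(function(a, b) a == 0 && b == 0, yt, yp)))
  }
  expect_error(confusion(integer(0), integer(0)), "empty")
})

test_that("metrics reproduce their defining formulas and handle undefined cells", {
  r <- metrics_from_counts(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f1, 2 / 3, tolerance = 1e-4)
  expect_equal(r$accuracy, 0.70)
  expect_equal(r$accuracy_pct, 70)

  perfect <- metrics_from_counts(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1, perfect$accuracy),
               rep(1, 4))

  # zero denominators propagate as missing, never as zero
  none_pred <- metrics_from_counts(list(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_true(is.na(none_pred$precision))
  expect_false(identical(none_pred$precision, 0))

  # F1 is the harmonic mean of precision and recall
  set.seed(2)
  for (i in 1:1000) {
    cc <- as.list(stats::setNames(rpois(4, 5) + c(1, 0, 0, 1),
                                  c("tp", "fp", "fn", "tn")))
    r <- metrics_from_counts(cc)
    if (!is.na(r$f1)) {
      expect_equal(r$f1, 2 / (1 / r$precision + 1 / r$recall), tolerance = 1e-12)
    }
  }
})

test_that("trapezoidal AUC equals the pairwise rank statistic", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(y, y)$auc, 1)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  rank_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(5)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # ties likely
    expect_equal(roc_auc(y, s)$auc, rank_auc(y, s), tolerance = 1e-10)
  }

  # scores independent of labels: chance-level AUC
  set.seed(6)
  y <- rbinom(5000, 1, 0.5)
  s <- runif(5000)
  expect_lt(abs(roc_auc(y, s)$auc - 0.5), 0.03)

  # independent library cross-check
  skip_if_not_installed("pROC")
  set.seed(7)
  y2 <- rbinom(300, 1, 0.4)
  s2 <- runif(300) + 0.3 * y2
  expect_equal(roc_auc(y2, s2)$auc,
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("grouped k-fold splits are seeded, disjoint, and conserving", {
  set <- tiny_benchmark()
  clf <- build_baseline("knn", list(k = 1))
  cv1 <- grouped_kfold(set, clf, k = 5, iterations = 3, seed = 42)
  cv2 <- grouped_kfold(set, clf, k = 5, iterations = 3, seed = 42)
  expect_equal(cv1$predictions$subject, cv2$predictions$subject)
  expect_equal(cv1$predictions$prob, cv2$predictions$prob)

  for (it in 1:3) {
    p <- cv1$predictions[cv1$predictions$iteration == it, ]
    test_sub <- unique(p$subject)
    # every window of a test subject is evaluated exactly once
    expect_equal(nrow(p), sum(set$subject %in% test_sub))
  }
  expect_error(grouped_kfold(set, clf, k = 10), "exceeds")
})

test_that("category LOOCV partitions subjects and conserves sample counts", {
  set <- tiny_benchmark()
  grouping <- stats::setNames(c("low", "low", "mid", "mid", "high"),
                              sprintf("T%02d", 1:5))
  res <- loocv_by_category(set, grouping, build_baseline("knn", list(k = 3)))
  expect_length(res, 3)
  total <- sum(vapply(res, function(x) nrow(x$predictions), integer(1)))
  expect_equal(total, length(set))
  for (cat in names(res)) {
    test_subjects <- unique(res[[cat]]$predictions$subject)
    expect_true(all(grouping[test_subjects] == cat))
  }
  expect_error(loocv_by_category(set, stats::setNames(rep("only", 5),
                                                      sprintf("T%02d", 1:5))),
               "2 categories")
})

test_that("daily counts aggregate decision slots and correlate exactly when equal", {
  pred <- c(1, 0, 1, 1, 0, 1)
  subj <- rep(c("A", "B"), each = 3)
  day <- rep("d1", 6)
  dc <- daily_counts(pred, subj, day)
  expect_equal(dc$count, c(2, 2))

  a <- c(10, 25, 40, 55)
  expect_equal(correlate_counts(a, a)$r, 1)
  lin <- correlate_counts(a, 2 * a + 7)
  expect_equal(lin$r, 1)
  expect_equal(lin$r_squared, 1)
  expect_error(correlate_counts(a[1:2], a[1:2]), "3")
})

test_that("speed-stratified weighting balances class skew", {
  # balanced bin: weighted metrics equal unweighted
  y <- rep(c(1, 0), each = 20)
  p <- c(rep(1, 15), rep(0, 5), rep(0, 16), rep(1, 4))
  acc <- rep(0.5, 40)
  strat <- speed_stratified_metrics(acc, y, p, bin_edges = c(0, 1))
  raw <- metrics_from_counts(confusion(y, p))
  expect_equal(strat[[1]]$report$accuracy, raw$accuracy, tolerance = 1e-12)

  # 90/10 imbalance, majority-class predictor: weighted accuracy 0.5
  y2 <- c(rep(0, 90), rep(1, 10))
  p2 <- rep(0, 100)
  strat2 <- speed_stratified_metrics(rep(0.1, 100), y2, p2, bin_edges = c(0, 1))
  expect_equal(strat2[[1]]$report$accuracy, 0.5)
  expect_equal(strat2[[1]]$fnr, 1)
  expect_equal(strat2[[1]]$fpr, 0)

  # per-bin counts sum to the total
  set.seed(3)
  acc3 <- runif(200, 0, 0.9)
  y3 <- rbinom(200, 1, 0.5)
  p3 <- rbinom(200, 1, 0.5)
  strat3 <- speed_stratified_metrics(acc3, y3, p3)
  expect_equal(sum(vapply(strat3, `[[`, integer(1), "n")), 200)
})

test_that("label-noise accuracy bounds obey Bayes' theorem", {
  b <- bayes_accuracy_bounds(0.77, 0.85)
  expect_equal(b$lower_pct, 65)
  expect_equal(b$upper_pct, 80)

  # perfect labeler: the bounds collapse
  b1 <- bayes_accuracy_bounds(0.9, 1)
  expect_equal(b1$lower, b1$upper)
  expect_equal(b1$lower, 0.9)

  # band width identity
  set.seed(8)
  for (i in 1:50) {
    pm <- runif(1); ph <- runif(1)
    bb <- bayes_accuracy_bounds(pm, ph)
    expect_equal(bb$upper - bb$lower, 1 - ph, tolerance = 1e-12)
  }
  expect_error(bayes_accuracy_bounds(1.2, 0.5), "probabilities")

  # Monte-Carlo evaluation of the total-probability identity at q = 0 and 1
  set.seed(9)
  n <- 1e6
  hand_ok <- runif(n) < 0.85
  agree <- runif(n) < 0.77
  correct_q0 <- hand_ok & agree
  correct_q1 <- (hand_ok & agree) | !hand_ok
  expect_equal(mean(correct_q0), b$lower, tolerance = 1e-3)
  expect_equal(mean(correct_q1), b$upper, tolerance = 1e-3)
})
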