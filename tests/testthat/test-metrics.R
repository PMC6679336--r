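test_that("confusion counts are one-vs-rest and conserve totals", {
  truth <- c("walking", "walking", "standing", "lying")
  pred <- c("walking", "lying", "standing", "lying")
  cm <- confusion(truth, pred)
  expect_equal(unname(rowSums(cm)), rep(4, 3))
  expect_equal(cm["walking", "FN"], 1)
  expect_equal(cm["lying", "FP"], 1)
  perfect <- confusion(truth, truth)
  expect_true(all(perfect[, c("FP", "FN")] == 0))
  expect_error(confusion(truth, pred[1:2]), "equal length")
})

test_that("per_class_metrics evaluates the epidemiological closed forms", {
  cm <- confusion(behaviour_labels(), behaviour_labels())
  expect_equal(unname(per_class_metrics(cm, "walking")), rep(100, 5))
  # TP=2 FP=1 TN=6 FN=1
  counts <- structure(rbind(walking = c(TP = 2, FP = 1, TN = 6, FN = 1),
                            standing = c(3, 0, 7, 0),
                            lying = c(3, 0, 7, 0)),
                      class = c("confusion_counts", "matrix", "array"))
  m <- per_class_metrics(counts, "walking")
  expect_equal(unname(m),
               c(80, 100 * 6 / 7, 100 * 2 / 3, 100 * 2 / 3, 100 * 2 / 3),
               tolerance = 1e-12)
  # zero denominators warn and report 0 instead of raising
  none <- structure(rbind(walking = c(TP = 0, FP = 0, TN = 9, FN = 1),
                          standing = c(0, 0, 10, 0),
                          lying = c(0, 0, 10, 0)),
                    class = c("confusion_counts", "matrix", "array"))
  warns <- capture_warnings(m0 <- per_class_metrics(none, "walking"))
  expect_match(warns, "precision", all = FALSE)
  expect_match(warns, "fscore", all = FALSE)
  expect_equal(m0[["precision"]], 0)
  expect_equal(m0[["fscore"]], 0)
})

test_that("random label vectors match an independent tallying oracle", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(20:500, 1)
    truth <- sample(behaviour_labels(), n, replace = TRUE)
    pred <- sample(behaviour_labels(), n, replace = TRUE)
    tab <- metrics_table(truth, pred)
    for (cls in behaviour_labels()) {
      tp <- sum(truth == cls & pred == cls)
      fp <- sum(truth != cls & pred == cls)
      fn <- sum(truth == cls & pred != cls)
      tn <- n - tp - fp - fn
      expect_equal(tab[cls, "accuracy"], 100 * (tp + tn) / n)
      expect_equal(tab[cls, "recall"], 100 * tp / (tp + fn))
      expect_equal(tab[cls, "specificity"], 100 * tn / (tn + fp))
      expect_equal(tab[cls, "precision"], 100 * tp / (tp + fp))
      p <- tp / (tp + fp)
      r <- tp / (tp + fn)
      expect_equal(tab[cls, "fscore"], 100 * 2 * p * r / (p + r))
    }
  }
})

test_that("macro averaging reproduces published Overall rows", {
  combined <- reference_metrics("combined")
  expect_equal(round(flockdrift:::round_half_up(macro_average(combined) * 100) / 100, 2),
               c(accuracy = 85.18, specificity = 82.84, recall = 57.82,
                 precision = 69.90, fscore = 60.40))
  online <- reference_metrics("online")
  expect_equal(unname(round(macro_average(online)[["accuracy"]], 2)), 69.49)
  # identical class values pass through unchanged
  same <- structure(data.frame(accuracy = rep(81.5, 3),
                               specificity = rep(70, 3),
                               recall = rep(60, 3), precision = rep(50, 3),
                               fscore = rep(54.5, 3),
                               row.names = behaviour_labels()),
                    class = c("metrics_table", "data.frame"))
  expect_equal(unname(macro_average(same)),
               c(81.5, 70, 60, 50, 54.5))
})

test_that("compare_methods returns signed deltas and their grand mean", {
  a <- reference_metrics("combined")
  b <- reference_metrics("online")
  cmp <- compare_methods(a, b)
  expect_equal(round(cmp$grand_mean, 2), 10.88)
  expect_equal(compare_methods(a, a)$deltas,
               c(accuracy = 0, specificity = 0, recall = 0, precision = 0,
                 fscore = 0))
  expect_equal(compare_methods(b, a)$deltas, -cmp$deltas)
})

test_that("the metrics report mirrors the published table layout", {
  set.seed(15)
  truth <- sample(behaviour_labels(), 60, replace = TRUE)
  pred <- sample(behaviour_labels(), 60, replace = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(metrics_table(truth, pred), path)
  rep_csv <- utils::read.csv(path)
  expect_equal(rep_csv$performance,
               c("walking", "standing", "lying", "Overall"))
  expect_equal(names(rep_csv)[-1],
               c("accuracy", "specificity", "recall", "precision", "fscore"))
  expect_equal(rep_csv$accuracy[4],
               round(flockdrift:::round_half_up(
                 mean(metrics_table(truth, pred)$accuracy) * 100) / 100, 2))
})
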