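make_labels <- function(counts) {
  # counts = c(TP, FN, FP, TN) with barnyard grass positive
  lv <- spectra_classes()
  y_true <- c(rep(lv[1], counts[1] + counts[2]), rep(lv[2], counts[3] + counts[4]))
  y_pred <- c(rep(lv[1], counts[1]), rep(lv[2], counts[2]),
              rep(lv[1], counts[3]), rep(lv[2], counts[4]))
  list(truth = y_true, pred = y_pred)
}

test_that("confusion matrix uses barnyard grass as the positive class", {
  v <- make_labels(c(95, 0, 3, 67))
  cm <- confusion_matrix(v$truth, v$pred)
  expect_equal(unname(cm), rbind(c(95L, 0L), c(3L, 67L)))
  expect_equal(sum(cm), 165)
  ident <- confusion_matrix(v$truth, v$truth)
  expect_equal(unname(ident[1, 2] + ident[2, 1]), 0L)
  expect_error(confusion_matrix(v$truth, v$pred[-1]), "length")
  set.seed(1)
  a <- sample(spectra_classes(), 40, replace = TRUE)
  b <- sample(spectra_classes(), 40, replace = TRUE)
  expect_equal(sum(confusion_matrix(a, b)), 40)
})

test_that("accuracy and MCC match their closed forms", {
  cm <- rbind(c(95, 0), c(3, 67))
  expect_equal(accuracy(cm), 162 / 165)
  expect_equal(mcc(cm), 6365 / sqrt(95 * 98 * 70 * 67))
  expect_equal(accuracy(rbind(c(10, 0), c(0, 5))), 1)
  expect_equal(accuracy(rbind(c(0, 10), c(5, 0))), 0)
  expect_equal(mcc(rbind(c(10, 0), c(0, 5))), 1)
  # single predicted class: degenerate denominator convention
  expect_equal(mcc(rbind(c(10, 0), c(5, 0))), 0)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("MCC is symmetric under simultaneous class swap", {
  cm <- rbind(c(40, 7), c(12, 30))
  swapped <- cm[2:1, 2:1]
  expect_equal(mcc(cm), mcc(swapped))
})

test_that("metrics from a matrix equal metrics from label vectors", {
  set.seed(7)
  truth <- sample(spectra_classes(), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.8, truth, sample(spectra_classes(), 60, TRUE))
  cm <- confusion_matrix(truth, pred)
  expect_equal(accuracy(cm), mean(truth == pred))
})

test_that("AUC equals exhaustive pair counting for small n", {
  brute_auc <- function(y, s) {
    pos <- which(y == spectra_classes()[1])
    neg <- which(y == spectra_classes()[2])
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    y <- c(spectra_classes(), sample(spectra_classes(), n - 2, replace = TRUE))
    s <- round(runif(n), 1)      # coarse grid induces ties
    expect_equal(roc_auc(y, s)$auc, brute_auc(y, s))
  }
})

test_that("AUC behaves as a ranking statistic", {
  y <- rep(spectra_classes(), each = 10)
  s <- c(runif(10, 0.6, 1), runif(10, 0, 0.4))
  ra <- roc_auc(y, s)
  expect_equal(ra$auc, 1)
  expect_true(all(diff(ra$roc_points$fpr) >= 0))
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(y, exp(3 * s))$auc, ra$auc)
  set.seed(13)
  y2 <- sample(spectra_classes(), 4000, replace = TRUE)
  expect_lt(abs(roc_auc(y2, runif(4000))$auc - 0.5), 0.05)
  expect_error(roc_auc(rep("rice", 5), runif(5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  y <- sample(spectra_classes(), 80, replace = TRUE)
  s <- runif(80) + 0.4 * (y == spectra_classes()[1])
  ref <- pROC::roc(response = y, predictor = s,
                   levels = rev(spectra_classes()), direction = "<",
                   quiet = TRUE)
  expect_equal(roc_auc(y, s)$auc, as.numeric(ref$auc))
})

test_that("eval_report bundles the metrics", {
  v <- make_labels(c(8, 2, 1, 9))
  s <- seq(1, 0, length.out = 20)
  rep <- eval_report(v$truth, v$pred, s)
  expect_equal(rep$acc, accuracy(rep$confusion))
  expect_equal(rep$mcc, mcc(rep$confusion))
  expect_equal(rep$auc, roc_auc(v$truth, s)$auc)
  expect_output(print(rep), "ACC")
})
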