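separable_xy <- function(n = 40, seed = 1) {
  set.seed(seed)
  cls <- rep(spectra_classes(), each = n / 2)
  X <- matrix(rnorm(n * 2), n, 2)
  X[cls == "barnyard_grass", 1] <- X[cls == "barnyard_grass", 1] + 6
  colnames(X) <- c("f1", "f2")
  list(X = X, y = cls)
}

test_that("the SVM search grid spans the documented exponent ranges", {
  spec <- baseline_spec("svm")
  expect_equal(length(spec$svm_log2C) * length(spec$svm_log2g), 399L)
  expect_equal(range(spec$svm_log2C), c(-5, 15))
  expect_equal(range(spec$svm_log2g), c(-15, 3))
})

test_that("random forest uses 500 trees and the square-root mtry rule", {
  set.seed(2)
  X <- matrix(rnorm(20 * 2151), 20, 2151)
  y <- rep(spectra_classes(), each = 10)
  fit <- train_baseline(baseline_spec("rf", seed = 1), X, y)
  expect_equal(fit$chosen$mtry, 46)
  expect_equal(fit$chosen$ntree, 500L)
})

test_that("every baseline separates a linearly separable toy set", {
  d <- separable_xy()
  for (m in c("dt", "rf", "svm", "xgb", "mlp")) {
    spec <- baseline_spec(m, cv_folds = 5, seed = 1,
                          svm_log2C = 0:3, svm_log2g = -3:0,
                          mlp_epochs = 80L, mlp_lr = 1e-3,
                          mlp_hidden = c(16L, 16L))
    fit <- train_baseline(spec, d$X, d$y)
    p <- predict(fit, d$X)
    expect_true(all(p >= 0 & p <= 1))
    pred <- ifelse(p >= 0.5, spectra_classes()[1], spectra_classes()[2])
    expect_equal(mean(pred == d$y), 1, info = m)
  }
  expect_error(train_baseline(baseline_spec("rf"), d$X,
                              rep("rice", nrow(d$X))), "single class")
})

test_that("baseline training is reproducible under a fixed seed", {
  d <- separable_xy(seed = 5)
  f1 <- train_baseline(baseline_spec("xgb", seed = 9), d$X, d$y)
  f2 <- train_baseline(baseline_spec("xgb", seed = 9), d$X, d$y)
  expect_equal(predict(f1, d$X), predict(f2, d$X))
})

test_that("the comparison table has model rows plus per-variant averages", {
  layout <- small_layout(seed = 7, per_class = 15, red_edge_shift = 6,
                         pigment_delta = 0.02)
  thin <- list(train = thin_bands(layout$train, 40),
               test = thin_bands(layout$test, 40))
  variants <- list(
    none = thin,
    snv = preprocess_spectra(thin$train, thin$test, method = "snv"))
  tab <- compare_models(c("dt", "xgb"), variants, seed = 1)
  expect_equal(nrow(tab), 6L)
  expect_equal(sum(tab$model == "average"), 2L)
  for (v in names(variants)) {
    rows <- tab[tab$preprocess == v & tab$model != "average", ]
    avg <- tab[tab$preprocess == v & tab$model == "average", ]
    expect_equal(avg$acc, mean(rows$acc))
    expect_equal(avg$mcc, mean(rows$mcc))
  }
  # all models beat the majority class on clearly separated data
  maj <- max(table(layout$test$labels)) / n_spectra(layout$test)
  expect_true(all(tab$acc[tab$model != "average"] > maj))
})

test_that("the MLP learns with its dedicated optimizer", {
  d <- separable_xy(n = 60, seed = 11)
  fit <- mlp_train(d$X, d$y, hidden = c(32L, 32L), epochs = 60,
                   batch_size = 11, lr = 1e-3, seed = 2)
  expect_length(fit$history, 60L)
  expect_lt(tail(fit$history, 1), fit$history[1])
  p <- predict(fit, d$X)
  pred <- ifelse(p >= 0.5, spectra_classes()[1], spectra_classes()[2])
  expect_gt(mean(pred == d$y), 0.95)
})
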