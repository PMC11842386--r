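#' Specification of a baseline classifier
#'
#' @param model One of `"dt"`, `"rf"`, `"svm"`, `"xgb"`, `"mlp"`.
#' @param cv_folds CV folds for hyperparameter search (default 10).
#' @param seed Integer seed.
#' @param svm_log2C Candidate `log2(C)` exponents for the RBF-SVM search
#'   (default `-5:15`).
#' @param svm_log2g Candidate `log2(gamma)` exponents (default `-15:3`).
#' @param mlp_epochs,mlp_lr,mlp_hidden Training settings for the MLP
#'   baseline (default: two 1024-unit hidden layers).
#' @return A `BaselineSpec` list.
#' @export
baseline_spec <- function(model = c("dt", "rf", "svm", "xgb", "mlp"),
                          cv_folds = 10L, seed = 1L,
                          svm_log2C = -5:15, svm_log2g = -15:3,
                          mlp_epochs = 150L, mlp_lr = 5e-6,
                          mlp_hidden = c(1024L, 1024L)) {
  model <- match.arg(model)
  structure(list(model = model, cv_folds = cv_folds, seed = seed,
                 svm_log2C = svm_log2C, svm_log2g = svm_log2g,
                 mlp_epochs = mlp_epochs, mlp_lr = mlp_lr,
                 mlp_hidden = as.integer(mlp_hidden)),
            class = "BaselineSpec")
}

#' Train a baseline classifier
#'
#' Reference models with their conventional hyperparameter treatments:
#' * `dt` - CART decision tree pruned at the complexity parameter with the
#'   least cross-validated error;
#' * `rf` - random forest with 500 trees and `mtry = round(sqrt(p))`;
#' * `svm` - RBF-kernel SVM; `C` and `gamma` searched over powers of two
#'   (`2^-5..2^15` and `2^-15..2^3`) by k-fold CV accuracy;
#' * `xgb` - gradient boosting at library defaults (100 rounds);
#' * `mlp` - the three-layer perceptron of [mlp_train()].
#'
#' @param spec A `BaselineSpec`.
#' @param X Numeric feature matrix.
#' @param y Class labels (both classes must be present).
#' @return A `baseline_model` list with the fitted classifier and the chosen
#'   hyperparameters.
#' @export
train_baseline <- function(spec, X, y) {
  stopifnot(inherits(spec, "BaselineSpec"))
  X <- as.matrix(X)
  yf <- factor(as.character(y), levels = spectra_classes())
  if (length(unique(yf)) < 2L) stop("training labels contain a single class")
  y01 <- label_to_numeric(yf)
  set.seed(spec$seed)
  chosen <- list()
  fit <- switch(spec$model,
    dt = {
      df <- data.frame(y = yf, X)
      tree <- rpart::rpart(y ~ ., data = df, method = "class",
                           control = rpart::rpart.control(xval = spec$cv_folds,
                                                          cp = 0))
      cp_best <- tree$cptable[which.min(tree$cptable[, "xerror"]), "CP"]
      chosen$cp <- cp_best
      rpart::prune(tree, cp = cp_best)
    },
    rf = {
      chosen$mtry <- round(sqrt(ncol(X)))
      chosen$ntree <- 500L
      randomForest::randomForest(X, yf, ntree = 500L, mtry = chosen$mtry)
    },
    svm = {
      folds <- stratified_folds(yf, spec$cv_folds, spec$seed)
      grid <- expand.grid(log2C = spec$svm_log2C, log2g = spec$svm_log2g)
      acc <- vapply(seq_len(nrow(grid)), function(i) {
        ok <- 0L
        for (f in unique(folds)) {
          tr <- folds != f
          m <- e1071::svm(X[tr, , drop = FALSE], yf[tr],
                          kernel = "radial", cost = 2^grid$log2C[i],
                          gamma = 2^grid$log2g[i], scale = FALSE)
          ok <- ok + sum(predict(m, X[!tr, , drop = FALSE]) == yf[!tr])
        }
        ok / length(yf)
      }, numeric(1))
      i_best <- which.max(acc)
      chosen$cost <- 2^grid$log2C[i_best]
      chosen$gamma <- 2^grid$log2g[i_best]
      e1071::svm(X, yf, kernel = "radial", cost = chosen$cost,
                 gamma = chosen$gamma, scale = FALSE, probability = TRUE)
    },
    xgb = {
      chosen$nrounds <- 100L
      fit_xgb(X, y01, nrounds = 100L)
    },
    mlp = mlp_train(X, yf, hidden = spec$mlp_hidden,
                    epochs = spec$mlp_epochs, lr = spec$mlp_lr,
                    seed = spec$seed)
  )
  structure(list(model = spec$model, fit = fit, chosen = chosen,
                 spec = spec),
            class = "baseline_model")
}

#' Predict barnyard-grass probability from a baseline model
#' @param object A `baseline_model`.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  pos <- spectra_classes()[1]
  switch(object$model,
    dt = {
      p <- predict(object$fit, data.frame(newdata), type = "prob")
      as.numeric(p[, pos])
    },
    rf = as.numeric(predict(object$fit, newdata, type = "prob")[, pos]),
    svm = {
      pr <- attr(predict(object$fit, newdata, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, pos])
    },
    xgb = predict_xgb(object$fit, newdata),
    mlp = predict(object$fit, newdata)
  )
}

#' Compare baseline models across preprocessing variants
#'
#' Trains every requested model on every named preprocessed variant of the
#' training set and evaluates on the matching test variant, producing the
#' model-by-preprocessing comparison table with per-preprocessing averages.
#'
#' @param models Character vector of baseline model names.
#' @param variants Named list; each element is a list with `train` and
#'   `test` `SpectraSet`s (as returned by [preprocess_spectra()]).
#' @param seed Integer seed shared across cells.
#' @param ... Passed to [baseline_spec()].
#' @return A data.frame with columns `model`, `preprocess`, `acc`, `mcc`,
#'   `auc`; rows with `model == "average"` hold per-preprocessing means.
#' @export
compare_models <- function(models, variants, seed = 1L, ...) {
  rows <- list()
  for (v in names(variants)) {
    tr <- variants[[v]]$train; te <- variants[[v]]$test
    for (m in models) {
      spec <- baseline_spec(model = m, seed = seed, ...)
      fit <- train_baseline(spec, tr$reflectance, tr$labels)
      p <- predict(fit, te$reflectance)
      pred <- ifelse(p >= 0.5, spectra_classes()[1], spectra_classes()[2])
      rep <- eval_report(te$labels, pred, p)
      rows[[length(rows) + 1L]] <-
        data.frame(model = m, preprocess = v, acc = rep$acc, mcc = rep$mcc,
                   auc = rep$auc)
    }
    block <- do.call(rbind, rows[seq(length(rows) - length(models) + 1L,
                                     length(rows))])
    rows[[length(rows) + 1L]] <-
      data.frame(model = "average", preprocess = v, acc = mean(block$acc),
                 mcc = mean(block$mcc), auc = mean(block$auc))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
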