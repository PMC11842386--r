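# 10-fold CV accuracy of a gradient-boosting classifier, used to pick the
# retained dimensionality in reduce_pca().
xgb_cv_acc <- function(X, y01, fold_id, nrounds = 50L) {
  correct <- 0L
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    fit <- fit_xgb(X[tr, , drop = FALSE], y01[tr], nrounds)
    pred <- predict_xgb(fit, X[!tr, , drop = FALSE]) > 0.5
    correct <- correct + sum(pred == (y01[!tr] == 1))
  }
  correct / length(y01)
}

# thin wrappers over the booster interface (stable across xgboost versions)
fit_xgb <- function(X, y01, nrounds = 100L) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y01)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   nthread = 1L),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

predict_xgb <- function(fit, X) {
  as.numeric(predict(fit, xgboost::xgb.DMatrix(as.matrix(X))))
}

#' PCA reduction with CV-selected dimensionality
#'
#' Fits principal components on the training matrix only and projects both
#' partitions. The number of retained components is the one maximizing the
#' k-fold cross-validated accuracy of a gradient-boosting classifier on the
#' training scores.
#'
#' @param X_train Training feature matrix.
#' @param X_test Test feature matrix (optional).
#' @param y_train Training class labels (needed to score component counts).
#' @param max_components Largest count to consider (default 30).
#' @param folds CV folds (default 10).
#' @param seed Seed for fold assignment.
#' @return List with `train`, `test` (score matrices), `n_components`,
#'   `trace` (CV accuracy per candidate count), and the fitted `prcomp`
#'   object `pca`.
#' @export
reduce_pca <- function(X_train, X_test = NULL, y_train, max_components = 30L,
                       folds = 10L, seed = 1L) {
  X_train <- as.matrix(X_train)
  max_components <- min(max_components, ncol(X_train), nrow(X_train) - 1L)
  if (max_components < 1L) stop("degenerate input: no components available")
  pca <- stats::prcomp(X_train, center = TRUE, scale. = FALSE)
  if (pca$sdev[1] < 1e-12) stop("degenerate covariance: no variance in X_train")
  scores <- pca$x
  y01 <- label_to_numeric(y_train)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(X_train)))
  acc <- vapply(seq_len(max_components), function(k) {
    xgb_cv_acc(scores[, seq_len(k), drop = FALSE], y01, fold_id)
  }, numeric(1))
  k_best <- which.max(acc)
  out <- list(train = scores[, seq_len(k_best), drop = FALSE],
              n_components = k_best,
              trace = data.frame(n_components = seq_len(max_components),
                                 cv_acc = acc),
              pca = pca)
  if (!is.null(X_test)) {
    out$test <- predict(pca, as.matrix(X_test))[, seq_len(k_best),
                                                drop = FALSE]
  }
  out
}

#' t-SNE embedding hook
#'
#' Wraps a standard t-distributed stochastic neighbor embedding, seeded for
#' reproducibility. For 1-3 output dimensions the Barnes-Hut implementation
#' of \pkg{Rtsne} is used; higher dimensionalities fall back to an exact
#' perplexity-calibrated gradient descent on the same objective. Note that
#' t-SNE has no out-of-sample transform: a classifier trained on embedded
#' coordinates cannot be applied to unseen spectra without re-embedding, so
#' this hook is primarily for visualization and training-set exploration.
#'
#' @param X Numeric feature matrix.
#' @param dims Output dimensionality (`1 <= dims < n_samples`).
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   when the sample count is small).
#' @param max_iter Gradient-descent iterations (default 500).
#' @return Numeric embedding matrix `[n x dims]`.
#' @export
reduce_tsne <- function(X, dims = 2L, seed = 1L, perplexity = 30,
                        max_iter = 500L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (dims < 1L) stop("dims must be >= 1")
  if (dims >= n) stop("dims must be smaller than the sample count")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  set.seed(seed)
  if (dims <= 3L) {
    fit <- Rtsne::Rtsne(X, dims = dims, perplexity = perplexity,
                        max_iter = max_iter, check_duplicates = FALSE,
                        pca = TRUE, verbose = FALSE)
    return(fit$Y)
  }
  tsne_exact(X, dims, perplexity, max_iter)
}

# Exact t-SNE for output dimensionalities beyond the Barnes-Hut limit.
tsne_exact <- function(X, dims, perplexity, max_iter) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  # binary-search per-point bandwidths to the target perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1e-12, length(di)) else p <- p / sp
      H <- -sum(p * log(pmax(p, 1e-12)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  gain <- matrix(1, n, dims); inc <- matrix(0, n, dims)
  eta <- 200; momentum <- 0.5
  Pex <- P * 4                          # early exaggeration
  for (it in seq_len(max_iter)) {
    if (it == 101) Pex <- P
    if (it == 21) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pex - Q) * num
    G <- 4 * (diag(rowSums(L)) - L) %*% Y
    gain <- ifelse(sign(G) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - eta * gain * G
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y), "-")
  }
  Y
}
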