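#' Multi-layer perceptron baseline
#'
#' Three fully connected layers: two ReLU hidden layers of `hidden` units
#' each and a 2-unit softmax output, trained with Adam on cross-entropy.
#' Used as the fully-connected reference model; by default it shares the
#' optimizer settings of the convolutional network.
#'
#' @param X Numeric feature matrix `[n x p]`.
#' @param y Class labels.
#' @param hidden Hidden-layer widths (default `c(1024, 1024)`).
#' @param epochs Training epochs (default 150).
#' @param batch_size Minibatch size (default 11).
#' @param lr Adam learning rate (default 5e-6).
#' @param weight_decay L2 penalty coupled into the gradient (default 1e-4).
#' @param seed Integer seed for init and shuffling.
#' @return An `mlp_model` list with weight matrices and training history.
#' @export
mlp_train <- function(X, y, hidden = c(1024L, 1024L), epochs = 150L,
                      batch_size = 11L, lr = 5e-6, weight_decay = 1e-4,
                      seed = 1L) {
  X <- as.matrix(X)
  y01 <- label_to_numeric(y)
  if (length(unique(y01)) < 2L) stop("training labels contain a single class")
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  sizes <- c(p, hidden, 2L)
  W <- lapply(seq_len(length(sizes) - 1L), function(i) {
    matrix(stats::rnorm(sizes[i + 1] * sizes[i], 0,
                        sqrt(2 / sizes[i])), sizes[i + 1], sizes[i])
  })
  b <- lapply(seq_len(length(sizes) - 1L), function(i) numeric(sizes[i + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
  L <- length(W)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      A <- t(X[idx, , drop = FALSE])          # p x B
      acts <- list(A)
      for (l in seq_len(L)) {
        Z <- W[[l]] %*% acts[[l]] + b[[l]]
        acts[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
      }
      Z <- acts[[L + 1]]
      Z <- sweep(Z, 2L, apply(Z, 2L, max), "-")
      Pm <- sweep(exp(Z), 2L, colSums(exp(Z)), "/")
      tgt <- rbind(y01[idx], 1 - y01[idx])    # row 1 = positive class
      ep_loss <- ep_loss - sum(log(pmax(Pm[cbind(2 - y01[idx],
                                                 seq_along(idx))], 1e-12)))
      dZ <- (Pm - tgt) / length(idx)
      t_step <- t_step + 1
      for (l in rev(seq_len(L))) {
        gW <- dZ %*% t(acts[[l]]) + weight_decay * W[[l]]
        gb <- rowSums(dZ)
        if (l > 1L) dZ <- (t(W[[l]]) %*% dZ) * (acts[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^t_step; cor2 <- 1 - beta2^t_step
        W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
      }
    }
    history[ep] <- ep_loss / n
  }
  structure(list(W = W, b = b, history = history), class = "mlp_model")
}

#' Predict barnyard-grass probability from an MLP
#' @param object An `mlp_model`.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  A <- t(as.matrix(newdata))
  L <- length(object$W)
  for (l in seq_len(L)) {
    Z <- object$W[[l]] %*% A + object$b[[l]]
    A <- if (l < L) pmax(Z, 0) else Z
  }
  Z <- sweep(A, 2L, apply(A, 2L, max), "-")
  P <- sweep(exp(Z), 2L, colSums(exp(Z)), "/")
  as.numeric(P[1, ])
}
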