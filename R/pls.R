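#' Partial least squares regression (SIMPLS)
#'
#' Univariate-response SIMPLS used as the calibration model inside CARS.
#' Components are extracted from the cross-covariance between the centered
#' predictors and response; extraction stops early if a component's score
#' norm collapses (rank deficiency).
#'
#' @param X Numeric predictor matrix `[n x p]`.
#' @param y Numeric response vector of length `n`.
#' @param ncomp Number of latent components.
#' @return A `pls_model` list with regression coefficients `coef` (length
#'   `p`), `intercept`, and the number of components actually used.
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  if (ncomp < 1L) stop("need at least one PLS component")
  mx <- colMeans(X); my <- mean(y)
  X0 <- sweep(X, 2L, mx, "-")
  y0 <- y - my

  S <- crossprod(X0, y0)                # p x 1 cross-covariance
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t <- X0 %*% r
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt < 1e-12) break
    t <- t / nt; r <- r / nt
    pl <- crossprod(X0, t)              # loading
    Q[a] <- sum(y0 * t)
    v <- pl
    if (a > 1L) {
      Va <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pl)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)      # deflate cross-covariance
    R[, a] <- r; V[, a] <- v
    used <- a
  }
  if (used == 0L) stop("PLS failed: degenerate predictors")
  coef <- R[, seq_len(used), drop = FALSE] %*% Q[seq_len(used)]
  structure(list(coef = as.numeric(coef),
                 intercept = my - sum(mx * coef),
                 ncomp = used),
            class = "pls_model")
}

#' Predict from a SIMPLS model
#' @param object A `pls_model`.
#' @param newdata Numeric matrix with the same columns as the training `X`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$coef + object$intercept)
}

# k-fold RMSE of a PLS calibration on (X, y)
pls_rmsecv <- function(X, y, ncomp, fold_id) {
  sq <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], ncomp)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    sq <- sq + sum((y[!tr] - pred)^2)
  }
  sqrt(sq / length(y))
}
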