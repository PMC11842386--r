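# Labels -> numeric 0/1 calibration target (positive class barnyard_grass = 1)
label_to_numeric <- function(y) {
  if (is.numeric(y)) return(as.numeric(y))
  yf <- factor(as.character(y), levels = spectra_classes())
  if (anyNA(yf)) stop("labels outside the two classes")
  as.numeric(yf == spectra_classes()[1])
}

# k-fold RMSE of an ordinary least-squares calibration on (X, y).
# Rank-deficient fits fall back to minimum-norm coefficients (NA -> 0).
lm_rmsecv <- function(X, y, fold_id) {
  sq <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    A <- cbind(1, X[tr, , drop = FALSE])
    cf <- qr.coef(qr(A), y[tr])
    cf[is.na(cf)] <- 0
    pred <- cbind(1, X[!tr, , drop = FALSE]) %*% cf
    sq <- sq + sum((y[!tr] - pred)^2)
  }
  sqrt(sq / length(y))
}

#' Successive projections algorithm for band selection
#'
#' Forward selection that minimizes collinearity: starting from a candidate
#' band, the next band is always the one with the largest norm after
#' orthogonal projection onto the complement of the span of the bands
#' already selected. Every chain prefix (sizes `1..max_bands`, every
#' candidate start) is scored by the k-fold cross-validated RMSE of an
#' ordinary linear calibration against the 0/1 class label, and the
#' prefix with the smallest RMSE wins.
#'
#' @param X Numeric band matrix `[n x p]`; column names (wavelengths in nm)
#'   are carried into the result when present.
#' @param y Class labels (coded 1 for barnyard grass) or a numeric response.
#' @param max_bands Largest subset size to consider.
#' @param folds Number of CV folds (default 10).
#' @param starts Candidate starting columns (default: all columns).
#' @param seed Seed for the fold assignment.
#' @return A `BandSelection` list: `selected` (column indices),
#'   `selected_wavelengths`, `method = "SPA"`, `criterion_trace` (RMSE per
#'   subset size for the winning start), and `chosen_step`.
#' @export
spa_select <- function(X, y, max_bands, folds = 10L, starts = NULL,
                       seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (max_bands < 1L || max_bands > p) stop("need 1 <= max_bands <= ncol(X)")
  yn <- label_to_numeric(y)
  if (folds > nrow(X)) stop("more folds than samples")
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(X)))
  if (is.null(starts)) starts <- seq_len(p)

  # chain of successive projections from one start column
  chain_from <- function(j0) {
    Xp <- X                      # working copy, progressively projected
    sel <- integer(0)
    j <- j0
    for (step in seq_len(max_bands)) {
      sel <- c(sel, j)
      s <- Xp[, j]
      ns2 <- sum(s^2)
      if (ns2 < 1e-12) break     # rank collapsed
      # project all columns onto the orthogonal complement of s
      Xp <- Xp - s %*% (crossprod(s, Xp) / ns2)
      norms <- colSums(Xp^2)
      norms[sel] <- -Inf
      if (length(sel) == max_bands || max(norms) < 1e-12) break
      j <- which.max(norms)
    }
    sel
  }

  best <- list(rmse = Inf)
  for (j0 in starts) {
    sel <- chain_from(j0)
    rmse_k <- vapply(seq_along(sel), function(k) {
      lm_rmsecv(X[, sel[seq_len(k)], drop = FALSE], yn, fold_id)
    }, numeric(1))
    k_best <- which.min(rmse_k)
    if (rmse_k[k_best] < best$rmse) {
      best <- list(rmse = rmse_k[k_best], start = j0, chain = sel,
                   k = k_best, trace = rmse_k)
    }
  }
  sel <- best$chain[seq_len(best$k)]
  wl <- if (!is.null(colnames(X))) {
    suppressWarnings(as.numeric(colnames(X)[sel]))
  } else sel
  structure(list(selected = sel,
                 selected_wavelengths = wl,
                 method = "SPA",
                 criterion_trace = data.frame(size = seq_along(best$trace),
                                              rmsecv = best$trace),
                 chosen_step = best$k,
                 start = best$start,
                 rmsecv = best$rmse),
            class = "BandSelection")
}

#' @export
print.BandSelection <- function(x, ...) {
  cat(sprintf("%s band selection: %d bands (min RMSECV = %.4f)\n",
              x$method, length(x$selected), x$rmsecv))
  cat("  ", paste(x$selected_wavelengths, collapse = ", "), "\n")
  invisible(x)
}
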