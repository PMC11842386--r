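#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds so that class proportions are
#' preserved as closely as possible. Deterministic given `seed`; the same
#' assignment can therefore be reused across models or across points of a
#' hyperparameter grid.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`, one per sample.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- as.factor(y)
  if (min(table(y)) < k) stop("k exceeds the smallest class count")
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
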