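#' Competitive adaptive reweighted sampling for band selection
#'
#' Monte-Carlo wavelength selection built on PLS regression. Each run fits a
#' PLS model on a random row subsample of the currently retained bands and
#' ranks bands by the absolute value of their regression coefficients. Two
#' pressures shrink the band set: an exponentially decaying retention ratio
#' (enforced reduction, keeping the top-weighted bands), followed by
#' adaptive reweighted sampling, which resamples bands with probability
#' proportional to coefficient weight. The RMSE of a k-fold cross-validated
#' PLS model on each run's retained set is recorded, and the run with the
#' smallest RMSECV defines the selected wavelengths.
#'
#' The decay schedule is the standard two-point exponential: run 1 retains
#' (essentially) all bands and the final run would retain two, so retained
#' counts are non-increasing across runs.
#'
#' @param X Numeric band matrix `[n x p]` (`p >= 2`); column names
#'   (wavelengths in nm) are carried into the result when present.
#' @param y Class labels (coded 1 for barnyard grass) or a numeric response.
#' @param n_runs Number of Monte-Carlo runs (default 50).
#' @param folds CV folds for the RMSECV criterion (default 10).
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @param subsample Fraction of rows drawn per run (default 0.8).
#' @param max_ncomp Cap on PLS components (default 10); truncated with a
#'   warning when a retained set is smaller than the cap.
#' @return A `BandSelection` list: `selected`, `selected_wavelengths`,
#'   `method = "CARS"`, `criterion_trace` (per-run enforced-reduction
#'   count, i.e. the decay envelope, and RMSECV), and `chosen_step` (the
#'   winning run).
#' @export
cars_select <- function(X, y, n_runs = 50L, folds = 10L, seed = 1L,
                        subsample = 0.8, max_ncomp = 10L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n_runs < 2L) stop("n_runs must be >= 2")
  if (p < 2L) stop("X must have at least 2 columns")
  yn <- label_to_numeric(y)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))

  # two-point exponential decay: r_1 = 1, r_{n_runs} = 2/p
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  retained <- seq_len(p)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    rows <- sample(n, max(2L, round(subsample * n)))
    ncomp <- min(max_ncomp, length(retained), length(rows) - 1L)
    if (ncomp < min(max_ncomp, length(retained))) {
      warning("PLS components truncated to ", ncomp, " in run ", i)
    }
    fit <- pls_fit(X[rows, retained, drop = FALSE], yn[rows], ncomp)
    w <- abs(fit$coef)
    w[!is.finite(w)] <- 0
    if (sum(w) <= 0) w <- rep(1, length(w))
    # enforced reduction by the decay envelope
    keep_n <- max(2L, min(length(retained),
                          as.integer(round(a * exp(-k * i) * p))))
    ord <- order(w, decreasing = TRUE)
    retained <- retained[ord[seq_len(keep_n)]]
    w <- w[ord[seq_len(keep_n)]]
    # adaptive reweighted sampling: draw keep_n with weight ~ |coef|;
    # the working set never shrinks below two bands
    drawn <- unique(sample(seq_along(retained), keep_n, replace = TRUE,
                           prob = w / sum(w)))
    if (length(drawn) < 2L) drawn <- union(drawn, order(w,
                                                        decreasing = TRUE)[1:2])
    retained <- sort(retained[drawn])
    rmse <- pls_rmsecv(X[, retained, drop = FALSE], yn,
                       min(max_ncomp, length(retained)), fold_id)
    runs[[i]] <- list(set = retained, n = keep_n, rmsecv = rmse)
  }
  trace <- data.frame(run = seq_len(n_runs),
                      n_retained = vapply(runs, `[[`, integer(1), "n"),
                      rmsecv = vapply(runs, `[[`, numeric(1), "rmsecv"))
  best <- which.min(trace$rmsecv)
  sel <- runs[[best]]$set
  wl <- if (!is.null(colnames(X))) {
    suppressWarnings(as.numeric(colnames(X)[sel]))
  } else sel
  structure(list(selected = sel,
                 selected_wavelengths = wl,
                 method = "CARS",
                 criterion_trace = trace,
                 chosen_step = best,
                 rmsecv = trace$rmsecv[best]),
            class = "BandSelection")
}
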