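#' Standard normal variate transform
#'
#' Standardizes each spectrum independently: subtract its mean and divide by
#' its sample (n-1) standard deviation. Removes multiplicative scatter and
#' baseline tilt so that only the shape of the curve remains.
#'
#' @param x Numeric reflectance vector (length >= 2).
#' @return Transformed vector with mean 0 and sample sd 1.
#' @export
snv <- function(x) {
  if (length(x) < 2) stop("snv needs at least 2 bands")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("snv is undefined for a constant spectrum")
  (x - mean(x)) / s
}

#' Centered moving-average smoothing
#'
#' Replaces each band by the mean of the bands inside a centered window.
#' Near the edges the window is truncated to the available bands, so the
#' output always has the same length as the input.
#'
#' @param x Numeric reflectance vector.
#' @param window Odd integer window width in bands (default 5).
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("moving-average window must be odd")
  if (window < 1L || window > length(x)) stop("window must be in [1, length(x)]")
  n <- length(x)
  half <- (window - 1L) %/% 2L
  # cumulative-sum sliding mean with edge truncation
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing, the standard chemometrics
#' filter for attenuating high-frequency instrument noise while preserving
#' band shape. Delegates to [signal::sgolayfilt()].
#'
#' @param x Numeric reflectance vector.
#' @param window Odd integer window width in bands (default 11).
#' @param polyorder Polynomial order, must be < `window` (default 2).
#' @return Smoothed vector of the same length.
#' @export
savitzky_golay <- function(x, window = 11L, polyorder = 2L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("Savitzky-Golay window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (window > length(x)) stop("window exceeds spectrum length")
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
}

#' Mean centering learned on the training partition
#'
#' Subtracts per-band means from every spectrum. The means are computed on
#' the training set only and then applied unchanged to any other set, so no
#' information leaks from the test partition. Centering the training set by
#' itself yields exactly zero column means.
#'
#' @param train `SpectraSet` defining the band means.
#' @param apply_to `SpectraSet` to transform (defaults to `train`).
#' @return `apply_to` with centered reflectance.
#' @export
mean_center <- function(train, apply_to = train) {
  stopifnot(inherits(train, "SpectraSet"), inherits(apply_to, "SpectraSet"))
  if (!isTRUE(all.equal(train$wavelengths, apply_to$wavelengths))) {
    stop("wavelength grids of train and apply_to differ")
  }
  mu <- colMeans(train$reflectance)
  out <- apply_to
  out$reflectance <- sweep(apply_to$reflectance, 2L, mu, "-")
  out
}

#' Apply a named preprocessing method to a train/test pair
#'
#' Dispatches the four spectral preprocessing transforms. SNV, MA and SG act
#' per spectrum and need nothing from the training set; MC learns per-band
#' means on the training partition and applies them to both partitions.
#'
#' @param train Training `SpectraSet`.
#' @param test Test `SpectraSet` (optional).
#' @param method One of `"none"`, `"snv"`, `"ma"`, `"sg"`, `"mc"`.
#' @param ma_window Moving-average window (odd, default 5).
#' @param sg_window Savitzky-Golay window (odd, default 11).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 2).
#' @return List with transformed `train` and (if given) `test` sets.
#' @export
preprocess_spectra <- function(train, test = NULL,
                               method = c("none", "snv", "ma", "sg", "mc"),
                               ma_window = 5L, sg_window = 11L,
                               sg_polyorder = 2L) {
  method <- match.arg(method)
  per_row <- function(data, f) {
    out <- data
    out$reflectance <- t(apply(data$reflectance, 1L, f))
    out
  }
  tr <- function(data) {
    switch(method,
      none = data,
      snv  = per_row(data, snv),
      ma   = per_row(data, function(v) moving_average(v, ma_window)),
      sg   = per_row(data, function(v) savitzky_golay(v, sg_window, sg_polyorder)),
      mc   = mean_center(train, data))
  }
  out <- list(train = tr(train))
  if (!is.null(test)) out$test <- tr(test)
  out
}
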