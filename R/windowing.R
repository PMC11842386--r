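#' Sliding-window configuration
#'
#' Parameters of the 1-D-to-2-D subsequence transform: a window of `w` bands
#' slides over the `m`-band spectrum in steps of `s` bands; the stacked
#' windows form the 2-D matrix fed to the network.
#'
#' @param w Window length in bands.
#' @param s Sliding step in bands; `1 <= s <= w <= m`.
#' @param m Spectrum length in bands (default 2151, the full-range grid).
#' @param tail Fill rule for the final window when it overruns the end of
#'   the spectrum (possible only under `count = "cover"`): `"mirror"`
#'   (default) reflects the sequence backwards from its last band;
#'   `"last_window"` instead uses the last `w` bands.
#' @param count Window-count rule. `"truncate"` (default) evaluates the
#'   textbook formula `(m - w)/s + 1` with integer truncation, so every
#'   window is an exact slice (when `s` does not divide `m - w`, up to
#'   `(m - w) %% s` trailing bands go unrepresented). `"cover"` rounds up
#'   instead, guaranteeing every band appears in some window and filling
#'   the final window's overrun by the `tail` rule.
#' @return A `WindowConfig` object.
#' @export
window_config <- function(w, s, m = 2151L, tail = c("mirror", "last_window"),
                          count = c("truncate", "cover")) {
  tail <- match.arg(tail)
  count <- match.arg(count)
  w <- as.integer(w); s <- as.integer(s); m <- as.integer(m)
  if (s < 1L || s > w) stop("need 1 <= s <= w")
  if (w > m) stop("window length w exceeds sequence length m")
  structure(list(w = w, s = s, m = m, tail = tail, count = count),
            class = "WindowConfig")
}

#' Number of windows produced by a configuration
#'
#' `(m - w)/s + 1` windows, integer-truncated under the default
#' `"truncate"` rule (so the count is exact when `s` divides `m - w`), or
#' rounded up under `"cover"` so that the final bands are always
#' represented (the last window is then filled by the configured tail
#' rule). The canonical full-range configuration `m = 2151`, `w = 200`,
#' `s = 150` yields 14 windows.
#'
#' @param config A `WindowConfig`.
#' @return Integer window count.
#' @export
window_count <- function(config) {
  stopifnot(inherits(config, "WindowConfig"))
  frac <- (config$m - config$w) / config$s
  k <- if (identical(config$count, "cover")) ceiling(frac) else floor(frac)
  as.integer(k) + 1L
}

#' Transform one spectrum into its subsequence matrix
#'
#' Row i (0-based) is the slice `[i*s, i*s + w)` of the spectrum. When the
#' final window overruns the end of the sequence, the missing tail is filled
#' by mirror reflection from the last band (`..., x[m-1], x[m-2], ...`,
#' without repeating the endpoint), or by the last `w` bands when
#' `tail = "last_window"`.
#'
#' @param x Numeric spectrum of length `config$m`.
#' @param config A `WindowConfig`.
#' @return A `SubsequenceMatrix`: numeric matrix `[n_windows x w]` with the
#'   configuration attached as attribute `"config"`.
#' @export
subsequence_matrix <- function(x, config) {
  stopifnot(inherits(config, "WindowConfig"))
  m <- config$m; w <- config$w; s <- config$s
  if (length(x) != m) {
    stop(sprintf("spectrum has %d bands, config expects %d", length(x), m))
  }
  k <- window_count(config)
  out <- matrix(0, nrow = k, ncol = w)
  for (i in seq_len(k)) {
    start <- (i - 1L) * s                       # 0-based
    idx <- start + seq_len(w)                   # 1-based into x
    if (idx[w] <= m) {
      out[i, ] <- x[idx]
    } else if (config$tail == "last_window") {
      out[i, ] <- x[(m - w + 1L):m]
    } else {
      # mirror: positions past the end fold back as m-1, m-2, ... (1-based:
      # index j > m maps to 2m - j)
      idx[idx > m] <- 2L * m - idx[idx > m]
      out[i, ] <- x[idx]
    }
  }
  structure(out, config = config, class = c("SubsequenceMatrix", "matrix"))
}

#' Transform every spectrum of a SpectraSet
#'
#' @param data A `SpectraSet` whose spectra have length `config$m`.
#' @param config A `WindowConfig`.
#' @return Numeric array `[n_samples x n_windows x w]` with `config`
#'   attached as attribute `"config"`.
#' @export
batch_transform <- function(data, config) {
  stopifnot(inherits(data, "SpectraSet"), inherits(config, "WindowConfig"))
  n <- n_spectra(data)
  k <- window_count(config)
  out <- array(0, dim = c(n, k, config$w))
  for (i in seq_len(n)) {
    out[i, , ] <- subsequence_matrix(data$reflectance[i, ], config)
  }
  structure(out, config = config)
}
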