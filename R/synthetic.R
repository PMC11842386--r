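#' Configuration of the synthetic leaf-reflectance generator
#'
#' The generator draws stylized green-leaf reflectance spectra on the full
#' 350-2500 nm grid: chlorophyll absorption troughs near 430 and 680 nm, a
#' green peak near 550 nm, a logistic red-edge rise between 700 and 750 nm,
#' an NIR plateau, and water-absorption dips near 1450 and 1940 nm. The two
#' classes differ subtly, the way rice and barnyard grass seedlings do: the
#' red-edge inflection of barnyard grass is shifted by `red_edge_shift` nm
#' and its pigment absorption bands are deeper by `pigment_delta`. Samples
#' vary in amplitude, baseline and their own red-edge position; batches add
#' a session-level baseline offset and gain, mimicking spectrometer drift
#' between acquisition sessions.
#'
#' The default sample counts reproduce the canonical three-batch layout:
#' 313 rice and 347 barnyard grass spectra, with batches 1-2 (243 rice +
#' 252 barnyard) intended as the training set and batch 3 (70 rice + 95
#' barnyard) as the independent test set.
#'
#' @param n_rice Integer vector: rice spectra per batch.
#' @param n_barnyard Integer vector: barnyard-grass spectra per batch; must
#'   have the same length (number of batches) as `n_rice`.
#' @param red_edge_shift Class effect: shift of the barnyard-grass red-edge
#'   inflection, in nm (default 4).
#' @param pigment_delta Class effect: extra depth of the barnyard-grass
#'   chlorophyll absorption bands, unitless reflectance (default 0.012).
#' @param noise_sd Additive Gaussian noise sd per band (default 0.006,
#'   roughly the repeatability of a field spectrometer).
#' @param batch_shift_sd Sd of the per-batch additive baseline offset
#'   (default 0.02).
#' @param batch_gain_sd Sd of the per-batch multiplicative gain around 1
#'   (default 0.01).
#' @param amp_sd Sd of the per-sample amplitude factor around 1 (default 0.04).
#' @param baseline_sd Sd of the per-sample additive baseline (default 0.01).
#' @param within_red_edge_sd Within-class sd of the per-sample red-edge
#'   position, in nm (default 2).
#' @param within_depth_sd Within-class sd of the per-sample pigment band
#'   depth (default 0.008).
#' @param seed Integer seed making the draw reproducible.
#' @return A `SimConfig` object.
#' @export
sim_config <- function(n_rice = c(122L, 121L, 70L),
                       n_barnyard = c(126L, 126L, 95L),
                       red_edge_shift = 4,
                       pigment_delta = 0.012,
                       noise_sd = 0.006,
                       batch_shift_sd = 0.02,
                       batch_gain_sd = 0.01,
                       amp_sd = 0.04,
                       baseline_sd = 0.01,
                       within_red_edge_sd = 2,
                       within_depth_sd = 0.008,
                       seed = 1L) {
  if (length(n_rice) != length(n_barnyard)) {
    stop("n_rice and n_barnyard must give counts for the same batches")
  }
  if (any(c(n_rice, n_barnyard) < 1L)) stop("per-batch counts must be >= 1")
  scales <- c(noise_sd, batch_shift_sd, batch_gain_sd, amp_sd, baseline_sd,
              within_red_edge_sd, within_depth_sd)
  if (any(scales < 0)) stop("all variation scales must be >= 0")
  structure(
    list(n_rice = as.integer(n_rice), n_barnyard = as.integer(n_barnyard),
         n_batches = length(n_rice),
         red_edge_shift = red_edge_shift, pigment_delta = pigment_delta,
         noise_sd = noise_sd, batch_shift_sd = batch_shift_sd,
         batch_gain_sd = batch_gain_sd, amp_sd = amp_sd,
         baseline_sd = baseline_sd,
         within_red_edge_sd = within_red_edge_sd,
         within_depth_sd = within_depth_sd, seed = as.integer(seed)),
    class = "SimConfig"
  )
}

# Deterministic leaf template: reflectance as a function of wavelength for a
# given red-edge midpoint and pigment-band depth.
leaf_template <- function(wl, red_edge_mid, depth680, depth430) {
  vis <- 0.09
  nir <- 0.50
  r <- vis + (nir - vis) * stats::plogis((wl - red_edge_mid) / 11) +
    0.055 * exp(-((wl - 550) / 30)^2) -       # green peak
    depth430 * exp(-((wl - 430) / 18)^2) -    # blue chlorophyll absorption
    depth680 * exp(-((wl - 680) / 13)^2) -    # red chlorophyll absorption
    0.18 * exp(-((wl - 1450) / 38)^2) -       # water band
    0.26 * exp(-((wl - 1940) / 48)^2) -       # water band
    0.14 * pmax(0, wl - 1000) / 1500          # gentle SWIR decline
  r
}

#' Generate a synthetic two-class spectral dataset
#'
#' Draws one spectrum per specimen according to a [sim_config()]:
#' class template + per-sample red-edge and pigment-depth jitter +
#' per-sample amplitude/baseline variation + per-batch offset and gain +
#' additive Gaussian noise, finally clipped to the physical range `[0, 1]`.
#' Fully reproducible given `config$seed`.
#'
#' @param config A `SimConfig`.
#' @return A `SpectraSet` on the 350-2500 nm grid.
#' @export
generate_spectra <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  wl <- default_grid()
  n_total <- sum(config$n_rice) + sum(config$n_barnyard)
  refl <- matrix(0, n_total, length(wl))
  labels <- character(n_total)
  batch <- integer(n_total)

  batch_offset <- stats::rnorm(config$n_batches, 0, config$batch_shift_sd)
  batch_gain <- stats::rnorm(config$n_batches, 1, config$batch_gain_sd)

  row <- 0L
  for (b in seq_len(config$n_batches)) {
    counts <- c(rice = config$n_rice[b], barnyard_grass = config$n_barnyard[b])
    for (cls in names(counts)) {
      is_bg <- cls == "barnyard_grass"
      for (i in seq_len(counts[[cls]])) {
        row <- row + 1L
        mid <- 716 + if (is_bg) config$red_edge_shift else 0
        mid <- mid + stats::rnorm(1, 0, config$within_red_edge_sd)
        d680 <- 0.05 + (if (is_bg) config$pigment_delta else 0) +
          stats::rnorm(1, 0, config$within_depth_sd)
        d430 <- 0.04 + (if (is_bg) config$pigment_delta else 0) +
          stats::rnorm(1, 0, config$within_depth_sd)
        amp <- stats::rnorm(1, 1, config$amp_sd)
        base <- stats::rnorm(1, 0, config$baseline_sd)
        r <- leaf_template(wl, mid, d680, d430)
        r <- batch_gain[b] * (amp * r + base + batch_offset[b]) +
          stats::rnorm(length(wl), 0, config$noise_sd)
        refl[row, ] <- pmin(pmax(r, 0), 1)
        labels[row] <- cls
        batch[row] <- b
      }
    }
  }
  spectra_set(refl, labels, batch, wl)
}

#' Three-batch benchmark layout
#'
#' Generates the canonical dataset layout used throughout the package's
#' examples: 660 spectra across three batches, batches 1-2 as the training
#' set (243 rice + 252 barnyard grass, 495 spectra) and batch 3 as the
#' independent test set (70 rice + 95 barnyard grass, 165 spectra).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()] (e.g. `red_edge_shift`).
#' @return List with `SpectraSet` elements `train` and `test`.
#' @export
benchmark_layout <- function(seed = 1L, ...) {
  config <- sim_config(seed = seed, ...)
  data <- generate_spectra(config)
  split_by_batch(data, train_batches = c(1L, 2L), test_batches = 3L)
}
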