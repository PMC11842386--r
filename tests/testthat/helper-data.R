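# Small fixtures built in code.

# tiny labeled spectra on a short wavelength grid
tiny_spectra <- function(n = 6L, m = 50L, seed = 1L) {
  set.seed(seed)
  wl <- seq(350L, length.out = m)
  refl <- matrix(runif(n * m, 0.05, 0.6), n, m)
  spectra_set(refl,
              rep(c("barnyard_grass", "rice"), length.out = n),
              rep(1:2, length.out = n), wl)
}

# small three-batch simulation (fast substitute for the full 660-sample layout)
small_layout <- function(seed = 1L, per_class = 20L, ...) {
  cfg <- sim_config(n_rice = rep(per_class, 3), n_barnyard = rep(per_class, 3),
                    seed = seed, ...)
  split_by_batch(generate_spectra(cfg), 1:2, 3L)
}

# subsample every k-th band to keep classical models fast
thin_bands <- function(data, k = 20L) {
  idx <- seq(1L, length(data$wavelengths), by = k)
  spectra_set(data$reflectance[, idx, drop = FALSE], data$labels,
              data$batch, data$wavelengths[idx])
}

# desk-scale network training settings used by the end-to-end checks
# (published defaults are lr 5e-6 / 150 epochs; see the methods vignette)
desk_train_config <- function(seed, epochs = 40L, lr = 3e-4) {
  train_config(learning_rate = lr, epochs = epochs, seed = seed)
}
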