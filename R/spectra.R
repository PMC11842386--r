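#' Default full-range wavelength grid
#'
#' Band centers of a full-range field spectrometer: 350 to 2500 nm inclusive
#' on a 1 nm grid, 2151 bands.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_grid <- function() seq(350L, 2500L)

#' Class labels used throughout the package
#'
#' Barnyard grass is the positive class; rice the negative. The order here
#' fixes the confusion-matrix layout and the meaning of predicted
#' probabilities everywhere in the package.
#'
#' @export
spectra_classes <- function() c("barnyard_grass", "rice")

#' Construct a labeled spectral dataset
#'
#' A `SpectraSet` bundles a reflectance matrix (one row per specimen, one
#' column per band), per-sample class labels, a batch (measurement session)
#' index, and the shared wavelength grid.
#'
#' @param reflectance Numeric matrix `[n_samples x n_bands]` of unitless
#'   reflectance values; all values must be finite.
#' @param labels Character or factor vector with levels among
#'   `c("barnyard_grass", "rice")`, one entry per row.
#' @param batch Integer vector of batch indices, one entry per row.
#' @param wavelengths Numeric vector of strictly increasing band centers in
#'   nm; length must equal `ncol(reflectance)`.
#' @return An object of class `SpectraSet`.
#' @export
spectra_set <- function(reflectance, labels, batch,
                        wavelengths = default_grid()) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  if (ncol(reflectance) != length(wavelengths)) {
    stop(sprintf("reflectance has %d bands but grid has %d wavelengths",
                 ncol(reflectance), length(wavelengths)))
  }
  if (!all(is.finite(reflectance))) {
    stop("reflectance contains non-finite values")
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), spectra_classes())
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  labels <- factor(labels, levels = spectra_classes())
  batch <- as.integer(batch)
  n <- nrow(reflectance)
  if (length(labels) != n || length(batch) != n) {
    stop("labels and batch must have one entry per spectrum")
  }
  structure(
    list(reflectance = reflectance, labels = labels, batch = batch,
         wavelengths = wavelengths),
    class = "SpectraSet"
  )
}

#' @export
print.SpectraSet <- function(x, ...) {
  cat(sprintf("SpectraSet: %d spectra x %d bands (%g-%g nm)\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  batches:", paste(sort(unique(x$batch)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra in a SpectraSet
#' @param data A `SpectraSet`.
#' @return Integer sample count.
#' @export
n_spectra <- function(data) nrow(data$reflectance)

#' Subset a SpectraSet by sample index
#' @param data A `SpectraSet`.
#' @param idx Integer or logical index over samples.
#' @return A `SpectraSet` containing the selected spectra.
#' @export
subset_spectra <- function(data, idx) {
  spectra_set(data$reflectance[idx, , drop = FALSE],
              data$labels[idx], data$batch[idx], data$wavelengths)
}

#' Read a spectral table from CSV
#'
#' Expects the storage format written by [save_spectra()]: one header row
#' whose first columns are wavelengths in nm (e.g. `350,351,...,2500`),
#' followed by a `label` and a `batch` column; one data row per specimen.
#'
#' @param path Path to a CSV file.
#' @return A validated `SpectraSet`.
#' @export
load_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  cn <- colnames(dt)
  if (!all(c("label", "batch") %in% cn)) {
    stop("malformed header: 'label' and 'batch' columns are required")
  }
  band_cols <- setdiff(cn, c("label", "batch"))
  wl <- suppressWarnings(as.numeric(band_cols))
  if (anyNA(wl)) {
    stop("malformed header: band columns must be numeric wavelengths, got: ",
         paste(utils::head(band_cols[is.na(wl)], 3), collapse = ", "))
  }
  refl <- as.matrix(dt[, band_cols, drop = FALSE])
  storage.mode(refl) <- "double"
  if (nrow(refl) > 0 && !all(is.finite(refl))) {
    stop("non-numeric or missing reflectance cells in ", path)
  }
  spectra_set(refl, dt$label, dt$batch, wl)
}

#' Write a spectral table to CSV
#'
#' Columns are wavelength-named reflectance values followed by `label` and
#' `batch`. The file round-trips through [load_spectra()] up to float
#' formatting precision.
#'
#' @param data A `SpectraSet`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_spectra <- function(data, path) {
  stopifnot(inherits(data, "SpectraSet"))
  df <- as.data.frame(data$reflectance)
  colnames(df) <- as.character(data$wavelengths)
  df$label <- as.character(data$labels)
  df$batch <- data$batch
  data.table::fwrite(df, path)
  invisible(path)
}

#' Split a SpectraSet by measurement batch
#'
#' The canonical protocol holds out one whole acquisition batch as the
#' independent test set (batches 1-2 train, batch 3 test), so that train and
#' test spectra never share a measurement session.
#'
#' @param data A `SpectraSet`.
#' @param train_batches Integer vector of batch indices for the training set.
#' @param test_batches Integer vector of batch indices for the test set;
#'   must be disjoint from `train_batches`.
#' @return A list with `SpectraSet` elements `train` and `test`.
#' @export
split_by_batch <- function(data, train_batches, test_batches) {
  stopifnot(inherits(data, "SpectraSet"))
  train_batches <- as.integer(train_batches)
  test_batches <- as.integer(test_batches)
  if (length(intersect(train_batches, test_batches)) > 0) {
    stop("train_batches and test_batches must be disjoint")
  }
  list(train = subset_spectra(data, data$batch %in% train_batches),
       test = subset_spectra(data, data$batch %in% test_batches))
}
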