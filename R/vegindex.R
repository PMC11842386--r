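#' Vegetation-index feature set
#'
#' Converts full spectra into 163 classical vegetation-index features,
#' computed on raw (unpreprocessed) reflectance:
#'
#' * 80 NDVI features `(R_r1 - R_r2) / (R_r1 + R_r2)` over all pairs of
#'   eight near-infrared bands `r1` = 724, 738, 750, 764, 776, 790, 802,
#'   814 nm and ten red bands `r2` = 601, 605, 614, 627, 636, 644, 652,
#'   660, 669, 677 nm;
#' * 80 RVI features `R_r1 / R_r2` over the same pairs;
#' * TVI `0.5 * (120 * (R750 - R550) - 200 * (R650 - R550))`;
#' * PRI `(R531 - R570) / (R531 + R570)`;
#' * NPCI `(R680 - R430) / (R680 + R430)`.
#'
#' Columns are ordered deterministically: all NDVI pairs (r1 outer, r2
#' inner), all RVI pairs, then TVI, PRI, NPCI. Zero denominators yield `NA`
#' with a warning.
#'
#' @param data A `SpectraSet` of raw reflectance whose grid contains all
#'   required wavelengths.
#' @param r1 Near-infrared band list in nm (default as above).
#' @param r2 Red band list in nm (default as above).
#' @return Numeric matrix `[n_samples x 163]` with named columns.
#' @export
vegetation_indices <- function(data,
                               r1 = c(724, 738, 750, 764, 776, 790, 802, 814),
                               r2 = c(601, 605, 614, 627, 636, 644, 652, 660,
                                      669, 677)) {
  stopifnot(inherits(data, "SpectraSet"))
  needed <- c(r1, r2, 750, 550, 650, 531, 570, 680, 430)
  missing <- setdiff(needed, data$wavelengths)
  if (length(missing) > 0) {
    stop("grid lacks required wavelengths: ", paste(missing, collapse = ", "))
  }
  R <- function(nm) data$reflectance[, match(nm, data$wavelengths)]

  n <- n_spectra(data)
  cols <- vector("list", 2 * length(r1) * length(r2) + 3)
  names_out <- character(length(cols))
  k <- 0L
  safe_ratio <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning("zero denominator in ", what, "; value set to NA")
      den[bad] <- NA_real_
    }
    num / den
  }
  for (a in r1) for (b in r2) {
    k <- k + 1L
    cols[[k]] <- safe_ratio(R(a) - R(b), R(a) + R(b), sprintf("NDVI_%g_%g", a, b))
    names_out[k] <- sprintf("NDVI_%g_%g", a, b)
  }
  for (a in r1) for (b in r2) {
    k <- k + 1L
    cols[[k]] <- safe_ratio(R(a), R(b), sprintf("RVI_%g_%g", a, b))
    names_out[k] <- sprintf("RVI_%g_%g", a, b)
  }
  k <- k + 1L
  cols[[k]] <- 0.5 * (120 * (R(750) - R(550)) - 200 * (R(650) - R(550)))
  names_out[k] <- "TVI"
  k <- k + 1L
  cols[[k]] <- safe_ratio(R(531) - R(570), R(531) + R(570), "PRI")
  names_out[k] <- "PRI"
  k <- k + 1L
  cols[[k]] <- safe_ratio(R(680) - R(430), R(680) + R(430), "NPCI")
  names_out[k] <- "NPCI"

  out <- do.call(cbind, cols)
  # guard against degenerate n = 1 dropping to a vector
  out <- matrix(out, nrow = n)
  colnames(out) <- names_out
  out
}
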