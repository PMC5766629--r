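#' Spectrum set container
#'
#' Bundles a set of 1D 1H-NMR spectra sharing a chemical-shift axis with
#' two-class group labels (control/treated).
#'
#' @param ppm numeric chemical-shift axis (ppm), strictly monotone (stored
#'   descending, the plotting convention for NMR).
#' @param intensities samples x length(ppm) matrix of non-negative reals;
#'   row names are sample IDs.
#' @param groups character/factor of class labels, one per sample.
#' @return object of class `netmet_spectra`.
#' @export
spectrum_set <- function(ppm, intensities, groups) {
  intensities <- as.matrix(intensities)
  if (length(ppm) != ncol(intensities)) {
    stop("ppm axis length must equal the number of intensity columns")
  }
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  if (d[1] > 0) { # store descending
    ppm <- rev(ppm)
    intensities <- intensities[, ncol(intensities):1, drop = FALSE]
  }
  if (length(groups) != nrow(intensities)) {
    stop("one group label per sample required")
  }
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- paste0("S", seq_len(nrow(intensities)))
  }
  structure(list(ppm = ppm, intensities = intensities,
                 groups = as.character(groups)),
            class = "netmet_spectra")
}

#' @export
print.netmet_spectra <- function(x, ...) {
  cat("netmet_spectra:", nrow(x$intensities), "spectra,",
      length(x$ppm), "points, ppm", round(min(x$ppm), 3), "-",
      round(max(x$ppm), 3), "\n")
  cat("groups:", paste(names(table(x$groups)), table(x$groups),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Bin spectra into fixed-width chemical-shift buckets
#'
#' Segments each spectrum into left-closed bins `[left, left+width)` of
#' `width` ppm spanning `range`, summing the grid intensities falling in
#' each bin. Bins intersecting any excluded interval (by default the
#' residual-water region delta 4.5-5.0) are dropped *before* any
#' normalization. With the defaults (0.01 ppm over [0.50, 9.00), water
#' exclusion) this yields 850 raw bins of which 800 are retained.
#'
#' @param spectra a `netmet_spectra`.
#' @param width bin width in ppm (default 0.01).
#' @param range two-element numeric, the half-open binning span (default
#'   `c(0.50, 9.00)`).
#' @param exclude list of half-open ppm intervals to drop (default
#'   `list(c(4.5, 5.0))`).
#' @return object of class `netmet_binned`: `X` (samples x retained bins,
#'   columns named by left edge), `bin_left`/`bin_right` (retained edges),
#'   `n_raw_bins`, `excluded`, `groups`, `normalized` flag.
#' @export
bin_spectra <- function(spectra, width = 0.01, range = c(0.50, 9.00),
                        exclude = list(c(4.5, 5.0))) {
  stopifnot(width > 0, length(range) == 2L, range[2] > range[1])
  ppm <- spectra$ppm
  eps <- 1e-9
  if (min(ppm) > range[1] + eps || max(ppm) < range[2] - width + eps) {
    stop(sprintf(
      "spectral grid [%.3f, %.3f] does not cover requested range [%.2f, %.2f)",
      min(ppm), max(ppm), range[1], range[2]))
  }
  n_bins <- as.integer(round((range[2] - range[1]) / width))
  lefts <- range[1] + width * (seq_len(n_bins) - 1L)
  idx <- floor((ppm - range[1]) / width + eps)
  in_range <- idx >= 0 & idx < n_bins
  X <- matrix(0, nrow(spectra$intensities), n_bins)
  agg <- rowsum(t(spectra$intensities[, in_range, drop = FALSE]),
                group = idx[in_range])
  X[, as.integer(rownames(agg)) + 1L] <- t(agg)
  rownames(X) <- rownames(spectra$intensities)
  # half-open interval intersection, tolerant to fp wobble on shared edges
  keep <- rep(TRUE, n_bins)
  for (ex in exclude) {
    keep <- keep & !(lefts < ex[2] - eps & lefts + width > ex[1] + eps)
  }
  structure(list(
    X = `colnames<-`(X[, keep, drop = FALSE], sprintf("%.4g", lefts[keep])),
    bin_left = lefts[keep], bin_right = lefts[keep] + width,
    n_raw_bins = n_bins, excluded = exclude,
    groups = spectra$groups, normalized = FALSE
  ), class = "netmet_binned")
}

#' @export
print.netmet_binned <- function(x, ...) {
  cat("netmet_binned:", nrow(x$X), "samples x", ncol(x$X), "retained bins",
      sprintf("(of %d raw)", x$n_raw_bins),
      if (x$normalized) "[row-normalized]" else "", "\n")
  invisible(x)
}

#' Row-sum (total-intensity) normalization
#'
#' Scales each sample's retained-bin vector to sum to 1, the constant-sum
#' normalization conventionally applied to binned NMR data to remove
#' dilution/mass differences between samples.
#'
#' @param binned a `netmet_binned`.
#' @return the same object with rows summing to 1 and `normalized = TRUE`.
#' @export
normalize_rows <- function(binned) {
  rs <- rowSums(binned$X)
  bad <- which(rs <= 0)
  if (length(bad)) {
    stop("non-positive row sum for sample(s): ",
         paste(rownames(binned$X)[bad], collapse = ", "))
  }
  binned$X <- binned$X / rs
  binned$normalized <- TRUE
  binned
}
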