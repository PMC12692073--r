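## FTIR spectrum handling and construction of the band-intensity block.

#' Built-in catalogue of the 37 ATR-FTIR band regions
#'
#' The band regions of the citrus-peel fingerprint table, from 3630 down to
#' 530-524 cm-1, with the chemical annotation carried as an opaque display
#' string (vibration mode; associated compound classes). Range labels such
#' as \code{"1016-1012"} use the range midpoint as the picking centre.
#'
#' @return data.frame with columns \code{label}, \code{low}, \code{high},
#'   \code{center}, \code{annotation}, ordered by descending wavenumber.
#' @export
citrusBands <- function() {
  path <- system.file("extdata", "ftir_bands.csv",
                      package = "peelfusion", mustWork = TRUE)
  b <- read.csv(path, stringsAsFactors = FALSE)
  b$center <- (b$low + b$high) / 2
  b[order(-b$center), c("label", "low", "high", "center", "annotation")]
}

#' Read a two-column spectrum CSV
#'
#' @param path CSV with numeric columns (wavenumber, absorbance); a header
#'   row is tolerated. At least 2 points required.
#' @return data.frame with columns \code{wavenumber}, \code{absorbance},
#'   sorted by descending wavenumber.
#' @export
readSpectrum <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1L,
                           stringsAsFactors = FALSE)
  hasHeader <- is.na(suppressWarnings(as.numeric(first[[1L]])))
  s <- utils::read.csv(path, header = hasHeader, stringsAsFactors = FALSE)
  if (ncol(s) < 2L) stop("expected a two-column spectrum file")
  s <- s[, 1:2]
  names(s) <- c("wavenumber", "absorbance")
  s$wavenumber <- suppressWarnings(as.numeric(s$wavenumber))
  s$absorbance <- suppressWarnings(as.numeric(s$absorbance))
  if (anyNA(s)) stop("non-numeric rows in spectrum file: ", path)
  if (nrow(s) < 2L) stop("spectrum has fewer than 2 points")
  if (any(s$wavenumber < 0)) stop("negative wavenumbers in spectrum file")
  s <- s[order(-s$wavenumber), ]
  rownames(s) <- NULL
  s
}

#' Write a spectrum as a two-column CSV
#'
#' @param s spectrum data.frame (wavenumber, absorbance).
#' @param path output path.
#' @export
writeSpectrum <- function(s, path) {
  utils::write.csv(s[, c("wavenumber", "absorbance")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Pick one band's intensity from a spectrum
#'
#' The intensity is the maximum absorbance inside the band window
#' \code{[low - window, high + window]} (a single per-band peak height, the
#' shape of the published intensity table), optionally after subtracting a
#' linear local baseline through the window endpoints. Integrated area over
#' the window is available as an alternative statistic.
#'
#' @param s spectrum data.frame (wavenumber, absorbance).
#' @param band one row of \code{\link{citrusBands}}, or a list/data.frame
#'   with \code{low} and \code{high} (equal for single-centre bands), or a
#'   single numeric centre.
#' @param window half-width extension in cm-1 (default 8).
#' @param baseline subtract the linear baseline through the window
#'   endpoints before picking (default FALSE: table intensities are
#'   treated as already-processed peak heights).
#' @param statistic \code{"max"} (peak height, default) or \code{"area"}
#'   (trapezoidal integral over the window).
#' @return single absorbance value.
#' @export
pickBandIntensity <- function(s, band, window = 8, baseline = FALSE,
                              statistic = c("max", "area")) {
  statistic <- match.arg(statistic)
  if (is.numeric(band) && is.null(names(band)) && length(band) == 1L)
    band <- list(low = band, high = band)
  lo <- band$low - window
  hi <- band$high + window
  inw <- s$wavenumber >= lo & s$wavenumber <= hi
  if (!any(inw))
    stop(sprintf("band window [%.1f, %.1f] does not intersect the spectrum",
                 lo, hi))
  w <- s$wavenumber[inw]
  a <- s$absorbance[inw]
  if (baseline && length(a) > 2L) {
    # linear baseline through the window endpoint absorbances
    b0 <- a[which.max(w)]; b1 <- a[which.min(w)]
    w0 <- max(w); w1 <- min(w)
    a <- a - (b0 + (b1 - b0) * (w - w0) / (w1 - w0))
  }
  if (statistic == "max") max(a)
  else {
    o <- order(w)
    sum(diff(w[o]) * (head(a[o], -1L) + a[o][-1L]) / 2)
  }
}

#' Build the band-intensity FeatureBlock from per-sample spectra
#'
#' Applies \code{\link{pickBandIntensity}} to every (sample, band) pair,
#' producing the n_samples x n_bands matrix with columns in descending
#' wavenumber order. A band absent from a spectrum simply yields its
#' windowed value (near zero), never a missing cell.
#'
#' @param spectra named list of spectrum data.frames, one per sample.
#' @param bands band definitions (\code{\link{citrusBands}} by default).
#' @param classes per-sample class labels (same length/order as
#'   \code{spectra}).
#' @param window picking half-width in cm-1.
#' @param ... further arguments to \code{\link{pickBandIntensity}}.
#' @return a \linkS4class{FeatureBlock} with \code{blockId = "ftir"}.
#' @export
buildBandBlock <- function(spectra, bands = citrusBands(), classes,
                           window = 8, ...) {
  if (length(classes) != length(spectra))
    stop("misaligned samples: one class label per spectrum required")
  bands <- bands[order(-bands$center), , drop = FALSE]
  vals <- vapply(spectra, function(s) {
    vapply(seq_len(nrow(bands)), function(i)
      pickBandIntensity(s, bands[i, ], window = window, ...), 0)
  }, numeric(nrow(bands)))
  vals <- t(vals)  # samples x bands
  colnames(vals) <- bands$label
  if (is.null(rownames(vals)))
    rownames(vals) <- if (!is.null(names(spectra))) names(spectra)
                      else sprintf("sample_%02d", seq_len(nrow(vals)))
  FeatureBlock(vals, blockId = "ftir", classes = classes,
               sampleIds = rownames(vals),
               units = rep("absorbance", nrow(bands)))
}
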