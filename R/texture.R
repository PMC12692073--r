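## Grayscale texture profiling: 4 first-order histogram statistics, 6
## co-occurrence (GLCM) features, 5 run-length (GLRLM) features.

#' Grayscale image container
#'
#' A plain integer matrix of gray levels in \code{[0, levels-1]} with the
#' gray-level count attached, so quantization downstream knows the input
#' range.
#'
#' @param pixels numeric/integer matrix, at least 2 x 2.
#' @param levels number of gray levels G (default 256).
#' @return the matrix with class \code{grayImage} and attribute
#'   \code{levels}.
#' @export
grayImage <- function(pixels, levels = 256L) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2")
  if (any(pixels < 0) || any(pixels > levels - 1L))
    stop("pixel values outside [0, levels-1]")
  storage.mode(pixels) <- "integer"
  structure(pixels, levels = as.integer(levels), class = "grayImage")
}

.imgLevels <- function(img) {
  lv <- attr(img, "levels")
  if (is.null(lv)) 256L else lv
}

#' Convert an RGB image to grayscale
#'
#' Standard luminance transform with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), rounded half-up to the nearest integer
#' gray level.
#'
#' @param rgb h x w x 3 array, either 8-bit integers in \code{[0, 255]} or
#'   doubles in \code{[0, 1]} (as returned by \code{png::readPNG}).
#' @return a \code{\link{grayImage}} with 256 levels.
#' @examples
#' px <- array(0, c(2, 2, 3)); px[, , 1] <- 255
#' toGrayscale(px)[1, 1]  # 76
#' @export
toGrayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] < 3L)
    stop("expected a 3-channel image array")
  if (max(rgb) <= 1) rgb <- rgb * 255
  g <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  grayImage(floor(g + 0.5), levels = 256L)
}

#' Read a PNG or TIFF image as grayscale
#'
#' @param path image file; 3-channel input is converted via
#'   \code{\link{toGrayscale}}, single-channel input is rescaled to
#'   \code{[0, 255]}.
#' @return a \code{\link{grayImage}}.
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] >= 3L) return(toGrayscale(px[, , 1:3]))
    px <- px[, , 1L]
  }
  grayImage(floor(px * 255 + 0.5), levels = 256L)
}

#' Write a grayscale image as PNG
#'
#' @param img a \code{\link{grayImage}}.
#' @param path output path.
#' @export
writeGrayImage <- function(img, path) {
  png::writePNG(unclass(img) / (.imgLevels(img) - 1L), path)
  invisible(path)
}

#' Extract regions of interest from an image
#'
#' \code{grid} placement is deterministic: candidate offsets are evenly
#' spaced from the image edges, so \code{k = 4} on a square image gives the
#' four corner-aligned ROIs and \code{k = 1} the centred one. \code{random}
#' placement is seeded and rejects overlaps while feasible.
#'
#' @param img a \code{\link{grayImage}}.
#' @param roiSize square ROI side in pixels (>= 8).
#' @param k number of ROIs.
#' @param strategy \code{"grid"} or \code{"random"}.
#' @param seed integer seed for random placement.
#' @return list of ROIs, each \code{list(row0, col0, height, width)}
#'   (1-based, fully inside the image).
#' @export
extractROIs <- function(img, roiSize = 64L, k = 4L,
                        strategy = c("grid", "random"), seed = NULL) {
  strategy <- match.arg(strategy)
  nr <- nrow(img); nc <- ncol(img)
  if (roiSize < 8L) stop("'roiSize' must be >= 8")
  if (roiSize > nr || roiSize > nc)
    stop("'roiSize' exceeds the image dimensions")
  roi <- function(r, c) list(row0 = r, col0 = c,
                             height = roiSize, width = roiSize)
  if (strategy == "grid") {
    maxNonOverlap <- floor(nr / roiSize) * floor(nc / roiSize)
    if (k > maxNonOverlap)
      stop(sprintf("k = %d exceeds the %d non-overlapping grid positions",
                   k, maxNonOverlap))
    g <- ceiling(sqrt(k))
    offs <- function(n) {
      if (g == 1L) round((n - roiSize) / 2) + 1L
      else round(seq(1L, n - roiSize + 1L, length.out = g))
    }
    pos <- expand.grid(col0 = offs(nc), row0 = offs(nr))  # row-major
    lapply(seq_len(k), function(i) roi(pos$row0[i], pos$col0[i]))
  } else {
    withSeed(seed, {
      out <- list(); tries <- 0L
      while (length(out) < k && tries < 200L * k) {
        tries <- tries + 1L
        r <- sample.int(nr - roiSize + 1L, 1L)
        c <- sample.int(nc - roiSize + 1L, 1L)
        overlaps <- any(vapply(out, function(o) {
          abs(o$row0 - r) < roiSize && abs(o$col0 - c) < roiSize
        }, TRUE))
        if (!overlaps || tries >= 100L * k)  # give up on non-overlap late
          out[[length(out) + 1L]] <- roi(r, c)
      }
      if (length(out) < k) stop("could not place the requested ROIs")
      out
    })
  }
}

.cropROI <- function(img, roi) {
  lv <- .imgLevels(img)
  grayImage(unclass(img)[roi$row0:(roi$row0 + roi$height - 1L),
                         roi$col0:(roi$col0 + roi$width - 1L),
                         drop = FALSE], levels = lv)
}

#' First-order histogram features
#'
#' Population moments (ddof 0) of the gray-level distribution:
#' mean intensity, standard deviation, skewness (m3 / sigma^3) and excess
#' (Fisher) kurtosis (m4 / sigma^4 - 3). A constant image has skewness and
#' kurtosis 0 by convention.
#'
#' @param img a \code{\link{grayImage}} (or numeric matrix).
#' @return named numeric: mean_intensity, std, skewness, kurtosis.
#' @export
firstOrderFeatures <- function(img) {
  x <- as.numeric(img)
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) {
    sk <- 0; ku <- 0
  } else {
    sk <- mean((x - mu)^3) / s^3
    ku <- mean((x - mu)^4) / s^4 - 3
  }
  c(mean_intensity = mu, std = s, skewness = sk, kurtosis = ku)
}

.ANGLE_OFFSETS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                       `90` = c(-1L, 0L), `135` = c(-1L, -1L))

.quantize <- function(img, levels) {
  G <- .imgLevels(img)
  if (levels < 2L) stop("'levels' must be >= 2")
  q <- floor(unclass(img) * (levels / G))
  q[q > levels - 1L] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of quantized gray levels at the given pixel offset for each
#' direction, symmetrizes each directional count matrix, sums over the
#' requested directions and normalizes to probabilities.
#'
#' @param img a \code{\link{grayImage}}.
#' @param distance pixel offset (default 1).
#' @param angles directions in degrees, subset of \code{c(0, 45, 90, 135)};
#'   all four by default (orientation-averaged).
#' @param levels number of quantized gray levels Gq (default 32 equal-width
#'   bins over the image's gray range).
#' @param symmetric symmetrize counts (default TRUE).
#' @return list of class \code{glcm}: \code{P} (Gq x Gq probability
#'   matrix), \code{levels}, \code{distance}, \code{angles}.
#' @export
computeGLCM <- function(img, distance = 1L, angles = c(0, 45, 90, 135),
                        levels = 32L, symmetric = TRUE) {
  q <- .quantize(img, levels)
  nr <- nrow(q); nc <- ncol(q)
  C <- matrix(0, levels, levels)
  for (a in as.character(angles)) {
    off <- .ANGLE_OFFSETS[[a]]
    if (is.null(off)) stop("unsupported angle: ", a)
    dr <- off[1L] * distance; dc <- off[2L] * distance
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1))
      stop("image smaller than the requested offset")
    i <- q[r1, c1, drop = FALSE]
    j <- q[r1 + dr, c1 + dc, drop = FALSE]
    Ca <- matrix(tabulate(as.vector(i) * levels + as.vector(j) + 1L,
                          nbins = levels * levels),
                 levels, levels, byrow = TRUE)
    if (symmetric) Ca <- Ca + t(Ca)
    C <- C + Ca
  }
  structure(list(P = C / sum(C), levels = levels, distance = distance,
                 angles = angles), class = "glcm")
}

#' Co-occurrence (Haralick-type) features
#'
#' With P the normalized co-occurrence matrix over levels i, j:
#' contrast = sum P (i-j)^2; dissimilarity = sum P |i-j|;
#' ASM = sum P^2; energy = sqrt(ASM); homogeneity = sum P / (1 + (i-j)^2);
#' correlation = sum P (i-mu_i)(j-mu_j) / (sigma_i sigma_j), defined as 1
#' when a marginal variance vanishes (constant image).
#'
#' @param g a \code{glcm} object from \code{\link{computeGLCM}}, or a
#'   normalized co-occurrence probability matrix.
#' @return named numeric: contrast, dissimilarity, energy, homogeneity,
#'   correlation, asm.
#' @export
glcmFeatures <- function(g) {
  P <- if (inherits(g, "glcm")) g$P else as.matrix(g)
  if (abs(sum(P) - 1) > 1e-8) stop("co-occurrence matrix is not normalized")
  n <- nrow(P)
  i <- matrix(0:(n - 1L), n, n)
  j <- t(i)
  d <- i - j
  contrast <- sum(P * d^2)
  dissim <- sum(P * abs(d))
  asm <- sum(P^2)
  energy <- sqrt(asm)
  homog <- sum(P / (1 + d^2))
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mui <- sum((0:(n - 1L)) * pi_); muj <- sum((0:(n - 1L)) * pj_)
  si <- sqrt(sum((0:(n - 1L) - mui)^2 * pi_))
  sj <- sqrt(sum((0:(n - 1L) - muj)^2 * pj_))
  corr <- if (si * sj == 0) 1 else sum(P * (i - mui) * (j - muj)) / (si * sj)
  c(contrast = contrast, dissimilarity = dissim, energy = energy,
    homogeneity = homog, correlation = corr, asm = asm)
}

## Split a matrix into its lines along a run direction.
.runLines <- function(q, angle) {
  nr <- nrow(q); nc <- ncol(q)
  switch(as.character(angle),
    `0` = lapply(seq_len(nr), function(r) q[r, ]),
    `90` = lapply(seq_len(nc), function(c) q[, c]),
    ## column-major order within a diagonal is a consistent traversal
    `45` = unname(split(as.vector(q), as.vector(row(q) + col(q)))),
    `135` = unname(split(as.vector(q), as.vector(col(q) - row(q)))),
    stop("unsupported angle: ", angle))
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal quantized gray level along each requested
#' direction; counts are summed over directions. \code{pixels} records the
#' total pixel count across directions (n_px per direction), so
#' \code{runs / pixels} is the run percentage.
#'
#' @inheritParams computeGLCM
#' @return list of class \code{glrlm}: \code{r} (Gq x Lmax run-count
#'   matrix), \code{runs} (N_r), \code{pixels} (N_p summed over
#'   directions), \code{levels}, \code{angles}.
#' @export
computeGLRLM <- function(img, angles = c(0, 45, 90, 135), levels = 32L) {
  q <- .quantize(img, levels)
  maxLen <- max(nrow(q), ncol(q))
  r <- matrix(0, levels, maxLen)
  for (a in angles) {
    for (line in .runLines(q, a)) {
      rl <- rle(as.integer(line))
      for (k in seq_along(rl$lengths))
        r[rl$values[k] + 1L, rl$lengths[k]] <-
          r[rl$values[k] + 1L, rl$lengths[k]] + 1
    }
  }
  structure(list(r = r, runs = sum(r), pixels = length(q) * length(angles),
                 levels = levels, angles = angles), class = "glrlm")
}

#' Run-length (Galloway) features
#'
#' With r(i, j) the run counts over gray level i and run length j, N_r the
#' total number of runs and N_p the pixel count:
#' SRE = (1/N_r) sum r/j^2; LRE = (1/N_r) sum r j^2;
#' GLN = (1/N_r) sum_i (sum_j r)^2; RLN = (1/N_r) sum_j (sum_i r)^2;
#' RP = N_r / N_p.
#'
#' @param rlm a \code{glrlm} object from \code{\link{computeGLRLM}}.
#' @return named numeric: sre, lre, gln, rln, rp.
#' @export
glrlmFeatures <- function(rlm) {
  r <- rlm$r; Nr <- rlm$runs
  if (Nr < 1) stop("run-length matrix holds no runs")
  j2 <- matrix((seq_len(ncol(r)))^2, nrow(r), ncol(r), byrow = TRUE)
  c(sre = sum(r / j2) / Nr,
    lre = sum(r * j2) / Nr,
    gln = sum(rowSums(r)^2) / Nr,
    rln = sum(colSums(r)^2) / Nr,
    rp = Nr / rlm$pixels)
}

.TEXTURE_FEATURES <- c("mean_intensity", "std", "skewness", "kurtosis",
                       "contrast", "dissimilarity", "energy", "homogeneity",
                       "correlation", "asm", "sre", "lre", "gln", "rln", "rp")

#' Full 15-feature texture profile of an image
#'
#' Computes the four first-order, six co-occurrence and five run-length
#' features, either on the whole image (\code{roiSize = NULL}) or per ROI
#' with the per-image profile taken as the mean over ROIs (the default
#' protocol: four 64 x 64 ROIs on a deterministic grid). First-order
#' statistics use the raw gray values; GLCM/GLRLM use the quantized levels.
#'
#' @param img a \code{\link{grayImage}}.
#' @param roiSize ROI side in pixels, or NULL to profile the whole image.
#' @param k number of ROIs.
#' @param strategy ROI placement, \code{"grid"} (deterministic) or
#'   \code{"random"} (seeded).
#' @param levels quantized gray levels for GLCM/GLRLM (default 32).
#' @param distance co-occurrence offset (default 1).
#' @param angles directions in degrees.
#' @param seed seed for random ROI placement.
#' @return list with \code{perROI} (data.frame, one row per ROI, 15
#'   columns) and \code{mean} (named numeric, the per-image profile).
#' @export
textureProfile <- function(img, roiSize = 64L, k = 4L, strategy = "grid",
                           levels = 32L, distance = 1L,
                           angles = c(0, 45, 90, 135), seed = NULL) {
  rois <- if (is.null(roiSize))
    list(list(row0 = 1L, col0 = 1L, height = nrow(img), width = ncol(img)))
  else extractROIs(img, roiSize, k, strategy, seed)
  per <- lapply(rois, function(ro) {
    sub <- .cropROI(img, ro)
    c(firstOrderFeatures(sub),
      glcmFeatures(computeGLCM(sub, distance, angles, levels)),
      glrlmFeatures(computeGLRLM(sub, angles, levels)))
  })
  perROI <- as.data.frame(do.call(rbind, per))[, .TEXTURE_FEATURES]
  list(perROI = perROI, mean = colMeans(perROI))
}
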