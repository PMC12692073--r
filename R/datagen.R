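## Synthetic replicate tables, spectra and peel-texture images with the
## statistical structure of the study design: six citrus classes, ten
## replicates per class, independent Gaussian noise at the published
## per-feature standard deviations.

.CITRUS_CLASSES <- c("yellow_grapefruit", "red_grapefruit", "lemon",
                     "orange", "clementine", "kumquat")
.BLOCK_ORDER <- c("physico", "spectro", "ftir")

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. Seeds are kept below 2^31 - 1.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

## Deterministic substream seed for (master seed, block index, class index):
## blocks generated independently stay stable when others change.
.subSeed <- function(seed, blockIdx, classIdx) {
  ((as.integer(seed) %% 1000003L) * 1009L + blockIdx * 101L + classIdx) %%
    2147483647L
}

#' Built-in class specifications from the published citrus peel tables
#'
#' Returns the per-class generative specification: the printed mean and
#' standard deviation of every measured feature across the three analytical
#' blocks (3 physicochemical parameters, 4 spectrophotometric assays, 37
#' ATR-FTIR band intensities) for the six citrus classes. FTIR bands printed
#' as absent for a class are encoded with \code{present = FALSE} and
#' \code{mean = sd = 0}: an absent band contributes no absorbance, giving a
#' complete matrix for fusion.
#'
#' @return data.frame with columns \code{class}, \code{block},
#'   \code{feature}, \code{unit}, \code{mean}, \code{sd}, \code{present};
#'   264 rows (6 classes x 44 features).
#' @examples
#' sp <- citrusClassSpecs()
#' subset(sp, class == "orange" & feature == "3300")  # mean 0.789, sd 0.005
#' @export
citrusClassSpecs <- function() {
  path <- system.file("extdata", "citrus_class_specs.csv",
                      package = "peelfusion", mustWork = TRUE)
  sp <- read.csv(path, stringsAsFactors = FALSE)
  sp$class <- factor(sp$class, levels = .CITRUS_CLASSES)
  sp$present <- as.logical(sp$present)
  sp
}

#' Simulate replicate measurement blocks from class specifications
#'
#' Draws \code{nPerClass} replicates per class for every feature
#' independently from Normal(mean, sd) at the specification values, with
#' negative draws clipped to zero by default (concentrations and
#' absorbances are non-negative). Absent features are exactly zero. All
#' blocks share one sample index; one master seed drives deterministic
#' per-(block, class) substreams, so regenerating with the same arguments
#' is byte-identical and blocks are individually stable.
#'
#' @param specs specification data.frame as from
#'   \code{\link{citrusClassSpecs}} (columns class, block, feature, mean,
#'   sd, present). Every class must carry the same feature set per block.
#' @param nPerClass replicates per class (>= 2); default 10, the study's
#'   replication.
#' @param seed master integer seed.
#' @param clipAtZero clip negative draws at 0 (default TRUE).
#' @return a \linkS4class{MultiBlock} with blocks in the order physico,
#'   spectro, ftir (those present in \code{specs}).
#' @export
simulateReplicateBlocks <- function(specs = citrusClassSpecs(),
                                    nPerClass = 10L, seed = 1L,
                                    clipAtZero = TRUE) {
  if (nPerClass < 2L) stop("'nPerClass' must be >= 2")
  if (any(specs$sd < 0)) stop("spec sd values must be >= 0")
  classes <- if (is.factor(specs$class)) levels(droplevels(specs$class))
             else unique(specs$class)
  blockIdsHere <- intersect(.BLOCK_ORDER, unique(specs$block))
  blockIdsHere <- c(blockIdsHere, setdiff(unique(specs$block), blockIdsHere))

  sampleId <- sprintf("%s_%02d", rep(classes, each = nPerClass),
                      rep(seq_len(nPerClass), times = length(classes)))
  labels <- factor(rep(classes, each = nPerClass), levels = classes)

  blocks <- lapply(seq_along(blockIdsHere), function(bi) {
    bid <- blockIdsHere[bi]
    sub <- specs[specs$block == bid, , drop = FALSE]
    feats <- unique(sub$feature)
    # alignment check: identical feature set for every class
    for (cl in classes) {
      fcl <- sub$feature[sub$class == cl]
      if (!identical(sort(fcl), sort(feats)) || anyDuplicated(fcl))
        stop(sprintf(
          "alignment error: class '%s' does not cover the '%s' feature set",
          cl, bid))
    }
    rows <- lapply(seq_along(classes), function(ci) {
      cl <- classes[ci]
      scl <- sub[sub$class == cl, , drop = FALSE]
      scl <- scl[match(feats, scl$feature), , drop = FALSE]
      m <- withSeed(.subSeed(seed, bi, ci), {
        matrix(rnorm(nPerClass * length(feats),
                     mean = rep(scl$mean, each = nPerClass),
                     sd = rep(scl$sd, each = nPerClass)),
               nrow = nPerClass)
      })
      m[, !scl$present] <- 0
      m
    })
    vals <- do.call(rbind, rows)
    if (clipAtZero) vals <- pmax(vals, 0)
    dimnames(vals) <- list(sampleId, feats)
    units <- sub$unit[match(feats, sub$feature)]
    FeatureBlock(vals, blockId = bid, classes = labels,
                 sampleIds = sampleId, units = units)
  })
  MultiBlock(blocks)
}

#' Simulate an ATR-FTIR-like absorbance trace from band amplitudes
#'
#' Builds a spectrum as a sum of Gaussian peaks centred at the given
#' wavenumbers, plus i.i.d. Gaussian noise, on a descending wavenumber
#' grid covering the instrument range 4000-499 cm-1.
#'
#' @param bandMeans named numeric: names are peak-centre wavenumbers
#'   (cm-1), values peak absorbance amplitudes. May be empty.
#' @param peakWidth Gaussian sigma in cm-1 (> 0). Default 3.5, narrow
#'   enough that the two closest catalogued bands (18 cm-1 apart) do not
#'   leak into each other's picking windows.
#' @param noiseSd i.i.d. noise standard deviation (absorbance units).
#' @param grid descending wavenumber grid; default 4000 to 499 cm-1 in
#'   0.5 cm-1 steps.
#' @param seed integer seed (only used when \code{noiseSd > 0}).
#' @return data.frame with columns \code{wavenumber}, \code{absorbance},
#'   wavenumbers descending.
#' @examples
#' s <- simulateSpectrum(c("1600" = 0.25), noiseSd = 0)
#' s$absorbance[s$wavenumber == 1600]  # 0.25
#' @export
simulateSpectrum <- function(bandMeans, peakWidth = 3.5, noiseSd = 0,
                             grid = seq(4000, 499, by = -0.5), seed = NULL) {
  if (peakWidth <= 0) stop("'peakWidth' must be > 0")
  if (length(grid) < 2L || is.unsorted(rev(grid)))
    stop("'grid' must be a descending wavenumber vector")
  centers <- as.numeric(names(bandMeans))
  if (length(bandMeans) && (anyNA(centers) ||
      any(centers > max(grid) | centers < min(grid))))
    stop("band center outside the wavenumber grid")
  a <- numeric(length(grid))
  for (i in seq_along(bandMeans))
    a <- a + bandMeans[[i]] * exp(-(grid - centers[i])^2 / (2 * peakWidth^2))
  if (noiseSd > 0)
    a <- a + withSeed(seed, rnorm(length(grid), 0, noiseSd))
  data.frame(wavenumber = grid, absorbance = unname(a))
}

#' Per-class spectra simulated from the built-in FTIR band table
#'
#' Convenience wrapper turning one class's catalogued band means (plus
#' optional per-band Gaussian perturbation at the printed SDs) into a full
#' synthetic trace via \code{\link{simulateSpectrum}}.
#'
#' @param class one of the six citrus class labels.
#' @param specs specification table (\code{\link{citrusClassSpecs}}).
#' @param sampleNoise if TRUE perturb each band amplitude by its printed
#'   SD before synthesis; if FALSE use the printed means exactly.
#' @param noiseSd additive trace noise passed to simulateSpectrum.
#' @param seed integer seed.
#' @param ... further arguments to \code{\link{simulateSpectrum}}.
#' @return data.frame spectrum.
#' @export
simulateClassSpectrum <- function(class, specs = citrusClassSpecs(),
                                  sampleNoise = FALSE, noiseSd = 0,
                                  seed = NULL, ...) {
  sub <- specs[specs$block == "ftir" & specs$class == class &
                 specs$present, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("unknown class '%s'", class))
  bands <- citrusBands()
  ctr <- (bands$low + bands$high) / 2
  names(ctr) <- bands$label
  amp <- sub$mean
  if (sampleNoise)
    amp <- pmax(0, withSeed(seed, rnorm(length(amp), amp, sub$sd)))
  bm <- stats::setNames(amp, as.character(ctr[sub$feature]))
  simulateSpectrum(bm, noiseSd = noiseSd, seed = if (is.null(seed)) NULL
                   else seed + 1L, ...)
}

#' Synthetic grayscale peel image with controllable texture uniformity
#'
#' Emulates the appearance regimes seen across citrus peels: a flat base
#' gray field plus pixel noise and dark elliptical blotches. Uniform
#' classes correspond to low noise and low blotch density; mottled classes
#' to high values.
#'
#' @param baseIntensity base gray level in \code{[0, levels-1]}.
#' @param noiseSd per-pixel Gaussian noise SD in gray levels.
#' @param blotchDensity expected blotches per 10^4 pixels (>= 0).
#' @param blotchScale typical blotch semi-axis in pixels.
#' @param size image (rows, cols), each >= 64.
#' @param levels number of gray levels G (pixels in \code{[0, G-1]}).
#' @param seed integer seed; identical arguments and seed give identical
#'   pixel arrays.
#' @return integer matrix of class \code{grayImage} (attribute
#'   \code{levels}).
#' @export
simulateTextureImage <- function(baseIntensity = 140, noiseSd = 10,
                                 blotchDensity = 10, blotchScale = 5,
                                 size = c(256L, 256L), levels = 256L,
                                 seed = NULL) {
  if (any(size < 64L)) stop("'size' must be at least 64 x 64")
  if (baseIntensity < 0 || baseIntensity > levels - 1L)
    stop("'baseIntensity' outside gray range")
  if (noiseSd < 0 || blotchDensity < 0)
    stop("'noiseSd' and 'blotchDensity' must be >= 0")
  nr <- size[1L]; nc <- size[2L]
  img <- withSeed(seed, {
    m <- matrix(baseIntensity, nr, nc)
    if (noiseSd > 0)
      m <- m + matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
    nBlotch <- round(blotchDensity * nr * nc / 1e4)
    if (nBlotch > 0) {
      for (b in seq_len(nBlotch)) {
        cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
        ay <- blotchScale * runif(1, 0.5, 1.5)
        ax <- blotchScale * runif(1, 0.5, 1.5)
        th <- runif(1, 0, pi)
        depth <- runif(1, 25, 70)
        r0 <- max(1L, floor(cy - 2 * max(ay, ax)))
        r1 <- min(nr, ceiling(cy + 2 * max(ay, ax)))
        c0 <- max(1L, floor(cx - 2 * max(ay, ax)))
        c1 <- min(nc, ceiling(cx + 2 * max(ay, ax)))
        rr <- r0:r1; cc <- c0:c1
        dy <- outer(rr - cy, rep(1, length(cc)))
        dx <- outer(rep(1, length(rr)), cc - cx)
        u <- (dy * cos(th) + dx * sin(th)) / ay
        v <- (-dy * sin(th) + dx * cos(th)) / ax
        inside <- u^2 + v^2 <= 1
        m[rr, cc][inside] <- m[rr, cc][inside] - depth
      }
    }
    m
  })
  img <- round(pmin(pmax(img, 0), levels - 1L))
  grayImage(img, levels = levels)
}

#' Image-generator settings for the two texture regimes
#'
#' Parameter sets for \code{\link{simulateTextureImage}} reproducing the
#' qualitative uniformity contrast among the peels: a smooth, lightly
#' blemished surface (as in lemon / yellow grapefruit) versus a mottled,
#' blotchy one (as in clementine / red grapefruit), with an intermediate
#' setting for orange / kumquat.
#'
#' @return named list of argument lists.
#' @export
peelImageSpecs <- function() {
  list(
    uniform = list(baseIntensity = 150, noiseSd = 6, blotchDensity = 2,
                   blotchScale = 4, size = c(256L, 256L)),
    intermediate = list(baseIntensity = 142, noiseSd = 10,
                        blotchDensity = 15, blotchScale = 5,
                        size = c(256L, 256L)),
    mottled = list(baseIntensity = 135, noiseSd = 14, blotchDensity = 40,
                   blotchScale = 7, size = c(256L, 256L))
  )
}

#' Map each citrus class to its texture regime
#'
#' @return named character: class -> one of "uniform", "intermediate",
#'   "mottled".
#' @export
citrusImageRegimes <- function() {
  c(yellow_grapefruit = "uniform", lemon = "uniform",
    orange = "intermediate", kumquat = "intermediate",
    red_grapefruit = "mottled", clementine = "mottled")
}
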