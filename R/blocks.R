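## Shared preprocessing: dry-weight conversion, auto-scaling, alignment,
## horizontal concatenation.

#' Convert an as-measured value to a dry-weight basis
#'
#' Assay results obtained on freeze-dried material still contain a small
#' residual moisture fraction; expressing them per gram of true dry matter
#' divides by the dry fraction.
#'
#' @param value amount per g of freeze-dried sample (vectorised).
#' @param residualMoisture residual moisture fraction of the freeze-dried
#'   sample, in \code{[0, 1)}. This is the residual moisture measured after
#'   lyophilisation, not the fresh-peel moisture (which is an analyte in the
#'   physicochemical block).
#' @return value per g dry weight: \code{value / (1 - residualMoisture)}.
#' @examples
#' dwConvert(100, 0.05)  # 105.2632
#' @export
dwConvert <- function(value, residualMoisture) {
  if (any(residualMoisture < 0 | residualMoisture >= 1))
    stop("'residualMoisture' must be a fraction in [0, 1)")
  value / (1 - residualMoisture)
}

.popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Auto-scale a FeatureBlock
#'
#' Mean-centres every feature and divides by its population standard
#' deviation (ddof 0, the convention of the usual chemometric standard
#' scaler), so all features contribute equally to downstream models
#' regardless of unit or magnitude. The fitted centre/scale are stored in
#' the returned \linkS4class{ScaledBlock} so new data can be transformed
#' identically (\code{\link{scaleApply}}) and raw values recovered
#' (\code{\link{scaleInvert}}).
#'
#' @param x a \linkS4class{FeatureBlock} (a \code{ScaledBlock} is rescaled
#'   from its current values, which is a no-op on the fitting set), or a
#'   plain numeric matrix (samples x features).
#' @param ... unused.
#' @return a \linkS4class{ScaledBlock}, or for matrix input a matrix with
#'   \code{"center"}/\code{"scale"} attributes.
#' @rdname autoscale
#' @aliases autoscale
#' @export
setMethod("autoscale", "FeatureBlock", function(x, ...) {
  m <- measurements(x)
  sc <- .autoscaleMatrix(m)
  ctr <- attr(sc, "center"); scl <- attr(sc, "scale")
  attr(sc, "center") <- NULL; attr(sc, "scale") <- NULL
  fb <- FeatureBlock(sc, blockId = blockId(x),
                     classes = classLabels(x), sampleIds = sampleIds(x),
                     units = featureUnits(x))
  new("ScaledBlock", fb, center = ctr, scale = scl)
})

#' @rdname autoscale
#' @export
setMethod("autoscale", "matrix", function(x, ...) .autoscaleMatrix(x))

#' @rdname autoscale
#' @export
setMethod("autoscale", "MultiBlock", function(x, ...) {
  MultiBlock(lapply(as.list(x@blocks), autoscale))
})

.autoscaleMatrix <- function(m) {
  ctr <- colMeans(m)
  scl <- apply(m, 2L, .popSd)
  bad <- scl <= 0
  if (any(bad))
    stop("zero-variance feature(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  out <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Apply stored auto-scaling parameters to new data
#'
#' @param scaled a \linkS4class{ScaledBlock} or a matrix returned by
#'   \code{autoscale()}.
#' @param newValues samples x features matrix with the same features.
#' @return scaled matrix \code{(newValues - center) / scale}.
#' @export
scaleApply <- function(scaled, newValues) {
  prm <- .scaleParams(scaled)
  if (ncol(newValues) != length(prm$center))
    stop("feature count mismatch")
  sweep(sweep(as.matrix(newValues), 2L, prm$center), 2L, prm$scale, "/")
}

#' Invert auto-scaling, recovering raw values
#'
#' @param scaled a \linkS4class{ScaledBlock} or a matrix returned by
#'   \code{autoscale()}.
#' @param values scaled matrix to invert; defaults to the stored values.
#' @return raw-scale matrix.
#' @export
scaleInvert <- function(scaled, values = NULL) {
  prm <- .scaleParams(scaled)
  if (is.null(values)) {
    values <- if (is(scaled, "ScaledBlock")) measurements(scaled)
              else scaled
  }
  sweep(sweep(as.matrix(values), 2L, prm$scale, "*"), 2L, prm$center, "+")
}

.scaleParams <- function(scaled) {
  if (is(scaled, "ScaledBlock"))
    list(center = scaleCenter(scaled), scale = scaleSd(scaled))
  else if (is.matrix(scaled) && !is.null(attr(scaled, "center")))
    list(center = attr(scaled, "center"), scale = attr(scaled, "scale"))
  else stop("no stored scaling parameters found")
}

#' Check the sample alignment of a MultiBlock-like list of blocks
#'
#' The fusion contract requires identical sample ids and class labels, in
#' identical order, across blocks. This reports violations rather than
#' erroring, so misassembled inputs can be diagnosed.
#'
#' @param blocks a \linkS4class{MultiBlock} or list of
#'   \linkS4class{FeatureBlock}s.
#' @return list with \code{pass} (logical) and \code{violations}
#'   (character, one message per offending block).
#' @export
validateAlignment <- function(blocks) {
  if (is(blocks, "MultiBlock")) blocks <- as.list(blocks@blocks)
  stopifnot(length(blocks) >= 1L)
  ref <- blocks[[1L]]
  violations <- character()
  for (i in seq_along(blocks)[-1L]) {
    b <- blocks[[i]]
    if (!identical(sampleIds(b), sampleIds(ref)))
      violations <- c(violations, sprintf(
        "block '%s': sample ids differ from block '%s' (order matters)",
        blockId(b), blockId(ref)))
    else if (!identical(as.character(classLabels(b)),
                        as.character(classLabels(ref))))
      violations <- c(violations, sprintf(
        "block '%s': class labels differ from block '%s'",
        blockId(b), blockId(ref)))
  }
  list(pass = length(violations) == 0L, violations = violations)
}

#' Horizontally concatenate blocks into a single fused FeatureBlock
#'
#' Joins the selected member blocks column-wise, preserving row (sample)
#' order and prefixing every feature name with its block of origin
#' (\code{"blockid::feature"}) so that, e.g., a texture \code{correlation}
#' cannot collide with another block's feature of the same name. For the
#' fusion models the members should be auto-scaled first (see
#' \code{\link{autoscale}}); concatenation itself is agnostic.
#'
#' @param mb a \linkS4class{MultiBlock}.
#' @param which block ids to include, in the order given; defaults to all.
#' @return a \linkS4class{FeatureBlock} with \code{blockId = "fused"}.
#' @export
concatenateBlocks <- function(mb, which = blockIds(mb)) {
  stopifnot(is(mb, "MultiBlock"))
  unknown <- setdiff(which, blockIds(mb))
  if (length(unknown))
    stop("unknown block id(s): ", paste(unknown, collapse = ", "))
  al <- validateAlignment(mb)
  if (!al$pass) stop("blocks are misaligned: ", al$violations[1L])
  parts <- lapply(which, function(id) {
    b <- getBlock(mb, id)
    m <- measurements(b)
    colnames(m) <- paste0(blockId(b), "::", colnames(m))
    m
  })
  fused <- do.call(cbind, parts)
  ref <- getBlock(mb, which[1L])
  FeatureBlock(fused, blockId = "fused",
               classes = classLabels(ref), sampleIds = sampleIds(ref))
}

#' Slice a fused matrix back into one origin block's columns
#'
#' @param fused a fused \linkS4class{FeatureBlock} (or its matrix).
#' @param id origin block id whose columns to extract.
#' @return samples x features matrix with the prefix stripped.
#' @export
sliceBlock <- function(fused, id) {
  m <- if (is(fused, "FeatureBlock")) measurements(fused) else as.matrix(fused)
  pick <- startsWith(colnames(m), paste0(id, "::"))
  if (!any(pick)) stop(sprintf("no columns from block '%s'", id))
  out <- m[, pick, drop = FALSE]
  colnames(out) <- sub("^[^:]+::", "", colnames(out))
  out
}

#' Write per-block wide CSV matrices and a tidy long table
#'
#' @param mb a \linkS4class{MultiBlock}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeBlockCSV <- function(mb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (id in blockIds(mb)) {
    b <- getBlock(mb, id)
    m <- data.frame(sample_id = sampleIds(b),
                    class = as.character(classLabels(b)),
                    measurements(b), check.names = FALSE)
    p <- file.path(dir, sprintf("block_%s.csv", id))
    write.csv(m, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "tidy_values.csv")
  write.csv(as.data.frame(mb), p, row.names = FALSE)
  invisible(c(paths, p))
}
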