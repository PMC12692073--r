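#' FeatureBlock: one analytical matrix with aligned class labels
#'
#' A \code{FeatureBlock} is the unit of multi-block fusion: a samples x
#' features measurement matrix from one analytical domain (ATR-FTIR band
#' intensities, spectrophotometric assays, physicochemical parameters or
#' image texture features), carried as a \linkS4class{SummarizedExperiment}
#' (features in rows, samples in columns) with the block identity and the
#' citrus class of every sample attached.
#'
#' The canonical block identifiers are \code{"ftir"}, \code{"spectro"},
#' \code{"physico"} and \code{"texture"}; horizontally fused blocks use
#' \code{"fused"}. Cells must be complete (no \code{NA}) and feature names
#' unique within a block.
#'
#' @slot blockId single string identifying the analytical block.
#'
#' @seealso \code{\link{FeatureBlock}} (constructor),
#'   \linkS4class{MultiBlock}, \code{\link{autoscale}}
#' @export
setClass("FeatureBlock",
  contains = "SummarizedExperiment",
  slots = c(blockId = "character"))

setValidity("FeatureBlock", function(object) {
  msg <- character()
  if (length(object@blockId) != 1L || !nzchar(object@blockId))
    msg <- c(msg, "'blockId' must be a single non-empty string")
  if (!"class" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'class' column")
  a <- SummarizedExperiment::assay(object)
  if (anyNA(a))
    msg <- c(msg, "measurement matrix contains missing cells")
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "feature names must be present and unique within a block")
  if (is.null(colnames(object)))
    msg <- c(msg, "sample ids must be present")
  if (length(msg)) msg else TRUE
})

#' ScaledBlock: an auto-scaled FeatureBlock with stored parameters
#'
#' Result of \code{\link{autoscale}}: each feature mean-centred and divided
#' by its population standard deviation, with the per-feature centre and
#' scale retained so that new data can be transformed identically and the
#' raw values recovered exactly.
#'
#' @slot center named numeric, per-feature means on the fitting set.
#' @slot scale named numeric, per-feature population standard deviations.
#' @export
setClass("ScaledBlock",
  contains = "FeatureBlock",
  slots = c(center = "numeric", scale = "numeric"))

setValidity("ScaledBlock", function(object) {
  msg <- character()
  p <- nrow(object)
  if (length(object@center) != p || length(object@scale) != p)
    msg <- c(msg, "'center' and 'scale' must have one entry per feature")
  if (any(object@scale <= 0))
    msg <- c(msg, "all scale values must be positive")
  if (length(msg)) msg else TRUE
})

#' MultiBlock: aligned FeatureBlocks over one sample set
#'
#' An ordered collection of \linkS4class{FeatureBlock} objects measured on
#' the same samples. Validity enforces the alignment contract of the fusion
#' design: identical sample ids and identical class labels, in the same
#' order, across every block.
#'
#' @slot blocks a \link[S4Vectors]{SimpleList} of \code{FeatureBlock}s,
#'   named by their block ids.
#' @export
setClass("MultiBlock", slots = c(blocks = "SimpleList"))

setValidity("MultiBlock", function(object) {
  b <- object@blocks
  if (length(b) == 0L) return("at least one block is required")
  if (!all(vapply(b, is, TRUE, "FeatureBlock")))
    return("all elements must be FeatureBlock objects")
  ids <- vapply(b, blockId, "")
  if (anyDuplicated(ids)) return("block ids must be unique")
  if (!identical(names(b), unname(ids)))
    return("list names must equal the block ids")
  ref <- b[[1L]]
  for (i in seq_along(b)[-1L]) {
    if (!identical(colnames(b[[i]]), colnames(ref)))
      return(sprintf("block '%s' has different sample ids/order", ids[i]))
    if (!identical(as.character(classLabels(b[[i]])),
                   as.character(classLabels(ref))))
      return(sprintf("block '%s' has different class labels", ids[i]))
  }
  TRUE
})

#' Construct a FeatureBlock
#'
#' @param values numeric matrix, samples in rows and features in columns
#'   (the orientation measurement tables are usually recorded in; it is
#'   transposed into the features-in-rows SummarizedExperiment layout).
#' @param blockId single string, e.g. \code{"ftir"}.
#' @param classes factor or character of per-sample class labels.
#' @param sampleIds sample identifiers; defaults to \code{rownames(values)}.
#' @param units optional per-feature unit strings.
#' @return a \linkS4class{FeatureBlock}.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("s", 1:4), c("tpc", "tfc", "frap")))
#' fb <- FeatureBlock(m, "spectro", rep(c("lemon", "orange"), 2))
#' measurements(fb)
#' @export
FeatureBlock <- function(values, blockId, classes,
                         sampleIds = rownames(values), units = NULL) {
  values <- as.matrix(values)
  if (is.null(sampleIds))
    sampleIds <- sprintf("sample_%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%d", seq_len(ncol(values)))
  if (length(classes) != nrow(values))
    stop("'classes' must have one label per sample (row of 'values')")
  if (!is.factor(classes)) classes <- factor(classes)
  rd <- S4Vectors::DataFrame(feature = colnames(values))
  if (!is.null(units)) rd$unit <- units
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(values = t(values)),
    colData = S4Vectors::DataFrame(class = classes, row.names = sampleIds),
    rowData = rd)
  new("FeatureBlock", se, blockId = blockId)
}

#' Construct a MultiBlock from FeatureBlocks
#'
#' @param ... \linkS4class{FeatureBlock} objects (or a single list of them),
#'   all measured on the same samples in the same order.
#' @return a \linkS4class{MultiBlock} named by block ids.
#' @export
MultiBlock <- function(...) {
  b <- list(...)
  if (length(b) == 1L && is.list(b[[1L]]) && !is(b[[1L]], "FeatureBlock"))
    b <- b[[1L]]
  names(b) <- vapply(b, blockId, "")
  new("MultiBlock", blocks = S4Vectors::SimpleList(b))
}

## ---- accessors ------------------------------------------------------------

#' @describeIn FeatureBlock block identity string.
#' @param x a FeatureBlock.
#' @export
setMethod("blockId", "FeatureBlock", function(x) x@blockId)

#' @describeIn FeatureBlock samples x features measurement matrix.
#' @export
setMethod("measurements", "FeatureBlock",
          function(x, ...) t(SummarizedExperiment::assay(x, "values")))

#' @describeIn FeatureBlock per-sample class labels (factor).
#' @export
setMethod("classLabels", "FeatureBlock",
          function(x) SummarizedExperiment::colData(x)$class)

#' @describeIn FeatureBlock sample identifiers.
#' @export
setMethod("sampleIds", "FeatureBlock", function(x) colnames(x))

#' @describeIn FeatureBlock feature names.
#' @export
setMethod("featureNames", "FeatureBlock", function(x) rownames(x))

#' @describeIn FeatureBlock per-feature unit strings (NA when unset).
#' @export
setMethod("featureUnits", "FeatureBlock", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("unit" %in% colnames(rd)) as.character(rd$unit)
  else rep(NA_character_, nrow(x))
})

#' @describeIn FeatureBlock number of samples.
#' @export
setMethod("nSamples", "FeatureBlock", function(x) ncol(x))

setMethod("show", "FeatureBlock", function(object) {
  cat(sprintf("FeatureBlock '%s': %d samples x %d features\n",
              blockId(object), ncol(object), nrow(object)))
  cat("classes:",
      paste(sprintf("%s(%d)", levels(classLabels(object)),
                    table(classLabels(object))), collapse = " "), "\n")
  fn <- featureNames(object)
  cat("features:", paste(head(fn, 6), collapse = ", "),
      if (length(fn) > 6) "...", "\n")
})

#' @describeIn ScaledBlock per-feature centring means.
#' @param x a ScaledBlock.
#' @export
setMethod("scaleCenter", "ScaledBlock", function(x) x@center)

#' @describeIn ScaledBlock per-feature population standard deviations.
#' @export
setMethod("scaleSd", "ScaledBlock", function(x) x@scale)

#' @describeIn MultiBlock ids of the member blocks.
#' @param x a MultiBlock.
#' @export
setMethod("blockIds", "MultiBlock", function(x) names(x@blocks))

#' @describeIn MultiBlock extract one member block by id.
#' @param id block id string.
#' @export
setMethod("getBlock", "MultiBlock", function(x, id) {
  if (!id %in% names(x@blocks))
    stop(sprintf("unknown block id '%s' (have: %s)", id,
                 paste(names(x@blocks), collapse = ", ")))
  x@blocks[[id]]
})

#' @describeIn MultiBlock number of (shared) samples.
#' @export
setMethod("nSamples", "MultiBlock", function(x) ncol(x@blocks[[1L]]))

#' @describeIn MultiBlock shared class labels.
#' @export
setMethod("classLabels", "MultiBlock",
          function(x) classLabels(x@blocks[[1L]]))

#' @describeIn MultiBlock shared sample ids.
#' @export
setMethod("sampleIds", "MultiBlock", function(x) colnames(x@blocks[[1L]]))

setMethod("show", "MultiBlock", function(object) {
  cat(sprintf("MultiBlock: %d blocks, %d samples\n",
              length(object@blocks), nSamples(object)))
  for (b in as.list(object@blocks))
    cat(sprintf("  %-8s %d features\n", blockId(b), nrow(b)))
})

#' Tidy long-format view of a MultiBlock
#'
#' @param x a MultiBlock.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns sample_id, class, block, feature, value.
#' @export
as.data.frame.MultiBlock <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  out <- lapply(as.list(x@blocks), function(b) {
    m <- measurements(b)
    data.frame(
      sample_id = rep(rownames(m), times = ncol(m)),
      class = rep(as.character(classLabels(b)), times = ncol(m)),
      block = blockId(b),
      feature = rep(colnames(m), each = nrow(m)),
      value = as.vector(m),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
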