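## Pearson correlation machinery: replicate- and class-mean-mode matrices,
## cross-block top pairs, thresholded networks with spring layout.

#' Pearson correlation matrix over features
#'
#' \code{replicate} mode correlates features over all samples;
#' \code{class_mean} mode first averages replicates within class and
#' correlates over the class means (the mode that reproduces the published
#' assay correlation table, whose printed values match Pearson over the
#' six class means rather than over replicates).
#'
#' @param x samples x features matrix, \linkS4class{FeatureBlock} or
#'   \linkS4class{MultiBlock} (blocks concatenated with
#'   \code{"blockid::"} prefixes).
#' @param mode \code{"replicate"} (default) or \code{"class_mean"}.
#' @param classes class labels, required for \code{class_mean} mode when
#'   \code{x} is a plain matrix.
#' @return correlation matrix with attribute \code{mode}.
#' @export
pearsonMatrix <- function(x, mode = c("replicate", "class_mean"),
                          classes = NULL) {
  mode <- match.arg(mode)
  if (is(x, "MultiBlock")) {
    classes <- classLabels(x)
    x <- measurements(concatenateBlocks(x))
  } else if (is(x, "FeatureBlock")) {
    classes <- classLabels(x)
    x <- measurements(x)
  }
  x <- as.matrix(x)
  if (mode == "class_mean") {
    if (is.null(classes)) stop("'classes' required for class_mean mode")
    classes <- factor(classes)
    x <- rowsum(x, classes) / as.vector(table(classes))
  }
  if (nrow(x) < 3L)
    stop("need at least 3 effective rows to correlate")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  attr(r, "mode") <- mode
  r
}

#' Top cross-block feature pairs by absolute correlation
#'
#' Correlates every feature of block A with every feature of block B over
#' the shared samples and returns the k pairs with the largest |r|
#' (ties broken lexicographically by feature names for determinism).
#'
#' @param A,B aligned \linkS4class{FeatureBlock}s or samples x features
#'   matrices with identical row order.
#' @param k number of pairs to return (default 5); capped at the number
#'   of pairs.
#' @return data.frame: featureA, featureB, r, ranked by |r| descending.
#' @export
crossBlockTopPairs <- function(A, B, k = 5L) {
  nmA <- NULL; nmB <- NULL
  if (is(A, "FeatureBlock")) { nmA <- sampleIds(A); A <- measurements(A) }
  if (is(B, "FeatureBlock")) { nmB <- sampleIds(B); B <- measurements(B) }
  if (nrow(A) != nrow(B) ||
      (!is.null(nmA) && !is.null(nmB) && !identical(nmA, nmB)))
    stop("blocks are misaligned")
  r <- stats::cor(as.matrix(A), as.matrix(B))
  pairs <- expand.grid(featureA = rownames(r), featureB = colnames(r),
                       stringsAsFactors = FALSE)
  pairs$r <- as.vector(r)
  ord <- order(-abs(pairs$r), pairs$featureA, pairs$featureB)
  out <- pairs[ord, , drop = FALSE][seq_len(min(k, nrow(pairs))), ]
  rownames(out) <- NULL
  out
}

#' Thresholded correlation network over the fused feature set
#'
#' Nodes are all features, tagged with their block of origin (parsed from
#' the \code{"blockid::feature"} name prefix); edges connect pairs with
#' \code{|r| >= edgeThreshold}, flagged bold at
#' \code{|r| >= boldThreshold}. Isolated nodes are retained.
#'
#' @param C square replicate-mode correlation matrix (from
#'   \code{\link{pearsonMatrix}} on a fused block).
#' @param edgeThreshold minimum |r| for an edge (default 0.60).
#' @param boldThreshold |r| for the bold flag (default 0.80); must be >=
#'   \code{edgeThreshold}. Both must lie in (0, 1].
#' @return list of class \code{correlationNetwork}: \code{nodes}
#'   (data.frame name, block, label — the label is the display name with
#'   the block prefix stripped) and \code{edges} (data.frame from, to, r,
#'   bold).
#' @export
buildNetwork <- function(C, edgeThreshold = 0.60, boldThreshold = 0.80) {
  if (edgeThreshold <= 0 || edgeThreshold > 1 ||
      boldThreshold <= 0 || boldThreshold > 1)
    stop("thresholds must lie in (0, 1]")
  if (boldThreshold < edgeThreshold)
    stop("'boldThreshold' must be >= 'edgeThreshold'")
  C <- as.matrix(C)
  nm <- rownames(C)
  blockOf <- ifelse(grepl("::", nm, fixed = TRUE),
                    sub("::.*$", "", nm), NA_character_)
  nodes <- data.frame(name = nm, block = blockOf,
                      label = sub("^[^:]*::", "", nm),
                      stringsAsFactors = FALSE)
  up <- which(upper.tri(C) & abs(C) >= edgeThreshold, arr.ind = TRUE)
  edges <- data.frame(from = nm[up[, 1L]], to = nm[up[, 2L]],
                      r = C[up], bold = abs(C[up]) >= boldThreshold,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 edgeThreshold = edgeThreshold,
                 boldThreshold = boldThreshold),
            class = "correlationNetwork")
}

#' @export
print.correlationNetwork <- function(x, ...) {
  cat(sprintf(
    "correlation network: %d nodes, %d edges (|r| >= %.2f), %d bold (|r| >= %.2f)\n",
    nrow(x$nodes), nrow(x$edges), x$edgeThreshold,
    sum(x$edges$bold), x$boldThreshold))
  invisible(x)
}

#' Convert a correlation network to an igraph graph
#'
#' @param net a \code{correlationNetwork}.
#' @return igraph object with vertex attributes \code{block}, \code{label}
#'   and edge attributes \code{r}, \code{bold}, \code{weight} (= |r|).
#' @export
asIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  if (nrow(net$edges))
    igraph::E(g)$weight <- abs(net$edges$r)
  g
}

#' Fruchterman-Reingold spring layout for a correlation network
#'
#' Deterministic for a given seed; a single node is placed at the origin.
#'
#' @param net a \code{correlationNetwork}.
#' @param seed integer seed.
#' @param niter iterations of the spring algorithm.
#' @return data.frame: name, x, y.
#' @export
springLayout <- function(net, seed = 1L, niter = 500L) {
  if (nrow(net$nodes) == 0L) stop("network has no nodes")
  if (nrow(net$nodes) == 1L)
    return(data.frame(name = net$nodes$name, x = 0, y = 0,
                      stringsAsFactors = FALSE))
  g <- asIgraph(net)
  xy <- withSeed(seed, igraph::layout_with_fr(g, niter = niter))
  data.frame(name = net$nodes$name, x = xy[, 1L], y = xy[, 2L],
             stringsAsFactors = FALSE)
}

#' Write a correlation network to GraphML and edge-list CSV
#'
#' @param net a \code{correlationNetwork}.
#' @param graphml path for the GraphML file (NULL to skip).
#' @param edgeCsv path for the edge-list CSV (source, target, r, bold;
#'   NULL to skip).
#' @return invisibly, the paths written.
#' @export
writeNetwork <- function(net, graphml = NULL, edgeCsv = NULL) {
  written <- character()
  if (!is.null(graphml)) {
    igraph::write_graph(asIgraph(net), graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(edgeCsv)) {
    e <- net$edges
    names(e)[1:2] <- c("source", "target")
    utils::write.csv(e, edgeCsv, row.names = FALSE)
    written <- c(written, edgeCsv)
  }
  invisible(written)
}
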