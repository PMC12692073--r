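## Non-parametric class comparison reproducing the superscript-letter
## structure of the summary tables: Kruskal-Wallis across the six classes,
## Dunn pairwise z-tests on pooled ranks with Holm adjustment, and a
## compact letter display at alpha = 0.05.

#' Kruskal-Wallis test across groups
#'
#' Thin wrapper over \code{stats::kruskal.test} (tie-corrected H, p from a
#' chi-square with k - 1 df) taking a list of group value vectors.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return list of class \code{kwResult}: \code{H}, \code{df}, \code{p}.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))$H  # 3.8571
#' @export
kruskalWallis <- function(groups) {
  .checkGroups(groups)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    stop("all pooled values are identical; H is undefined")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value), class = "kwResult")
}

.checkGroups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least 2 groups")
  if (any(lengths(groups) < 2L))
    stop("every group needs at least 2 values")
}

#' Dunn post hoc pairwise comparisons
#'
#' Dunn z-statistics on the pooled ranks with the standard tie correction:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)), with
#' T = sum(t^3 - t) / (12 (N - 1)) over tie groups. Two-sided p-values are
#' adjusted across all pairs; the default Benjamini-Hochberg adjustment is
#' the usual companion of Dunn's test and retains enough power at ten
#' replicates per class to resolve the letter structures typical of
#' published assay tables, where the stricter Holm correction does not.
#'
#' @param groups named list of numeric group vectors (names become class
#'   labels; defaults to G1, G2, ...).
#' @param adjust p-adjustment method passed to \code{stats::p.adjust};
#'   default \code{"BH"} (use \code{"holm"} for family-wise control).
#' @return symmetric matrix of adjusted pairwise p-values with unit
#'   diagonal, class \code{posthocMatrix}, attribute \code{adjust}.
#' @export
dunnPosthoc <- function(groups, adjust = "BH") {
  .checkGroups(groups)
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- sprintf("G%d", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    stop("all pooled values are identical; ranks are degenerate")
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  n <- lengths(groups)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  z <- apply(pairs, 1L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[i] + 1 / n[j]))
    (rbar[i] - rbar[j]) / se
  })
  praw <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(praw, method = adjust)
  P <- matrix(1, k, k, dimnames = list(labs, labs))
  P[pairs] <- padj
  P[pairs[, 2:1, drop = FALSE]] <- padj
  structure(P, adjust = adjust, z = z, class = c("posthocMatrix", "matrix"))
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Greedy insert-and-absorb letter assignment: classes start in one shared
#' letter group; each significantly different pair splits every group
#' containing both, and groups that become subsets of others are absorbed.
#' The result guarantees that significantly different pairs never share a
#' letter and non-different pairs share at least one. Groups are ordered by
#' their first member (class order), and letters a, b, c, ... assigned in
#' that order, so the output is deterministic.
#'
#' @param ph symmetric matrix of adjusted pairwise p-values (class labels
#'   as dimnames), e.g. from \code{\link{dunnPosthoc}}.
#' @param alpha significance level (default 0.05).
#' @return named character vector mapping class to its letter string.
#' @examples
#' p <- matrix(c(1, .01, .01, .01, 1, .8, .01, .8, 1), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' letterDisplay(p)  # A "a", B "b", C "b"
#' @export
letterDisplay <- function(ph, alpha = 0.05) {
  ph <- as.matrix(ph)
  k <- nrow(ph)
  labs <- rownames(ph)
  if (is.null(labs)) labs <- sprintf("G%d", seq_len(k))
  sets <- list(seq_len(k))
  sig <- which(upper.tri(ph) & ph < alpha, arr.ind = TRUE)
  if (nrow(sig)) {
    ord <- order(sig[, 1L], sig[, 2L])
    for (s in ord) {
      i <- sig[s, 1L]; j <- sig[s, 2L]
      newSets <- list()
      for (st in sets) {
        if (i %in% st && j %in% st) {
          newSets <- c(newSets, list(setdiff(st, i)), list(setdiff(st, j)))
        } else newSets <- c(newSets, list(st))
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(newSets))
      for (a in seq_along(newSets)) {
        for (b in seq_along(newSets)) {
          if (a != b && keep[b] &&
              all(newSets[[a]] %in% newSets[[b]]) &&
              (length(newSets[[a]]) < length(newSets[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      sets <- newSets[keep]
    }
  }
  sets <- sets[lengths(sets) > 0L]
  sets <- sets[order(vapply(sets, min, 0L),
                     vapply(sets, function(s) sum(2^s), 0))]
  letters_ <- letters[seq_along(sets)]
  out <- vapply(seq_len(k), function(ci)
    paste(letters_[vapply(sets, function(s) ci %in% s, TRUE)],
          collapse = ""), "")
  names(out) <- labs
  out
}

#' Per-feature class comparison table for a FeatureBlock
#'
#' The machine twin of a published summary table: per feature the
#' Kruskal-Wallis H and p plus the compact letter display over classes from
#' Dunn post hoc comparisons. Features that are constant across all
#' samples (e.g. a band absent everywhere) are reported with NA statistics.
#'
#' @param block a \linkS4class{FeatureBlock}.
#' @param alpha significance level for the letters.
#' @param adjust p-adjustment for the post hoc matrix.
#' @return data.frame: feature, H, df, p, then one letter column per class.
#' @export
classComparisonTable <- function(block, alpha = 0.05, adjust = "BH") {
  m <- measurements(block)
  cls <- classLabels(block)
  out <- lapply(colnames(m), function(f) {
    groups <- split(m[, f], cls)
    if (length(unique(m[, f])) == 1L) {
      letters_ <- stats::setNames(rep(NA_character_, nlevels(cls)),
                                  levels(cls))
      return(data.frame(feature = f, H = NA_real_, df = NA_integer_,
                        p = NA_real_, t(letters_),
                        check.names = FALSE, stringsAsFactors = FALSE))
    }
    kw <- kruskalWallis(groups)
    cld <- letterDisplay(dunnPosthoc(groups, adjust), alpha)
    data.frame(feature = f, H = kw$H, df = kw$df, p = kw$p, t(cld),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
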