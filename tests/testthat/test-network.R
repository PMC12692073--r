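# Correlation matrices, cross-block top pairs, thresholded networks and
# spring layout.

test_that("class-mean Pearson reproduces the published assay correlations", {
  sp <- citrusClassSpecs()
  sub <- sp[sp$block == "spectro", ]
  m <- do.call(rbind, lapply(split(sub, sub$class), function(d)
    stats::setNames(d$mean, d$feature)))
  r <- pearsonMatrix(m[, c("tpc", "tfc", "frap", "abts")],
                     mode = "class_mean", classes = rownames(m))
  expect_lt(abs(r["tpc", "tfc"] - 0.8592), 5e-4)
  expect_lt(abs(r["tpc", "frap"] - 0.5348), 5e-4)
  expect_lt(abs(r["tfc", "abts"] - 0.8532), 5e-4)
  expect_true(all(diag(r) == 1))
  expect_equal(unclass(r), t(unclass(r)), ignore_attr = TRUE)
})

test_that("replicate-mode correlations behave like Pearson r", {
  X <- peelfusion:::withSeed(4, {
    x <- rnorm(30)
    cbind(a = x, b = -x, c = rnorm(30))
  })
  r <- pearsonMatrix(X)
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "b"], -1)
  expect_true(all(abs(r) <= 1 + 1e-12))
  Xz <- cbind(X, dead = rep(2, 30))
  expect_error(pearsonMatrix(Xz), "zero-variance.*dead")
  # r -> 1 as the noise on a near-duplicate feature vanishes
  rr <- vapply(c(1, 0.1, 0.001), function(s) {
    Y <- cbind(f = X[, "a"],
               g = X[, "a"] + peelfusion:::withSeed(9, rnorm(30, 0, s)))
    pearsonMatrix(Y)["f", "g"]
  }, 0)
  expect_true(all(diff(rr) > 0) && rr[3] > 0.999)
})

test_that("top cross-block pairs rank by |r| with deterministic ties", {
  x <- c(1, 2, 3, 4, 5, 7)
  A <- cbind(a1 = x, a2 = c(2, 1, 4, 3, 6, 5))
  B <- cbind(b1 = -x, b2 = c(5, 3, 4, 1, 2, 6))
  top <- crossBlockTopPairs(A, B, k = 2L)
  expect_equal(top$featureA[1], "a1")
  expect_equal(top$featureB[1], "b1")
  expect_equal(top$r[1], -1)
  expect_true(all(abs(top$r) == sort(abs(top$r), decreasing = TRUE)))
  # k beyond the pair count returns everything
  expect_equal(nrow(crossBlockTopPairs(A, B, k = 100L)), 4L)
  # a feature duplicated across blocks self-pairs at r = 1 first
  topDup <- crossBlockTopPairs(cbind(dup = x), cbind(dup = x, o = B[, 2]))
  expect_equal(topDup$r[1], 1)
  expect_equal(topDup$featureA[1], "dup")
  # exact |r| ties break lexicographically
  topTie <- crossBlockTopPairs(cbind(f1 = x, f2 = x), cbind(g = x))
  expect_equal(topTie$featureA, c("f1", "f2"))
  expect_error(crossBlockTopPairs(A, B[1:3, ]), "misaligned")
})

toyCorr <- function() {
  C <- diag(3)
  dimnames(C) <- list(c("ftir::1600", "spectro::tpc", "physico::tss"),
                      c("ftir::1600", "spectro::tpc", "physico::tss"))
  C[1, 2] <- C[2, 1] <- 0.85
  C[1, 3] <- C[3, 1] <- 0.65
  C[2, 3] <- C[3, 2] <- 0.30
  C
}

test_that("network thresholds select and flag edges correctly", {
  net <- buildNetwork(toyCorr())
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(net$nodes$block,
               c("ftir", "spectro", "physico"))  # parsed from prefixes
  expect_equal(nrow(net$edges), 2L)
  expect_equal(sum(net$edges$bold), 1L)
  expect_true(all(abs(net$edges$r) >= 0.60))
  # identity matrix: isolated nodes retained, no edges
  I3 <- diag(3); dimnames(I3) <- dimnames(toyCorr())
  net0 <- buildNetwork(I3)
  expect_equal(nrow(net0$nodes), 3L)
  expect_equal(nrow(net0$edges), 0L)
  # raising the threshold can only shrink the edge set
  netHi <- buildNetwork(toyCorr(), edgeThreshold = 0.80)
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_true(all(key(netHi) %in% key(net)))
  expect_error(buildNetwork(toyCorr(), edgeThreshold = 0), "\\(0, 1\\]")
  expect_error(buildNetwork(toyCorr(), edgeThreshold = .7,
                            boldThreshold = .6), ">=")
})

test_that("spring layout is deterministic and attraction pulls neighbours", {
  net <- buildNetwork(toyCorr())
  l1 <- springLayout(net, seed = 3L)
  l2 <- springLayout(net, seed = 3L)
  expect_identical(l1, l2)
  expect_true(all(is.finite(c(l1$x, l1$y))))
  # single node at the origin
  C1 <- matrix(1, 1, 1, dimnames = list("ftir::a", "ftir::a"))
  lone <- springLayout(buildNetwork(C1), seed = 1L)
  expect_equal(c(lone$x, lone$y), c(0, 0))
  # connected pair ends up closer than a disconnected pair, on average
  C4 <- diag(4)
  nm <- paste0("b::", letters[1:4])
  dimnames(C4) <- list(nm, nm)
  C4[1, 2] <- C4[2, 1] <- 0.95
  n4 <- buildNetwork(C4)
  d <- vapply(1:20, function(s) {
    l <- springLayout(n4, seed = s)
    c(sqrt(sum((l[1, 2:3] - l[2, 2:3])^2)),
      sqrt(sum((l[3, 2:3] - l[4, 2:3])^2)))
  }, numeric(2))
  expect_lt(mean(d[1, ]), mean(d[2, ]))
})

test_that("network export writes GraphML and an edge list", {
  net <- buildNetwork(toyCorr())
  gml <- withr::local_tempfile(fileext = ".graphml")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeNetwork(net, graphml = gml, edgeCsv = csv)
  expect_true(file.exists(gml) && file.exists(csv))
  e <- read.csv(csv)
  expect_equal(names(e), c("source", "target", "r", "bold"))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
})
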