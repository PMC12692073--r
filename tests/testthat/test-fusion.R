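# LDA fitting, projection, prediction and stratified cross-validation.

test_that("perfectly separated 1-D classes give one axis and full accuracy", {
  X <- peelfusion:::withSeed(1, cbind(x = c(rnorm(10, -5, .1),
                                            rnorm(10, 5, .1))))
  y <- rep(c("a", "b"), each = 10)
  fit <- ldaFit(X, y, nComponents = 1L)
  expect_equal(ncol(fit$axes), 1L)
  expect_equal(as.character(ldaPredict(fit, X)), y)
  expect_error(ldaFit(X, y, nComponents = 5L), "classes - 1")
  expect_error(ldaFit(X[1:11, , drop = FALSE], c(rep("a", 10), "b")),
               "at least 2 samples")
})

test_that("collinear class means concentrate variance on LD1", {
  X <- peelfusion:::withSeed(2, {
    centers <- rbind(c(0, 0), c(5, 5), c(10, 10))
    do.call(rbind, lapply(1:3, function(i)
      sweep(matrix(rnorm(40, 0, 0.3), 20, 2), 2, centers[i, ], "+")))
  })
  y <- rep(letters[1:3], each = 20)
  fit <- ldaFit(X, y)
  expect_gt(fit$explainedVariance[1], 0.99)
  expect_true(all(diff(fit$explainedVariance) <= 1e-10))
  expect_true(all(fit$explainedVariance >= 0) &&
              sum(fit$explainedVariance) <= 1 + 1e-10)
})

test_that("transform is consistent, linear and duplicates rows faithfully", {
  X <- peelfusion:::withSeed(3, matrix(rnorm(120), 30, 4))
  y <- rep(letters[1:3], each = 10)
  fit <- ldaFit(X, y)
  expect_equal(ldaTransform(fit, X), fit$scores, tolerance = 1e-12)
  dup <- ldaTransform(fit, X[c(7, 7), , drop = FALSE])
  expect_equal(dup[1, ], dup[2, ])
  # affine shift moves scores by the projected shift
  delta <- c(1, -2, 0.5, 3)
  shifted <- ldaTransform(fit, sweep(X, 2, -delta))
  expect_equal(shifted, fit$scores + rep(1, 30) %o% drop(delta %*% fit$axes),
               tolerance = 1e-10)
  expect_error(ldaTransform(fit, X[, 1:3]), "mismatch")
})

test_that("discriminant subspace matches the brute-force generalized eigensolver", {
  for (p in c(3L, 6L, 10L)) {
    X <- peelfusion:::withSeed(100 + p, matrix(rnorm(60 * p), 60, p))
    y <- rep(letters[1:6], each = 10)
    fit <- ldaFit(X, y)
    ref <- bruteLDASubspace(X, y)
    expect_lt(subspaceAngle(fit$axes, ref), 1e-6)
  }
})

test_that("discriminant subspace agrees with an independent reference fit", {
  skip_if_not_installed("MASS")
  X <- peelfusion:::withSeed(55, matrix(rnorm(60 * 4), 60, 4))
  colnames(X) <- paste0("f", 1:4)
  y <- factor(rep(letters[1:3], each = 20))
  fit <- ldaFit(X, y, gamma = 1e-12)
  ref <- MASS::lda(X, grouping = y)
  expect_lt(subspaceAngle(fit$axes, ref$scaling), 1e-4)
})

test_that("accuracy is invariant to feature order", {
  mb <- simulateReplicateBlocks(nPerClass = 10L, seed = 17L)
  X <- measurements(concatenateBlocks(mb, c("spectro", "physico")))
  y <- classLabels(mb)
  a1 <- cvAccuracy(X, y, seed = 4L)
  a2 <- cvAccuracy(X[, rev(colnames(X))], y, seed = 4L)
  expect_equal(a1$foldAccuracy, a2$foldAccuracy, tolerance = 1e-10)
})

test_that("stratified folds are deterministic and balanced", {
  y <- factor(rep(letters[1:6], each = 10))
  f1 <- peelfusion:::.stratifiedFolds(y, 5L, seed = 2L)
  f2 <- peelfusion:::.stratifiedFolds(y, 5L, seed = 2L)
  expect_identical(f1, f2)
  # every fold holds exactly 2 samples of every class (10 / 5)
  expect_true(all(table(f1, y) == 2L))
  expect_error(cvAccuracy(matrix(rnorm(12), 6, 2),
                          rep(c("a", "b"), 3), folds = 5L), "folds")
})

test_that("cross-validated accuracy hits the ceiling and the chance floor", {
  # separable case: accuracy 1 +/- 0
  X <- peelfusion:::withSeed(6, {
    centers <- seq(0, 50, by = 10)
    do.call(rbind, lapply(centers, function(cc)
      matrix(rnorm(10 * 2, cc, 0.2), 10, 2)))
  })
  y <- factor(rep(letters[1:6], each = 10))
  cv <- cvAccuracy(X, y, seed = 1L)
  expect_equal(cv$mean, 1)
  expect_equal(cv$sd, 0)
  expect_equal(cv$mean, mean(cv$foldAccuracy))
  # uninformative features: accuracy near 1/6 averaged over seeds
  acc <- vapply(1:40, function(s) {
    Xn <- peelfusion:::withSeed(1000 + s, matrix(rnorm(60 * 5), 60, 5))
    cvAccuracy(Xn, y, seed = s)$mean
  }, 0)
  expect_lt(abs(mean(acc) - 1 / 6), 0.07)
})

test_that("fusion accuracy ordering physico <= cross <= multi holds on average", {
  n <- 20L
  acc <- vapply(seq_len(n), function(s) {
    mb <- simulateReplicateBlocks(nPerClass = 10L, seed = 3000L + s)
    y <- classLabels(mb)
    one <- cvAccuracy(measurements(concatenateBlocks(mb, "physico")),
                      y, seed = s)$mean
    cross <- cvAccuracy(
      measurements(concatenateBlocks(mb, c("spectro", "physico"))),
      y, seed = s)$mean
    multi <- cvAccuracy(measurements(concatenateBlocks(mb)),
                        y, seed = s)$mean
    c(one, cross, multi)
  }, numeric(3))
  means <- rowMeans(acc)
  expect_lt(means[1], means[2] - 0.1)  # fusion clearly beats physico alone
  expect_lt(means[1], means[3] - 0.1)
  # at the synthetic accuracy ceiling cross and multi are equivalent to
  # within fold noise; multi must not fall materially below cross
  expect_lte(means[2], means[3] + 0.01)
})
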