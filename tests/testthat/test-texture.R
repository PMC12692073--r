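# The 15 texture features: first-order moments, co-occurrence and
# run-length statistics, ROI protocol, and brute-force oracle agreement.

handImage <- function() grayImage(rbind(c(0, 0, 1),
                                        c(0, 0, 1),
                                        c(0, 2, 2)), levels = 3)

test_that("grayscale conversion uses BT.601 weights, rounded half-up", {
  px <- array(0, c(2, 2, 3))
  px[, , 1] <- 120; px[, , 2] <- 120; px[, , 3] <- 120
  expect_true(all(toGrayscale(px) == 120))
  px[] <- 255
  expect_true(all(toGrayscale(px) == 255))
  px[] <- 0; px[, , 1] <- 255
  expect_true(all(toGrayscale(px) == 76))  # 0.299 * 255 = 76.245
  # [0,1]-scaled input (readPNG convention) is equivalent
  expect_equal(unclass(toGrayscale(px / 255)), unclass(toGrayscale(px)))
  expect_error(toGrayscale(matrix(0, 2, 2)), "3-channel")
})

test_that("image IO round-trips through PNG", {
  img <- simulateTextureImage(size = c(64L, 64L), seed = 2L)
  path <- withr::local_tempfile(fileext = ".png")
  writeGrayImage(img, path)
  back <- readGrayImage(path)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE)
})

test_that("first-order features are population moments with the constant-image convention", {
  img <- grayImage(matrix(c(0, 0, 0, 0, 0, 1, 1, 2, 2), 3, 3), levels = 3)
  fo <- firstOrderFeatures(img)
  expect_equal(unname(fo["mean_intensity"]), 2 / 3, tolerance = 1e-4)
  expect_equal(unname(fo["std"]), 0.8165, tolerance = 1e-4)
  const <- firstOrderFeatures(grayImage(matrix(7, 4, 4), levels = 256))
  expect_equal(unname(const[c("std", "skewness", "kurtosis")]), c(0, 0, 0))
  sym <- firstOrderFeatures(grayImage(matrix(c(0, 1, 1, 2), 2, 2),
                                      levels = 3))
  expect_equal(unname(sym["skewness"]), 0)
})

test_that("GLCM matches the hand-enumerated horizontal example", {
  g <- computeGLCM(handImage(), angles = 0, levels = 3)
  P <- g$P
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))
  expect_equal(P[1, 1], 4 / 12)
  expect_equal(P[1, 2], 2 / 12); expect_equal(P[2, 1], 2 / 12)
  expect_equal(P[1, 3], 1 / 12); expect_equal(P[3, 1], 1 / 12)
  expect_equal(P[3, 3], 2 / 12)
  f <- glcmFeatures(g)
  expect_equal(unname(f["contrast"]), 1.0)
  expect_equal(unname(f["dissimilarity"]), 2 / 3, tolerance = 1e-10)
  expect_equal(unname(f["asm"]), 30 / 144, tolerance = 1e-10)
  expect_equal(unname(f["energy"]), sqrt(30 / 144), tolerance = 1e-10)
  expect_equal(unname(f["homogeneity"]), 0.70, tolerance = 1e-10)
  expect_equal(unname(f["energy"])^2, unname(f["asm"]), tolerance = 1e-12)
})

test_that("GLCM degenerate and checkerboard cases", {
  const <- grayImage(matrix(5, 4, 4), levels = 256)
  f <- glcmFeatures(computeGLCM(const, levels = 32))
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["correlation"]), 1)  # sigma = 0 convention
  board <- grayImage(outer(1:4, 1:4, function(r, c) (r + c) %% 2),
                     levels = 2)
  fb <- glcmFeatures(computeGLCM(board, angles = 0, levels = 2))
  expect_equal(unname(fb["contrast"]), 1)
  expect_equal(unname(fb["correlation"]), -1)
})

test_that("GLRLM matches the hand-enumerated run example", {
  rlm <- computeGLRLM(handImage(), angles = 0, levels = 3)
  expect_equal(rlm$r[1, 2], 2)  # two runs of gray 0, length 2
  expect_equal(rlm$r[2, 1], 2)  # two single-pixel runs of gray 1
  expect_equal(rlm$r[1, 1], 1)
  expect_equal(rlm$r[3, 2], 1)
  expect_equal(rlm$runs, 6)
  # pixel conservation for the single direction
  expect_equal(sum(sweep(rlm$r, 2, seq_len(ncol(rlm$r)), "*")), 9)
  f <- glrlmFeatures(rlm)
  expect_equal(unname(f["sre"]), 0.625)
  expect_equal(unname(f["lre"]), 2.5)
  expect_equal(unname(f["gln"]), 14 / 6, tolerance = 1e-10)
  expect_equal(unname(f["rln"]), 3.0)
  expect_equal(unname(f["rp"]), 2 / 3, tolerance = 1e-10)
})

test_that("run-length feature formulas on degenerate matrices", {
  # single run of length 4
  r <- matrix(0, 2, 4); r[1, 4] <- 1
  one <- structure(list(r = r, runs = 1, pixels = 4, levels = 2, angles = 0),
                   class = "glrlm")
  f <- glrlmFeatures(one)
  expect_equal(unname(f["sre"]), 1 / 16)
  expect_equal(unname(f["lre"]), 16)
  expect_equal(unname(f["rp"]), 1 / 4)
  # all-distinct pixels: every run has length 1
  img <- grayImage(matrix(0:3, 2, 2), levels = 4)
  fd <- glrlmFeatures(computeGLRLM(img, angles = 0, levels = 4))
  expect_equal(unname(fd[c("sre", "lre", "rp")]), c(1, 1, 1))
  # constant 4x4 image, one direction: four runs of length 4
  cm <- computeGLRLM(grayImage(matrix(2, 4, 4), levels = 4),
                     angles = 0, levels = 4)
  expect_equal(cm$r[3, 4], 4)
  expect_equal(cm$runs, 4)
})

test_that("pixel conservation holds per direction on random images", {
  set.seed(71)
  for (rep in 1:10) {
    m <- randomQuantizedImage(6L, 3L)
    for (a in c(0, 45, 90, 135)) {
      rlm <- computeGLRLM(grayImage(m, levels = 3), angles = a, levels = 3)
      expect_equal(sum(sweep(rlm$r, 2, seq_len(ncol(rlm$r)), "*")),
                   length(m))
    }
  }
})

test_that("GLCM and GLRLM agree exactly with the brute-force enumerator", {
  set.seed(42)
  for (rep in 1:60) {
    m <- randomQuantizedImage(6L, 3L)
    img <- grayImage(m, levels = 3)
    for (angles in list(0, c(0, 45, 90, 135))) {
      g <- computeGLCM(img, angles = angles, levels = 3)
      expect_equal(g$P, bruteGLCM(m, 3, angles = angles),
                   tolerance = 1e-14)
      rlm <- computeGLRLM(img, angles = angles, levels = 3)
      ref <- bruteGLRLM(m, 3, angles = angles)
      expect_equal(rlm$r, ref$r)
      expect_equal(rlm$runs, ref$runs)
      expect_equal(rlm$pixels, ref$pixels)
    }
  }
})

test_that("ROI extraction is deterministic and respects feasibility", {
  img <- simulateTextureImage(size = c(256L, 256L), seed = 1L)
  rois <- extractROIs(img, 64L, 4L, "grid")
  corners <- t(vapply(rois, function(r) c(r$row0, r$col0), c(0, 0)))
  expect_equal(nrow(unique(corners)), 4L)
  expect_setequal(corners[, 1], c(1, 193))
  expect_setequal(corners[, 2], c(1, 193))
  centered <- extractROIs(img, 64L, 1L, "grid")[[1]]
  expect_equal(centered$row0, 97)
  r1 <- extractROIs(img, 32L, 3L, "random", seed = 5L)
  r2 <- extractROIs(img, 32L, 3L, "random", seed = 5L)
  expect_identical(r1, r2)
  expect_error(extractROIs(img, 300L, 1L), "exceeds")
  small <- simulateTextureImage(size = c(64L, 64L), seed = 1L)
  expect_error(extractROIs(small, 64L, 2L, "grid"), "non-overlapping")
})

test_that("texture profile reports all 15 features and their ROI mean", {
  img <- simulateTextureImage(size = c(128L, 128L), seed = 3L)
  prof <- textureProfile(img)
  expect_equal(nrow(prof$perROI), 4L)
  expect_equal(ncol(prof$perROI), 15L)
  expect_equal(unname(prof$mean), unname(colMeans(prof$perROI)))
  # the energy^2 = asm identity holds per ROI record (not for ROI means)
  expect_equal(prof$perROI$energy^2, prof$perROI$asm, tolerance = 1e-12)
  # whole-image profiling of a constant image hits every degenerate value
  const <- grayImage(matrix(9L, 64, 64), levels = 256)
  pc <- textureProfile(const, roiSize = NULL)$mean
  expect_equal(unname(pc[c("std", "skewness", "kurtosis", "contrast",
                           "dissimilarity")]), rep(0, 5))
  expect_equal(unname(pc[c("homogeneity", "correlation", "asm", "energy")]),
               rep(1, 4))
})

test_that("energy squared equals ASM on arbitrary images", {
  set.seed(8)
  for (rep in 1:5) {
    img <- simulateTextureImage(noiseSd = runif(1, 2, 20),
                                blotchDensity = runif(1, 0, 40),
                                size = c(96L, 96L), seed = rep)
    f <- glcmFeatures(computeGLCM(img))
    expect_equal(unname(f["energy"])^2, unname(f["asm"]), tolerance = 1e-12)
  }
})

test_that("contrast increases with blotch density (sign test over seeds)", {
  diffs <- vapply(1:20, function(s) {
    lo <- simulateTextureImage(blotchDensity = 0, noiseSd = 5,
                               size = c(128L, 128L), seed = s)
    hi <- simulateTextureImage(blotchDensity = 50, noiseSd = 5,
                               size = c(128L, 128L), seed = s)
    glcmFeatures(computeGLCM(hi))["contrast"] -
      glcmFeatures(computeGLCM(lo))["contrast"]
  }, 0)
  wins <- sum(diffs > 0)
  expect_lt(binom.test(wins, 20, alternative = "greater")$p.value, 0.01)
})
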