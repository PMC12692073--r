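# Independent brute-force oracles used to cross-check the texture and LDA
# machinery. These deliberately use naive element-by-element enumeration,
# not the package's vectorized code paths.

.oracleOffsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                       `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# Pair enumeration over every pixel and direction; m holds quantized levels
# 0..levels-1.
bruteGLCM <- function(m, levels, distance = 1L, angles = c(0, 45, 90, 135)) {
  C <- matrix(0, levels, levels)
  nr <- nrow(m); nc <- ncol(m)
  for (a in as.character(angles)) {
    o <- .oracleOffsets[[a]]
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      r2 <- r + o[1L] * distance; c2 <- cc + o[2L] * distance
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- m[r, cc] + 1L; j <- m[r2, c2] + 1L
        C[i, j] <- C[i, j] + 1
        C[j, i] <- C[j, i] + 1
      }
    }
  }
  C / sum(C)
}

# Maximal-run enumeration walking each line pixel by pixel.
bruteGLRLM <- function(m, levels, angles = c(0, 45, 90, 135)) {
  nr <- nrow(m); nc <- ncol(m)
  linesFor <- function(a) {
    switch(as.character(a),
      `0` = lapply(seq_len(nr), function(r) m[r, ]),
      `90` = lapply(seq_len(nc), function(cc) m[, cc]),
      `45` = lapply(2:(nr + nc), function(s) {
        out <- c()
        for (cc in seq_len(nc)) {
          r <- s - cc
          if (r >= 1 && r <= nr) out <- c(out, m[r, cc])
        }
        out
      }),
      `135` = lapply((1 - nr):(nc - 1), function(d) {
        out <- c()
        for (cc in seq_len(nc)) {
          r <- cc - d
          if (r >= 1 && r <= nr) out <- c(out, m[r, cc])
        }
        out
      }))
  }
  maxLen <- max(nr, nc)
  rmat <- matrix(0, levels, maxLen)
  for (a in angles) {
    for (line in linesFor(a)) {
      runLen <- 1L
      for (i in seq_along(line)) {
        if (i < length(line) && line[i + 1L] == line[i]) {
          runLen <- runLen + 1L
        } else {
          rmat[line[i] + 1L, runLen] <- rmat[line[i] + 1L, runLen] + 1
          runLen <- 1L
        }
      }
    }
  }
  list(r = rmat, runs = sum(rmat), pixels = nr * nc * length(angles))
}

# Generalized-eigen LDA oracle via direct (non-symmetric) solve.
bruteLDASubspace <- function(X, y, gamma = 1e-6) {
  y <- factor(y)
  p <- ncol(X)
  grand <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in levels(y)) {
    Xc <- X[y == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    Sw <- Sw + crossprod(sweep(Xc, 2, mc))
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - grand)
  }
  Swr <- Sw + gamma * (sum(diag(Sw)) / p) * diag(p)
  e <- eigen(solve(Swr, Sb))
  m <- min(nlevels(y) - 1L, p)
  Re(e$vectors[, seq_len(m), drop = FALSE])
}

# Largest principal angle (radians) between the column spaces of A and B.
subspaceAngle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(max(-1, min(1, min(s))))
}

# Random small quantized test image.
randomQuantizedImage <- function(maxDim = 6L, levels = 3L) {
  nr <- sample(2:maxDim, 1L); nc <- sample(2:maxDim, 1L)
  matrix(sample(0:(levels - 1L), nr * nc, replace = TRUE), nr, nc)
}
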