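# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form kernels: matrix exponentials are truncated power
# series, distances are brute-force minima, warps are per-voxel loops.

# Truncated power-series matrix exponential (>= 30 terms).
seriesExpm <- function(A, nTerms = 40L) {
  out <- diag(nrow(A))
  term <- diag(nrow(A))
  for (n in seq_len(nTerms)) {
    term <- term %*% A / n
    out <- out + term
  }
  out
}

hat4 <- function(xi) {
  rbind(cbind(matrix(c(0, xi[3], -xi[2], -xi[3], 0, xi[1], xi[2], -xi[1], 0),
                     3, 3), xi[4:6]),
        c(0, 0, 0, 0))
}

# Random twist with rotation magnitude at most maxAngle.
randTwist <- function(maxAngle = pi - 0.1, maxTrans = 20) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  c(ax * runif(1, 0, maxAngle), runif(3, -maxTrans, maxTrans))
}

# Naive per-voxel polyrigid mapping: exp(sum_k w_k log T_k) x via the series
# exponential; `twistRows` are already the logs of the structure transforms.
naivePolyrigid <- function(W, twistRows, X) {
  out <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) {
    mixed <- as.vector(W[i, , drop = FALSE] %*% twistRows)
    T <- seriesExpm(hat4(mixed))
    out[i, ] <- (T %*% c(X[i, ], 1))[1:3]
  }
  out
}

# Brute-force Euclidean distance (mm) from every voxel to a mask.
bruteDistance <- function(mask, spacing) {
  d <- dim(mask)
  pts <- as.matrix(expand.grid(seq_len(d[1]) - 1, seq_len(d[2]) - 1,
                               seq_len(d[3]) - 1))
  pts <- sweep(pts, 2, spacing, "*")
  src <- pts[as.vector(mask), , drop = FALSE]
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    dif <- sweep(src, 2, pts[i, ])
    out[i] <- sqrt(min(rowSums(dif^2)))
  }
  array(out, d)
}

# Small fast phantom used by the registration-level unit tests.
smallPhantomConfig <- function() {
  phantomConfig(gridShape = c(48L, 48L, 48L),
                body = list(center = c(0, 0, 0), radii = c(19, 18, 19)),
                bones = list(
                  list(center = c(-9, -2, 0), radii = c(4, 6, 7)),
                  list(center = c(10, 2, 0), radii = c(3, 4, 5))))
}

smallCase <- function(seed = 0, maxRotDeg = 8, maxTransMm = 6, ...) {
  generateCase(smallPhantomConfig(), maxRotDeg = maxRotDeg,
               maxTransMm = maxTransMm, detectorShape = c(48L, 48L),
               pixelSpacing = c(2.2, 2.2), seed = seed, ...)
}

# Pose errors of recovered twists against a case's ground truth.
caseRecovery <- function(case, twists) {
  K <- nrow(case@gtTwists)
  sp <- spacing(case@labelmap)
  sapply(seq_len(K), function(k) {
    idx <- which(voxelData(case@labelmap) == k, arr.ind = TRUE)
    pts <- sweep((idx - 1) %*% diag(sp), 2, origin(case@labelmap), "+")
    pe <- poseError(expSE3(twists[k, ]), expSE3(case@gtTwists[k, ]), pts)
    c(rotDeg = pe$rotDeg, transMm = pe$transMm)
  })
}
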