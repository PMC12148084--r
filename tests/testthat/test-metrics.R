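test_that("Dice handles the counting cases and degenerate inputs", {
  a <- matrix(FALSE, 8, 8); a[1:4, 1:4] <- TRUE
  b <- matrix(FALSE, 8, 8); b[1:4, 3:6] <- TRUE
  expect_equal(diceCoefficient(a, b), 2 * 8 / (16 + 16))  # 4x2 overlap
  expect_equal(diceCoefficient(a, a), 1.0)
  expect_equal(diceCoefficient(a, !a & FALSE), 0.0)
  expect_equal(diceCoefficient(a & FALSE, b & FALSE), 1.0)
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  expect_error(diceCoefficient(a, matrix(TRUE, 4, 4)), "lattice")
})

bruteHD95 <- function(a, b, spacing, probs = 0.95) {
  bnd <- function(m) {
    d <- dim(m)
    out <- array(FALSE, d)
    for (i in which(m)) {
      idx <- arrayInd(i, d)
      nb <- rbind(idx + c(1, 0, 0), idx - c(1, 0, 0), idx + c(0, 1, 0),
                  idx - c(0, 1, 0), idx + c(0, 0, 1), idx - c(0, 0, 1))
      outside <- apply(nb, 1, function(j) {
        any(j < 1) || any(j > d) || !m[j[1], j[2], j[3]]
      })
      if (any(outside)) out[i] <- TRUE
    }
    out
  }
  pa <- which(bnd(a), arr.ind = TRUE); pb <- which(bnd(b), arr.ind = TRUE)
  pa <- sweep(pa - 1, 2, spacing, "*"); pb <- sweep(pb - 1, 2, spacing, "*")
  dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
                Vectorize(function(i, j) sqrt(sum((pa[i, ] - pb[j, ])^2))))
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  as.numeric(quantile(pooled, probs, type = 7))
}

test_that("HD95 pools directed boundary distances, in physical units", {
  a <- array(FALSE, c(12, 12, 3)); a[3, 4, 2] <- TRUE
  b <- array(FALSE, c(12, 12, 3)); b[6, 4, 2] <- TRUE
  expect_equal(hd95(a, b, spacing = c(1, 1, 1)), 3.0)
  expect_equal(hd95(a, a, spacing = c(1, 1, 1)), 0.0)

  sq <- array(FALSE, c(16, 16, 3)); sq[3:12, 3:12, 2] <- TRUE
  sh <- array(FALSE, c(16, 16, 3)); sh[5:14, 3:12, 2] <- TRUE
  expect_equal(hd95(sq, sh, spacing = c(1, 1, 1)),
               bruteHD95(sq, sh, c(1, 1, 1)))
  expect_equal(hd95(sq, sh, spacing = c(1, 1, 1)),
               hd95(sh, sq, spacing = c(1, 1, 1)))
  expect_equal(hd95(sq, sh, spacing = c(2, 2, 2)),
               bruteHD95(sq, sh, c(2, 2, 2)))
  expect_error(hd95(sq, sh & FALSE), "non-empty")
})

test_that("Jacobian statistics recognise scalings and reflections", {
  d <- c(8L, 8L, 8L)
  X <- array(0, c(d, 3))
  grid <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  for (c in 1:3) X[, , , c] <- array(grid[, c], d)

  idf <- new("DenseField", disp = array(0, c(d, 3)), spacing = c(1, 1, 1),
             origin = c(0, 0, 0))
  js <- jacobianStats(idf)
  expect_equal(js$percentFolds, 0.0)
  expect_equal(js$sigmaLogJac, 0.0)

  js <- jacobianStats(X * 1.1, spacing = c(1, 1, 1))
  expect_equal(js$percentFolds, 0.0)
  expect_lt(js$sigmaLogJac, 1e-12)

  refl <- X; refl[, , , 1] <- -X[, , , 1]
  expect_equal(jacobianStats(refl, spacing = c(1, 1, 1))$percentFolds, 100.0)
  expect_error(jacobianStats(X[1:2, , , , drop = FALSE],
                             spacing = c(1, 1, 1)), "3 voxels")
})

test_that("projected silhouettes match analytic geometry", {
  # centred sphere, radius 31.5 mm on a 0.5 mm grid, magnification 2;
  # the silhouette rim is blurred by about one voxel (grazing rays through
  # the trilinear ramp), so the area converges to the analytic disc as the
  # resolution grows
  n <- 140L; sp <- 0.5
  X <- sweep(as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1))), 2,
             (n - 1) / 2) * sp
  R <- 31.5
  lab <- array(as.integer(rowSums(X^2) <= R^2), c(n, n, n))
  lm <- Labelmap(lab, spacing = rep(sp, 3))
  cam <- orbitCameras(nViews = 1, detectorShape = c(160L, 160L),
                      pixelSpacing = c(1, 1))[[1]]
  sil <- projectMask(lm, 1L, cam, renderConfig(stepMm = 0.5))
  area <- sum(sil)  # px^2, 1 mm pixels; projected radius = 2 R
  expect_lt(abs(area - pi * (2 * R)^2) / (pi * (2 * R)^2), 0.05)

  # empty (absent) structure projects to nothing; invalid ids error
  expect_true(all(!projectMask(lm, 2L, cam)))
  expect_error(projectMask(lm, -1L, cam), "id")

  # in-plane translation shifts the silhouette by the magnified amount
  lmShift <- Labelmap(lab, spacing = rep(sp, 3),
                      origin = origin(lm) + c(0, 5, 0))
  sil2 <- projectMask(lmShift, 1L, cam, renderConfig(stepMm = 0.5))
  c1 <- colMeans(which(sil, arr.ind = TRUE))
  c2 <- colMeans(which(sil2, arr.ind = TRUE))
  shift <- c2 - c1
  # world +y maps to detector -x at this view angle, magnified by 2
  expect_lt(abs(max(abs(shift)) - 10) / 10, 0.1)
})
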