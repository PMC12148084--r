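twoBlockLabelmap <- function(counts = c(2L, 2L), spacing = c(1, 1, 1)) {
  lab <- array(0L, c(10, 10, 10))
  lab[1:counts[1], 1, 1] <- 1L
  lab[1:counts[2], 5, 5] <- 2L
  Labelmap(lab, spacing = spacing)
}

test_that("masses are proportional to physical structure volume", {
  expect_equal(as.numeric(computeMasses(twoBlockLabelmap(c(2L, 2L)))),
               c(0.5, 0.5))
  lab <- array(0L, c(10, 10, 10)); lab[1:4, 1:5, 1:5] <- 1L
  expect_equal(as.numeric(computeMasses(Labelmap(lab))), 1.0)
  # counts 100 vs 300 on uniform spacing -> (0.25, 0.75)
  lab3 <- array(0L, c(10, 10, 10))
  lab3[1:4, 1:5, 1:5] <- 1L     # 100 voxels
  lab3[5:10, 6:10, 1:10] <- 2L  # 300 voxels
  expect_equal(as.numeric(computeMasses(Labelmap(lab3))), c(0.25, 0.75))
  expect_error(computeMasses(Labelmap(lab3), ids = c(1L, 4L)), "4")
})

test_that("distance maps are exact physical Euclidean distances", {
  lab <- array(0L, c(7, 7, 7)); lab[4, 4, 4] <- 1L
  dm <- computeDistanceMaps(Labelmap(lab, spacing = c(1, 1, 2)))[[1]]
  expect_equal(dm[4, 4, 4], 0)
  expect_equal(dm[5, 4, 4], 1)        # x neighbour, 1 mm
  expect_equal(dm[4, 4, 5], 2)        # z neighbour at 2 mm spacing
  expect_equal(dm[5, 5, 5], sqrt(1 + 1 + 4))

  set.seed(8)
  lab <- array(0L, c(10, 10, 10))
  lab[sample(1000, 15)] <- 1L
  sp <- c(1, 1.3, 0.7)
  dm <- computeDistanceMaps(Labelmap(lab, spacing = sp))[[1]]
  expect_equal(dm, bruteDistance(lab == 1L, sp), tolerance = 1e-12)
})

test_that("weight fields follow the mass and reciprocal-distance formulas", {
  lm <- twoBlockLabelmap(c(2L, 6L))
  ss <- structureSet(lm)
  Wm <- buildWeights(ss, "mass")
  D <- vapply(ss@distanceMaps, as.vector, numeric(1000))
  raw <- sweep(1 / (1 + D^2), 2, ss@masses, "*")
  expect_equal(Wm@W, raw / rowSums(raw), tolerance = 1e-12,
               ignore_attr = TRUE)
  # inside S_k the unnormalized weight is exactly m_k (d_k = 0)
  inside1 <- which(as.vector(voxelData(lm) == 1L))
  expect_equal(unique(raw[inside1, 1]), ss@masses[1])
  # spot values of the two formulas
  expect_equal(0.5 / (1 + 3^2), 0.05)
  expect_equal(1 / (1 + 1 * 1^2), 0.5)

  Wr <- buildWeights(ss, "reciprocal", epsilon = 0.1)
  rawr <- 1 / (1 + 0.1 * D^2)
  expect_equal(Wr@W, rawr / rowSums(rawr), tolerance = 1e-12,
               ignore_attr = TRUE)

  # normalization on a random phantom
  ph <- generatePhantom(phantomConfig())
  W <- buildWeights(structureSet(ph$labelmap), "mass")
  expect_lt(max(abs(rowSums(W@W) - 1)), 1e-6)
  expect_true(all(W@W >= 0 & W@W <= 1))

  # mode/hyperparameter contract
  expect_error(buildWeights(ss, "mass", epsilon = 0.5), "hyperparameter-free")
  expect_error(buildWeights(ss, "reciprocal"), "epsilon")
  expect_error(buildWeights(ss, "reciprocal", epsilon = 2), "epsilon")
})

test_that("polyrigid fusion reduces to rigid transforms in the limits", {
  lm <- twoBlockLabelmap()
  v <- Volume(array(0, dim(lm)), spacing(lm), origin(lm))
  X <- cbind(as.matrix(expand.grid(0:9, 0:9, 0:9)), 1)
  X[, 1:3] <- sweep(X[, 1:3], 2, origin(lm), "+")

  # K = 1: the field is the rigid transform exactly
  lab1 <- array(1L, c(10, 10, 10))
  W1 <- buildWeights(structureSet(Labelmap(lab1, origin = origin(lm))),
                     "mass")
  xi <- c(0.2, -0.1, 0.15, 3, -2, 1)
  f1 <- buildField(W1, matrix(xi, 1))
  expect_lt(max(abs(matrix(mappingGrid(f1), ncol = 3) -
                    (X %*% t(expSE3(xi)))[, 1:3])), 1e-12)

  # identical twists: weighted mean of identical logs
  W2 <- buildWeights(structureSet(lm), "mass")
  f2 <- buildField(W2, rbind(xi, xi))
  expect_lt(max(abs(matrix(mappingGrid(f2), ncol = 3) -
                    (X %*% t(expSE3(xi)))[, 1:3])), 1e-10)

  # zero twists: identity at every voxel
  f0 <- buildField(W2, matrix(0, 2, 6))
  expect_equal(max(abs(matrix(mappingGrid(f0), ncol = 3) - X[, 1:3])), 0)

  expect_error(buildField(W2, matrix(0, 3, 6)), "match")
})

test_that("vectorized fusion equals the naive per-voxel evaluation", {
  set.seed(9)
  lab <- array(0L, c(12, 12, 12))
  lab[2:4, 2:4, 2:4] <- 1L
  lab[8:10, 3:5, 4:6] <- 2L
  lm <- Labelmap(lab)
  W <- buildWeights(structureSet(lm), "mass")
  tw <- rbind(randTwist(0.3, 5), randTwist(0.3, 5))
  f <- buildField(W, tw)
  X <- sweep(as.matrix(expand.grid(0:11, 0:11, 0:11)), 2, origin(lm), "+")
  sub <- seq(1, nrow(X), by = 7)
  naive <- naivePolyrigid(W@W[sub, , drop = FALSE], tw, X[sub, ])
  expect_lt(max(abs(matrix(mappingGrid(f), ncol = 3)[sub, ] - naive)), 1e-8)
})

test_that("off-lattice field evaluation extends the lattice continuously", {
  lm <- twoBlockLabelmap()
  W <- buildWeights(structureSet(lm), "mass")
  tw <- rbind(c(0, 0, 0, 2, 0, 0), c(0, 0, 0, -1, 3, 0))
  f <- buildField(W, tw)
  X <- sweep(as.matrix(expand.grid(0:9, 0:9, 0:9)), 2, origin(lm), "+")
  expect_equal(fieldAtPoints(f, X), matrix(mappingGrid(f), ncol = 3),
               tolerance = 1e-9)

  f0 <- buildField(W, matrix(0, 2, 6))
  pts <- matrix(rnorm(30, sd = 3), 10, 3)
  expect_equal(fieldAtPoints(f0, pts), pts)

  # displacement at a point between two voxel centres stays within the
  # bounding box of the two voxel displacements (pure-translation field)
  p1 <- X[1, ]; p2 <- X[2, ]
  d1 <- fieldAtPoints(f, matrix(p1, 1)) - p1
  d2 <- fieldAtPoints(f, matrix(p2, 1)) - p2
  mid <- (p1 + p2) / 2
  dm <- fieldAtPoints(f, matrix(mid, 1)) - mid
  expect_true(all(dm >= pmin(d1, d2) - 1e-9 & dm <= pmax(d1, d2) + 1e-9))
})

test_that("influence of a structure decays monotonically with distance", {
  ph <- generatePhantom(phantomConfig(gridShape = c(32L, 32L, 32L),
    body = list(center = c(0, 0, 0), radii = c(13, 12, 13)),
    bones = list(list(center = c(-5, -1, 0), radii = c(3, 4, 5)),
                 list(center = c(6, 1, 0), radii = c(2, 3, 3)))))
  W <- buildWeights(structureSet(ph$labelmap), "mass")
  tw <- rbind(c(0, 0, 0, 4, 0, 0), c(0, 0, 0, 0, -3, 0))
  f <- buildField(W, tw)
  T1 <- expSE3(tw[1, ])
  # walk away from bone 1 along +y: deviation from T1 never decreases
  line <- cbind(-5, seq(-1, 11, by = 0.5), 0)
  dev <- sqrt(rowSums((fieldAtPoints(f, line) -
                       (cbind(line, 1) %*% t(T1))[, 1:3])^2))
  expect_true(all(diff(dev) > -1e-9))
})

test_that("rigid-reduction and identity fields have trivial Jacobians", {
  ph <- generatePhantom(phantomConfig(gridShape = c(24L, 24L, 24L),
    body = list(center = c(0, 0, 0), radii = c(9, 9, 9)),
    bones = list(list(center = c(-4, 0, 0), radii = c(2, 2.5, 3)),
                 list(center = c(4, 0, 0), radii = c(1.5, 2, 2)))))
  W <- buildWeights(structureSet(ph$labelmap), "mass")
  xi <- c(0.1, 0.05, -0.08, 2, 1, -1)
  js <- jacobianStats(buildField(W, rbind(xi, xi)))
  expect_equal(js$percentFolds, 0)
  expect_lt(js$sigmaLogJac, 1e-6)
})
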