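# A homogeneous cube embedded in zero padding: the line integral of the
# trilinear interpolant along an axis-aligned ray equals mu times the chord
# through the box extended half a voxel beyond the outer cube voxel centres
# (the zero-padding ramp integrates to exactly half a voxel per side).
cubeVolume <- function(mu = 0.02, n = 32L, inner = 5:28) {
  a <- array(0, c(n, n, n))
  a[inner, inner, inner] <- mu
  Volume(a, spacing = c(1, 1, 1))
}

axialCamera <- function(detectorShape = c(15L, 15L), pixelSpacing = c(4, 4)) {
  orbitCameras(nViews = 1, detectorShape = detectorShape,
               pixelSpacing = pixelSpacing)[[1]]
}

test_that("source position satisfies its defining equation", {
  cam <- Camera(extrinsic = diag(4), detectorShape = c(8L, 8L),
                pixelSpacing = c(1, 1), focalLengthMm = 100)
  expect_equal(sourcePosition(cam), c(0, 0, 0))

  T <- diag(4); T[3, 4] <- -500
  cam <- Camera(extrinsic = T, detectorShape = c(8L, 8L),
                pixelSpacing = c(1, 1), focalLengthMm = 100)
  expect_equal(sourcePosition(cam), c(0, 0, 500))

  set.seed(5)
  for (i in 1:20) {
    T <- expSE3(randTwist(2, 300))
    cam <- Camera(extrinsic = T, detectorShape = c(8L, 8L),
                  pixelSpacing = c(1, 1), focalLengthMm = 100)
    S <- sourcePosition(cam)
    expect_lt(max(abs(T[1:3, 1:3] %*% S + T[1:3, 4])), 1e-9)
  }
})

test_that("pixel/world mappings are mutually consistent", {
  cam <- orbitCameras(nViews = 1, angularSpanDeg = 0, startDeg = 33)[[1]]
  # the principal point maps to the optical axis at distance f
  pp <- c(cam@intrinsic[1, 3], cam@intrinsic[2, 3])
  P <- pixelToWorld(cam, matrix(pp, 1))
  S <- sourcePosition(cam)
  expect_equal(sqrt(sum((P - S)^2)), focalLength(cam))
  zhat <- cam@extrinsic[3, 1:3]
  expect_equal(as.vector(P), S + focalLength(cam) * zhat, tolerance = 1e-9)

  # projecting detector points recovers the pixels
  set.seed(6)
  px <- cbind(runif(100, 0, 63), runif(100, 0, 63))
  expect_lt(max(abs(projectWorld(cam, pixelToWorld(cam, px)) - px)), 1e-6)

  # translating the camera rigidly translates detector points identically
  d <- c(10, -20, 5)
  T2 <- cam@extrinsic
  T2[1:3, 4] <- T2[1:3, 4] - T2[1:3, 1:3] %*% d
  cam2 <- setExtrinsic(cam, T2)
  P1 <- pixelToWorld(cam, px)
  P2 <- pixelToWorld(cam2, px)
  expect_equal(P2, sweep(P1, 2, d, "+"), tolerance = 1e-9)
})

test_that("rendering matches the analytic chord of a homogeneous cube", {
  v <- cubeVolume()
  cam <- axialCamera()
  img <- renderDRR(v, cam, renderConfig(stepMm = 0.5))
  # central axial ray: chord through [3.5, 27.5] in voxel units = 24 mm
  centre <- img[8, 8]
  expect_lt(abs(centre - 0.02 * 24) / (0.02 * 24), 0.01)

  # quadrature convergence: halving the step changes the value by < 0.5%
  img2 <- renderDRR(v, cam, renderConfig(stepMm = 0.25))
  expect_lt(abs(img2[8, 8] - centre) / centre, 0.005)

  # an off-centre but still axial ray sees the same chord
  expect_lt(abs(img[8, 9] - 0.02 * 24) / (0.02 * 24), 0.01)

  # linearity in the volume
  v5 <- Volume(voxelData(v) * 5, spacing(v), origin(v))
  expect_equal(renderDRR(v5, cam, renderConfig(stepMm = 0.5)), 5 * img,
               tolerance = 1e-12)

  # empty integrand
  v0 <- Volume(array(0, c(32, 32, 32)))
  expect_true(all(renderDRR(v0, cam) == 0))
})

test_that("ray clipping redistributes quadrature without changing values", {
  v <- cubeVolume()
  cam <- axialCamera()
  a <- renderDRR(v, cam, renderConfig(stepMm = 0.5, clipToVolume = TRUE))
  b <- renderDRR(v, cam, renderConfig(stepMm = 0.5, clipToVolume = FALSE))
  expect_lt(max(abs(a - b)) / max(a), 0.005)
})

test_that("a source inside the volume is a geometry error", {
  v <- cubeVolume()
  T <- diag(4)  # camera at the world origin = cube centre
  cam <- Camera(extrinsic = T, detectorShape = c(4L, 4L),
                pixelSpacing = c(1, 1), focalLengthMm = 100)
  expect_error(renderDRR(v, cam), "inside")
})

test_that("structure rendering masks the volume", {
  ph <- generatePhantom(phantomConfig(gridShape = c(32L, 32L, 32L),
    body = list(center = c(0, 0, 0), radii = c(13, 12, 13)),
    bones = list(list(center = c(-5, -1, 0), radii = c(3, 4, 5)),
                 list(center = c(6, 1, 0), radii = c(2, 3, 3)))))
  cam <- axialCamera(c(21L, 21L), c(3, 3))
  cfg <- renderConfig(stepMm = 0.5)
  both <- renderStructure(ph$volume, ph$labelmap, c(1, 2), cam, cfg)
  manual <- renderDRR(maskVolume(ph$volume, ph$labelmap, c(1, 2)), cam, cfg)
  expect_equal(both, manual)
  expect_true(all(renderStructure(ph$volume, ph$labelmap, integer(0), cam,
                                  cfg) == 0))
  expect_error(renderStructure(ph$volume, ph$labelmap, 9, cam, cfg),
               "unknown")

  # thickness map of a binary mask: maximum equals the largest chord
  maskV <- Volume(array(as.numeric(voxelData(ph$labelmap) == 1),
                        dim(ph$labelmap)), spacing(ph$labelmap),
                  origin(ph$labelmap))
  th <- renderDRR(maskV, cam, renderConfig(stepMm = 0.25))
  # rays run along -x through the bone (x-radius 3): continuum max chord is
  # 6 mm, voxelization can add up to about one voxel
  expect_gt(max(th), 5.5)
  expect_lt(max(th), 7.6)
})

test_that("the analytic pose gradient matches finite differences", {
  ph <- generatePhantom(phantomConfig(gridShape = c(32L, 32L, 32L),
    body = list(center = c(0, 0, 0), radii = c(13, 12, 13)),
    bones = list(list(center = c(-5, -1, 0), radii = c(3, 4, 5)),
                 list(center = c(6, 1, 0), radii = c(2, 3, 3)))))
  v <- ph$volume
  cam <- axialCamera(c(21L, 21L), c(3, 3))
  cfg <- renderConfig(stepMm = 0.5)
  xi0 <- c(0.02, -0.015, 0.03, 0.671, -0.382, 0.257)  # generic offset
  pixel <- c(11L, 13L)
  res <- drrPixelPoseGradient(v, cam, cfg, xi0, pixel)
  expect_gt(abs(res$value), 0)

  fd <- numeric(6)
  for (j in 1:6) {
    h <- if (j <= 3) 1e-6 else 1e-5
    e <- numeric(6); e[j] <- h
    W <- buildWeights(structureSet(Labelmap(array(1L, dim(v)), spacing(v),
                                            origin(v))), "mass")
    fp <- renderDRR(warpVolume(v, buildField(W, matrix(xi0 + e, 1))), cam,
                    cfg)[pixel[1], pixel[2]]
    fm <- renderDRR(warpVolume(v, buildField(W, matrix(xi0 - e, 1))), cam,
                    cfg)[pixel[1], pixel[2]]
    fd[j] <- (fp - fm) / (2 * h)
  }
  expect_lt(max(abs(res$gradient - fd)) / max(abs(fd)), 1e-3)
})
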