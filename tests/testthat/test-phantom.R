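test_that("phantom generation is deterministic and material-consistent", {
  cfg <- phantomConfig()
  p1 <- generatePhantom(cfg)
  p2 <- generatePhantom(cfg)
  expect_identical(voxelData(p1$volume), voxelData(p2$volume))
  expect_identical(voxelData(p1$labelmap), voxelData(p2$labelmap))

  # bone attenuation appears only inside labelled voxels
  boneVox <- voxelData(p1$volume) >= cfg@lacMarrow
  expect_true(all(voxelData(p1$labelmap)[voxelData(p1$volume) == cfg@lacBone] > 0))
  expect_true(all(voxelData(p1$volume)[voxelData(p1$labelmap) > 0] %in%
                  c(cfg@lacBone, cfg@lacMarrow)))
  # soft tissue fills an outer ellipsoid
  expect_true(any(voxelData(p1$volume) == cfg@lacSoft))
})

test_that("configured radii control structure masses", {
  # radii ratio 2:1 per axis -> volume (mass) ratio 8:1
  cfg <- phantomConfig(bones = list(
    list(center = c(-12, -2, 0), radii = c(6, 9, 10)),
    list(center = c(13, 2, 0), radii = c(3, 4.5, 5))))
  ph <- generatePhantom(cfg)
  m <- computeMasses(ph$labelmap)
  expect_lt(abs(m[1] / m[2] - 8) / 8, 0.05)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(generatePhantom(phantomConfig(bones = list(
    list(center = c(0, 0, 0), radii = c(8, 8, 8)),
    list(center = c(5, 0, 0), radii = c(8, 8, 8))))), "overlap")
  expect_error(generatePhantom(phantomConfig(bones = list(
    list(center = c(30, 0, 0), radii = c(8, 8, 8))))), "beyond")
})

test_that("cases honour the requested geometry and motion bounds", {
  cfg <- phantomConfig()
  case <- generateCase(cfg, nViews = 2, angularSpanDeg = 30, seed = 4)
  expect_equal(length(case@cameras), 2L)
  # two views, 30 degrees apart on the orbit
  s1 <- sourcePosition(case@cameras[[1]])
  s2 <- sourcePosition(case@cameras[[2]])
  ang <- acos(sum(s1 * s2) / sqrt(sum(s1^2) * sum(s2^2))) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-9)

  # same seed reproduces the case bit for bit
  case2 <- generateCase(cfg, nViews = 2, angularSpanDeg = 30, seed = 4)
  expect_identical(case@gtTwists, case2@gtTwists)
  expect_identical(case@images, case2@images)

  # sampled motions respect the bounds
  for (k in 1:nrow(case@gtTwists)) {
    T <- expSE3(case@gtTwists[k, ])
    ang <- acos(pmin(1, (sum(diag(T[1:3, 1:3])) - 1) / 2)) * 180 / pi
    expect_lte(ang, 10 + 1e-9)
    expect_lte(sqrt(sum(T[1:3, 4]^2)), 10 + 1e-9)
  }

  # fixed images are exactly the DRRs of the warped moving volume
  warped <- warpVolume(case@volume, case@gtField)
  expect_equal(case@images[[1]],
               renderDRR(warped, case@cameras[[1]], case@renderConfig))

  # the ground-truth field is fold-free by construction
  expect_equal(jacobianStats(case@gtField)$percentFolds, 0)
})

test_that("zero motion bounds reproduce the unwarped projections", {
  case <- generateCase(phantomConfig(), maxRotDeg = 0, maxTransMm = 0,
                       seed = 1)
  expect_equal(case@gtTwists, matrix(0, 2, 6))
  for (n in seq_along(case@images))
    expect_equal(case@images[[n]],
                 renderDRR(case@volume, case@cameras[[n]], case@renderConfig))
  # metrics of the ground truth against itself are perfect
  expect_equal(unname(warpedMaskDice(case@labelmap, case@gtField,
                                     case@gtField)), c(1, 1))
})

test_that("motions that leave the field of view are a configuration error", {
  expect_error(generateCase(phantomConfig(), maxRotDeg = 0, maxTransMm = 200,
                            seed = 1), "field of view")
})

test_that("a case round-trips through the on-disk layout", {
  case <- smallCase(seed = 2)
  dir <- tempfile()
  writeCase(case, dir)
  vol <- readVolume(file.path(dir, "volume.nii.gz"))
  expect_equal(voxelData(vol), voxelData(case@volume), tolerance = 1e-7)
  cams <- readGeometry(file.path(dir, "geometry.json"))
  expect_equal(cams[[1]]@extrinsic, case@cameras[[1]]@extrinsic,
               tolerance = 1e-12)
  expect_equal(cams[[2]]@intrinsic, case@cameras[[2]]@intrinsic,
               tolerance = 1e-12)
  img <- readProjection(file.path(dir, "views", "view_01.tiff"))
  expect_equal(img, case@images[[1]], tolerance = 1e-5, ignore_attr = TRUE)
  tw <- readTwists(file.path(dir, "gt_twists.json"))
  expect_equal(tw$twists, case@gtTwists, ignore_attr = TRUE)
  df <- readField(file.path(dir, "gt_field.nii.gz"))
  expect_equal(df@disp, displacementField(case@gtField)@disp,
               tolerance = 1e-6, ignore_attr = TRUE)
})
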