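# Registration-level tests run on a 48-cube phantom with a 48x48 detector so
# the full suite stays fast; the study-scale experiments live in
# test-acceptance.R.

test_that("registration of undeformed fixtures returns identity twists", {
  case <- smallCase(seed = 1, maxRotDeg = 0, maxTransMm = 0)
  res <- registerPolyrigid(case@volume, case@labelmap, images = case@images,
                           cameras = case@cameras,
                           optCfg = optimConfig(maxIters = 60L),
                           renderCfg = case@renderConfig)
  rotDeg <- sqrt(rowSums(res$twists[, 1:3]^2)) * 180 / pi
  transMm <- sqrt(rowSums(res$twists[, 4:6]^2))
  expect_lt(max(rotDeg), 0.2)
  expect_lt(max(transMm), 0.2)
})

test_that("the loss gradient reaches every structure's twist", {
  case <- smallCase(seed = 3)
  g <- polyrigidObjective(case@volume, case@labelmap, images = case@images,
                          cameras = case@cameras,
                          twists = matrix(0, 2, 6),
                          renderCfg = case@renderConfig)
  perBone <- sqrt(rowSums(g$grad^2))
  expect_true(all(perBone > 0))
})

test_that("per-structure poses and masks are recovered from two views", {
  case <- smallCase(seed = 3)
  res <- registerPolyrigid(case@volume, case@labelmap, images = case@images,
                           cameras = case@cameras,
                           renderCfg = case@renderConfig)
  err <- caseRecovery(case, res$twists)
  expect_lt(max(err["rotDeg", ]), 1)
  expect_lt(max(err["transMm", ]), 1)
  dice <- warpedMaskDice(case@labelmap, res$field, case@gtField)
  expect_gte(min(dice), 0.95)

  # ascent contract: the accepted trajectory is monotone and ends at least
  # as high as it started
  expect_true(all(diff(res$report$accepted) >= 0))
  expect_gte(res$report$finalValue, res$report$initialValue)

  # a subset registration leaves the excluded structure untouched
  sub <- registerPolyrigid(case@volume, case@labelmap, structureIdsUsed = 1L,
                           images = case@images, cameras = case@cameras,
                           optCfg = optimConfig(maxIters = 40L),
                           renderCfg = case@renderConfig)
  expect_equal(nrow(sub$twists), 1L)
  expect_equal(length(sub$field@weights@ids), 1L)
})

test_that("registration rejects degenerate inputs", {
  case <- smallCase(seed = 1)
  expect_error(registerPolyrigid(case@volume, case@labelmap,
                                 images = list(), cameras = list()),
               "view")
  expect_error(registerPolyrigid(case@volume, case@labelmap,
                                 structureIdsUsed = integer(0),
                                 images = case@images,
                                 cameras = case@cameras), "structure")
  expect_error(registerPolyrigid(case@volume, case@labelmap,
                                 structureIdsUsed = c(1L, 9L),
                                 images = case@images,
                                 cameras = case@cameras), "unknown")
  expect_error(registerCamera(case@volume, case@labelmap, anchorId = 9,
                              images = case@images, cameras = case@cameras),
               "anchor")
})

test_that("camera registration is stable at the truth and recovers offsets", {
  ph <- generatePhantom(smallPhantomConfig())
  rc <- renderConfig(stepMm = 1)
  cams <- orbitCameras(nViews = 1, detectorShape = c(48L, 48L),
                       pixelSpacing = c(2.2, 2.2))
  obs <- list(renderDRR(ph$volume, cams[[1]], rc))

  # started at the ground truth, the pose does not diverge
  res0 <- registerCamera(ph$volume, ph$labelmap, 1, obs, cams,
                         optCfg = optimConfig(maxIters = 40L),
                         renderCfg = rc)
  tw <- logSE3(solve(cams[[1]]@extrinsic) %*% res0$cameras[[1]]@extrinsic)
  expect_lt(sqrt(sum(tw[1:3]^2)) * 180 / pi, 0.1)
  expect_lt(sqrt(sum(tw[4:6]^2)), 0.1)
  expect_gte(res0$reports[[1]]$finalValue, res0$reports[[1]]$initialValue)

  # a ~4 degree / 9 mm offset is recovered to sub-degree, sub-mm accuracy
  delta <- c(0.05, -0.045, 0.04, 6, -5, 4)
  init <- list(setExtrinsic(cams[[1]], cams[[1]]@extrinsic %*% expSE3(delta)))
  res <- registerCamera(ph$volume, ph$labelmap, 1, obs, init, renderCfg = rc)
  tw <- logSE3(solve(cams[[1]]@extrinsic) %*% res$cameras[[1]]@extrinsic)
  expect_lt(sqrt(sum(tw[1:3]^2)) * 180 / pi, 0.5)
  expect_lt(sqrt(sum(tw[4:6]^2)), 1)
  expect_gte(res$reports[[1]]$finalValue, res$reports[[1]]$initialValue)
})

test_that("camera and deformable stages compose", {
  # localized motion: the anchor structure is static, the second bone moves
  case <- generateCase(smallPhantomConfig(), maxRotDeg = c(0, 4),
                       maxTransMm = c(0, 3), detectorShape = c(48L, 48L),
                       pixelSpacing = c(2.2, 2.2), seed = 5)
  rc <- case@renderConfig
  opt <- optimConfig(maxIters = 150L)
  set.seed(11)
  init <- lapply(case@cameras, function(cam) {
    setExtrinsic(cam, cam@extrinsic %*% expSE3(c(rnorm(3) * 0.02,
                                                 rnorm(3) * 2)))
  })
  cres <- registerCamera(case@volume, case@labelmap, 1, case@images, init,
                         optCfg = opt, renderCfg = rc)
  resEst <- registerPolyrigid(case@volume, case@labelmap,
                              images = case@images, cameras = cres$cameras,
                              optCfg = opt, renderCfg = rc)
  diceEst <- mean(warpedMaskDice(case@labelmap, resEst$field, case@gtField))

  # comparator: ground-truth cameras perturbed by <= 0.5 degree
  set.seed(12)
  pert <- lapply(case@cameras, function(cam) {
    setExtrinsic(cam, cam@extrinsic %*% expSE3(c(rnorm(3) * 0.005,
                                                 rnorm(3) * 0.3)))
  })
  resRef <- registerPolyrigid(case@volume, case@labelmap,
                              images = case@images, cameras = pert,
                              optCfg = opt, renderCfg = rc)
  diceRef <- mean(warpedMaskDice(case@labelmap, resRef$field, case@gtField))
  expect_gte(diceEst, diceRef - 0.02)
})
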