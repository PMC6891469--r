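test_that("forward model matches the direct-convolution oracle", {
  sys <- paperOptics()
  obj <- toyObject()          # 32 x 32 at half the camera pitch
  # equal grids (ratio 1): pure coherent low-pass filtering on axis
  objEq <- complexField(fieldData(obj), pixelPitchUm(sys))
  got <- simulateLRIntensity(objEq, sys, c(0, 0))
  want <- oracleLowpassIntensity(fieldData(objEq), pixelPitchUm(sys),
                                 sys@objectiveNA, sys@wavelengthUm)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("uniform objects image to flat bright field and empty dark field", {
  sys <- paperOptics()
  obj <- complexField(matrix(1 + 0i, 64, 64), pixelPitchUm(sys) / 2)
  bright <- simulateLRIntensity(obj, sys, c(0, 0))
  expect_equal(max(abs(bright - 1)), 0, tolerance = 1e-10)
  # wave vector beyond the pupil cutoff excludes the DC component entirely
  f <- c(cutoffFrequency(sys) * 1.6, 0)
  dark <- simulateLRIntensity(obj, sys, f)
  expect_lt(max(dark), 1e-20)
})

test_that("intensity factors are lognormal, median-1 and reproducible", {
  plan <- illuminationPlan(paperGeometry())
  f0 <- drawFactors(plan, sigma = 0, seed = 2)
  expect_equal(f0, rep(1, 961))
  f1 <- drawFactors(plan, sigma = 0.2, seed = 2)
  expect_identical(f1, drawFactors(plan, sigma = 0.2, seed = 2))
  expect_length(f1, 961)
  expect_true(all(f1 > 0))
  # median of 961 lognormal draws: 3 sigma Monte-Carlo band around 1
  expect_lt(abs(median(f1) - 1), 3 * 0.2 * 1.2533 / sqrt(961))
})

test_that("stack simulation is linear in exposure and flags saturation", {
  sys <- paperOptics()
  geom <- toyGeometry()
  obj <- toyObject()
  cam <- idealCameraModel(photonBudget = 20)  # far from full well
  p1 <- illuminationPlan(geom, ringMap = c(100, 100))
  p2 <- illuminationPlan(geom, ringMap = c(200, 200))
  s1 <- simulateStack(obj, sys, geom, p1, cam = cam, seed = 1)
  s2 <- simulateStack(obj, sys, geom, p2, cam = cam, seed = 1)
  for (i in seq_len(length(s1)))
    expect_equal(stackImages(s2)[[i]], 2 * stackImages(s1)[[i]],
                 tolerance = 1e-12)
  # photon budget pushing expected codes past full scale clips and flags
  hot <- idealCameraModel(photonBudget = 1e5)
  sHot <- simulateStack(obj, sys, geom, p1, cam = hot, seed = 1)
  i0 <- which(stackMeta(sHot)$m == 0 & stackMeta(sHot)$n == 0)
  sat <- stackSatMask(sHot)[[i0]]
  expect_gt(sum(sat), 0)
  expect_true(all(stackImages(sHot)[[i0]][sat] == 2^hot@bitDepth - 1))
})

test_that("normalization inverts the radiometric scaling", {
  sys <- paperOptics()
  geom <- toyGeometry()
  obj <- toyObject()
  cam <- idealCameraModel(photonBudget = 100)  # no clipping at 700 ms either
  plan <- illuminationPlan(geom, ringMap = c(100, 100))
  st <- normalizeStack(simulateStack(obj, sys, geom, plan, cam = cam, seed = 1),
                       cam)
  e <- stackMeta(st)
  for (i in seq_len(length(st))) {
    f <- waveVector(e$m[i], e$n[i], geom, sys)
    ideal <- simulateLRIntensity(obj, sys, f)
    unsat <- !stackSatMask(st)[[i]]
    expect_equal(stackImages(st)[[i]][unsat], ideal[unsat], tolerance = 1e-9)
  }
  # same LED at 100 ms and 700 ms: identical after normalization
  planLong <- illuminationPlan(geom, ringMap = c(700, 700))
  stLong <- normalizeStack(
    simulateStack(obj, sys, geom, planLong, cam = cam, seed = 1), cam)
  expect_equal(stackImages(stLong)[[1]], stackImages(st)[[1]],
               tolerance = 1e-9)
  # saturation flags survive normalization
  hot <- idealCameraModel(photonBudget = 1e5)
  sHot <- simulateStack(obj, sys, geom, plan, cam = hot, seed = 1)
  nHot <- normalizeStack(sHot, hot)
  expect_identical(stackSatMask(nHot), stackSatMask(sHot))
  # missing metadata is an error
  broken <- sHot
  broken@meta$exposure_ms <- NULL
  expect_error(normalizeStack(broken, hot), "exposure_ms")
})

test_that("photon conservation holds per entry in the noiseless limit", {
  sys <- paperOptics()
  geom <- toyGeometry()
  obj <- toyObject()
  cam <- idealCameraModel(photonBudget = 100)   # unclipped
  plan <- illuminationPlan(geom, ringMap = c(100, 100))
  factors <- drawFactors(plan, sigma = 0.3, seed = 9)
  st <- normalizeStack(
    simulateStack(obj, sys, geom, plan, factors, cam, seed = 1), cam)
  e <- stackMeta(st)
  for (i in seq_len(length(st))) {
    f <- waveVector(e$m[i], e$n[i], geom, sys)
    ideal <- simulateLRIntensity(obj, sys, f)
    expect_equal(mean(stackImages(st)[[i]]), mean(ideal) * factors[i],
                 tolerance = 1e-9)
  }
})

test_that("bright-field images dominate dark-field ones for a uniform object", {
  sys <- paperOptics()
  geom <- ledArrayGeometry(halfExtent = 5L)
  obj <- complexField(matrix(1 + 0i, 64, 64), pixelPitchUm(sys) / 2)
  plan <- illuminationPlan(geom, ringMap = rep(100, 6))
  st <- normalizeStack(simulateStack(obj, sys, geom, plan, cam = cameraModel(),
                                     seed = 3), cameraModel())
  e <- stackMeta(st)
  cutoff <- cutoffFrequency(sys)
  fmag <- vapply(seq_len(nrow(e)), function(i)
    sqrt(sum(waveVector(e$m[i], e$n[i], geom, sys)^2)), 0)
  means <- vapply(stackImages(st), mean, 0)
  expect_gt(mean(means[fmag < cutoff]), 10 * mean(means[fmag > cutoff]))
})

test_that("full-array plan renders 961 images", {
  sys <- paperOptics()
  geom <- paperGeometry()
  obj <- complexField(matrix(1 + 0i, 64, 64), pixelPitchUm(sys) / 4)
  plan <- illuminationPlan(geom)
  st <- simulateStack(obj, sys, geom, plan, cam = idealCameraModel(), seed = 1)
  expect_equal(length(st), 961)
  expect_true(validObject(st))
})
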