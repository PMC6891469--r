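test_that("line profiles interpolate, reverse and stay in bounds", {
  img <- matrix(3, 32, 32)
  p <- lineProfile(img, 1, c(-10, 0), c(10, 0), 50)
  expect_equal(p, rep(3, 50))
  set.seed(3)
  img2 <- matrix(runif(32 * 32), 32, 32)
  fwd <- lineProfile(img2, 1, c(-8, -5), c(9, 6), 41)
  rev <- lineProfile(img2, 1, c(9, 6), c(-8, -5), 41)
  expect_equal(fwd, base::rev(rev))
  expect_error(lineProfile(img2, 1, c(0, 0), c(40, 0)), "outside")
})

test_that("profiles across bar targets oscillate at the bar period", {
  period <- 4
  tgt <- barTarget(period, 6, "vertical", 128L, 0.5)
  prof <- lineProfile(amplitude(tgt)^2, 0.5, c(-16, 0), c(16, 0), 256)
  sp <- Mod(stats::fft(prof - mean(prof)))[1:128]
  peak <- which.max(sp) - 1
  # profile spans 32 um: the bar period of 4 um sits at 8 cycles per span
  expect_lte(abs(peak - 8), 1)
})

test_that("resolvability implements the Michelson-contrast criterion", {
  expect_false(resolvable(rep(1, 100), 3))
  square <- rep(rep(c(1, 0), each = 10), 4)
  expect_true(resolvable(square, 4, minContrast = 0.99))
  expect_true(resolvable(1 - square, 4, minContrast = 0.99,
                         feature = "valleys"))
  # monotone: raising the threshold never flips false -> true
  set.seed(9)
  for (rep in 1:20) {
    prof <- abs(stats::filter(rnorm(120), rep(1, 5), circular = TRUE))
    thresholds <- c(0.05, 0.2, 0.5, 0.8)
    r <- vapply(thresholds, function(t) resolvable(prof, 3, t), NA)
    expect_true(all(diff(as.integer(r)) <= 0))
  }
})

test_that("bars below the coherent cutoff are unresolved in a raw image", {
  sys <- paperOptics()
  # 2.15 um bars vs the lambda/NA = 6.33 um coherent cutoff
  tgt <- barTarget(1000 / 465, 3, "vertical", 128L, pixelPitchUm(sys) / 2)
  lr <- simulateLRIntensity(tgt, sys, c(0, 0))
  prof <- lineProfile(lr, pixelPitchUm(sys), c(-5, 0), c(5, 0), 80)
  expect_false(resolvable(prof, 3, 0.2, feature = "valleys"))
})

test_that("smallest resolved period reads charts correctly", {
  chart <- defaultChart(c(6.6, 4.4, 2.19, 1.6), 192L, 0.575)
  # a perfect (unimaged) chart resolves its finest element
  expect_equal(smallestResolvedPeriod(chart, chartElements(chart)), 1.6)
  single <- defaultChart(8, 128L, 0.575)
  expect_equal(smallestResolvedPeriod(single, chartElements(single)), 8)
  expect_error(smallestResolvedPeriod(chart, chartElements(chart)[0, ]),
               "no elements")
})

test_that("resolution improves monotonically with illumination NA", {
  sys <- paperOptics()
  k <- 3L
  chart <- defaultChart(c(6.6, 3.6), 96L, pixelPitchUm(sys) / k)
  cam <- idealCameraModel()
  resolved <- vapply(c(0L, 4L, 9L), function(h) {
    geom <- ledArrayGeometry(halfExtent = h)
    plan <- illuminationPlan(geom)
    st <- normalizeStack(
      simulateStack(chart, sys, geom, plan, cam = cam, seed = 21), cam)
    res <- fpmReconstruct(st, sys, geom,
                          reconConfig(upsamplingFactor = k, maxSweeps = 6L,
                                      relTol = 0))
    smallestResolvedPeriod(hrField(res), chartElements(chart), 0.2)
  }, 0)
  expect_true(all(diff(resolved) <= 0))
  expect_lt(resolved[3], resolved[1])
})

test_that("background ripple is zero for flat fields and grows with noise", {
  flat <- matrix(2, 32, 32)
  region <- matrix(TRUE, 32, 32)
  expect_equal(backgroundRipple(flat, region), 0)
  set.seed(5)
  noisy <- flat + matrix(rnorm(32 * 32, 0, 0.1), 32, 32)
  expect_gt(backgroundRipple(noisy, region), 0)
  noisier <- flat + matrix(rnorm(32 * 32, 0, 0.4), 32, 32)
  expect_gt(backgroundRipple(noisier, region), backgroundRipple(noisy, region))
  expect_error(backgroundRipple(flat, matrix(FALSE, 32, 32)), "empty")
})

test_that("complex RMSE is gauge-invariant and detects differences", {
  set.seed(7)
  a <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  expect_equal(rmseComplex(a, a), 0, tolerance = 1e-12)
  expect_equal(rmseComplex(a * exp(1.3i), a), 0, tolerance = 1e-12)
  expect_equal(rmseComplex(2 * a, a), 0, tolerance = 1e-12)
  b <- a + 0.5
  r <- rmseComplex(b, a)
  expect_gt(r, 0)
  # simultaneous global phase/scale of both arguments leaves the error fixed
  expect_equal(rmseComplex(b * 3 * exp(0.4i), a * 3 * exp(0.4i)), r,
               tolerance = 1e-10)
  expect_error(rmseComplex(a, matrix(0 + 0i, 4, 4)), "equal shapes")
})
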