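# Shared fixtures. The acceptance-scale experiment (rings 0-9 of the platform
# geometry, 64 x 64 camera patch, lognormal sigma 0.2 brightness factors) is
# computed once and memoized across test files.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

paperOptics <- function() opticalSystem()
paperGeometry <- function() ledArrayGeometry()

# Tiny 3 x 3 LED geometry with exaggerated pitch so sub-aperture centers land
# on distinct bins of a 32 x 32 HR grid (16 x 16 camera patch, ratio 2).
toyGeometry <- function() ledArrayGeometry(halfExtent = 1L, pitchMm = 12.5,
                                           standoffMm = 90)

toyObject <- function(seed = 5L) {
  sys <- paperOptics()
  phaseObject(featureScaleUm = 8, maxPhaseRad = 0.8, shape = 32L,
              pitchUm = pixelPitchUm(sys) / 2, seed = seed)
}

toyStack <- function(seed = 5L, cam = idealCameraModel(), factors = NULL) {
  sys <- paperOptics()
  geom <- toyGeometry()
  plan <- illuminationPlan(geom, ringMap = c(100, 100))
  st <- simulateStack(toyObject(seed), sys, geom, plan, factors, cam,
                      seed = seed + 1L)
  normalizeStack(st, cam)
}

# The scaled-down reproduction of the platform's resolution experiment:
# 19 x 19 LEDs (rings 0-9), 64 x 64 camera patch, chart with elements at
# 6.6 / 4.4 / 2.19 / 1.6 um, lognormal sigma 0.2 factors, 10 sweeps.
acceptanceChart <- function() {
  memo("chart", defaultChart(c(6.6, 4.4, 2.19, 1.6), 192L,
                             pixelPitchUm(paperOptics()) / 3))
}

acceptanceRun <- function(noisy) {
  key <- if (noisy) "runNoisy" else "runClean"
  memo(key, {
    sys <- paperOptics()
    geom <- ledArrayGeometry(halfExtent = 9L)
    plan <- illuminationPlan(geom)
    chart <- acceptanceChart()
    factors <- drawFactors(plan, sigma = 0.2, seed = 101L)
    cam <- if (noisy) cameraModel() else idealCameraModel()
    stack <- normalizeStack(
      simulateStack(chart, sys, geom, plan, factors, cam, seed = 102L), cam)
    cfg <- reconConfig(upsamplingFactor = 3L, maxSweeps = 10L, relTol = 0,
                       seed = 103L)
    resSA <- fpmReconstruct(stack, sys, geom, cfg, saConfig(enabled = TRUE))
    res0 <- if (noisy) NULL else
      fpmReconstruct(stack, sys, geom, cfg, saConfig(enabled = FALSE))
    list(sys = sys, geom = geom, plan = plan, chart = chart,
         factors = factors, stack = stack, resSA = resSA, res0 = res0)
  })
}
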