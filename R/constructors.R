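#' Construct an optical system
#'
#' Defaults describe a 2x telecentric objective of NA 0.1 with a 3.45 um,
#' 50 dB industrial camera under 633 nm LED illumination.
#'
#' @param wavelengthUm illumination wavelength (um)
#' @param objectiveNA objective numerical aperture
#' @param magnification lateral magnification
#' @param cameraPixelUm camera pixel pitch (um)
#' @param bitDepth nominal ADC bit depth
#' @param dynamicRangeDb nominal dynamic range (dB)
#' @param sensorShape sensor (rows, cols) in pixels
#' @return an [OpticalSystem-class]
#' @examples
#' sys <- opticalSystem()
#' pixelPitchUm(sys)    # 1.725 um object-space sampling
#' cutoffFrequency(sys) # 0.158 cycles/um pupil cutoff
#' @export
opticalSystem <- function(wavelengthUm = 0.633, objectiveNA = 0.1,
                          magnification = 2, cameraPixelUm = 3.45,
                          bitDepth = 10L, dynamicRangeDb = 50,
                          sensorShape = c(1536L, 2048L)) {
  new("OpticalSystem", wavelengthUm = wavelengthUm, objectiveNA = objectiveNA,
      magnification = magnification, cameraPixelUm = cameraPixelUm,
      bitDepth = as.integer(bitDepth), dynamicRangeDb = dynamicRangeDb,
      sensorShape = as.integer(sensorShape))
}

#' Object-space pixel pitch of the camera grid (um)
#' @param sys an [OpticalSystem-class]
#' @export
pixelPitchUm <- function(sys) sys@cameraPixelUm / sys@magnification

#' Coherent pupil cutoff frequency NA/lambda (cycles/um)
#' @param sys an [OpticalSystem-class]
#' @export
cutoffFrequency <- function(sys) sys@objectiveNA / sys@wavelengthUm

#' Construct an LED array geometry
#'
#' Defaults are a 31 x 31 array at 2.5 mm pitch, 93 mm from the sample,
#' perfectly aligned.
#'
#' @param halfExtent indices run -halfExtent..halfExtent per axis
#' @param pitchMm LED pitch (mm)
#' @param standoffMm sample-to-array distance (mm)
#' @param offsetMm length-2 lateral misalignment (mm)
#' @param rollDeg in-plane rotation (degrees)
#' @return a [LEDArrayGeometry-class]
#' @export
ledArrayGeometry <- function(halfExtent = 15L, pitchMm = 2.5, standoffMm = 93,
                             offsetMm = c(0, 0), rollDeg = 0) {
  new("LEDArrayGeometry", halfExtent = as.integer(halfExtent),
      pitchMm = pitchMm, standoffMm = standoffMm,
      offsetMm = as.numeric(offsetMm), rollDeg = rollDeg)
}

#' Number of LEDs in the array
#' @param geom a [LEDArrayGeometry-class]
#' @export
ledCount <- function(geom) (2L * geom@halfExtent + 1L)^2L

#' Construct a camera model
#'
#' Defaults emulate a 10-bit industrial sensor with 1e5 e- full well
#' (full-scale shot-noise SNR ~316, i.e. ~50 dB), 50 e- read noise, and a
#' photon budget placing a unit-intensity pixel at ~70% of full well for the
#' 100 ms central-ring exposure.
#'
#' @param photonBudget expected photoelectrons per (ms x duty) at unit
#'   ideal intensity
#' @param readNoiseE read noise, electrons RMS
#' @param bitDepth ADC bit depth
#' @param fullWell full-well capacity (electrons)
#' @param shotNoise apply Poisson shot noise
#' @param quantize round digital codes to integers
#' @return a [CameraModel-class]
#' @export
cameraModel <- function(photonBudget = 700, readNoiseE = 50, bitDepth = 10L,
                        fullWell = 1e5, shotNoise = TRUE, quantize = TRUE) {
  new("CameraModel", photonBudget = photonBudget, readNoiseE = readNoiseE,
      bitDepth = as.integer(bitDepth), fullWell = fullWell,
      shotNoise = shotNoise, quantize = quantize)
}

#' Noise-free camera model
#'
#' Same radiometric chain as [cameraModel()] but without shot noise, read
#' noise or quantization; clipping at full scale is retained. Useful for
#' algorithm-consistency experiments.
#' @param ... overrides passed to [cameraModel()]
#' @export
idealCameraModel <- function(...) {
  cameraModel(readNoiseE = 0, shotNoise = FALSE, quantize = FALSE, ...)
}

#' Construct a complex field
#' @param data complex (or numeric) square matrix with even side
#' @param pixelPitchUm object-space pixel pitch (um)
#' @return a [ComplexField-class]
#' @export
complexField <- function(data, pixelPitchUm) {
  storage.mode(data) <- "complex"
  new("ComplexField", data = data, pixelPitchUm = pixelPitchUm)
}

#' Amplitude of a complex field
#' @param field a [ComplexField-class]
#' @export
amplitude <- function(field) Mod(field@data)

#' Phase of a complex field (radians in (-pi, pi])
#' @param field a [ComplexField-class]
#' @export
phaseMap <- function(field) Arg(field@data)

#' Intensity (squared amplitude) of a complex field
#' @param field a [ComplexField-class]
#' @export
intensity <- function(field) Mod(field@data)^2

#' Field data as a complex matrix
#' @param field a [ComplexField-class]
#' @export
fieldData <- function(field) field@data

#' Reconstruction configuration
#' @param upsamplingFactor HR grid side / LR side; `NA` = auto (Nyquist for
#'   the synthetic aperture)
#' @param maxSweeps maximum sweeps over the LED set
#' @param relTol relative convergence tolerance on the data-fidelity cost
#' @param updateOrder "center_out_spiral" or "raster"
#' @param seed integer seed for stochastic components
#' @return a [ReconConfig-class]
#' @export
reconConfig <- function(upsamplingFactor = NA_integer_, maxSweeps = 10L,
                        relTol = 1e-3, updateOrder = "center_out_spiral",
                        seed = 1L) {
  new("ReconConfig", upsamplingFactor = as.integer(upsamplingFactor),
      maxSweeps = as.integer(maxSweeps), relTol = relTol,
      updateOrder = updateOrder, seed = as.integer(seed))
}

#' Simulated-annealing configuration
#' @param enabled logical; disable to run conventional FPM
#' @param tInitial initial temperature (`NA` = auto from first-sweep proposals)
#' @param cooling geometric cooling per sweep, in (0, 1)
#' @param proposalsPerVisit proposals per LED visit
#' @param proposalWidth half-width of the uniform log-scale step
#' @param tFloor temperature floor
#' @return a [SAConfig-class]
#' @export
saConfig <- function(enabled = TRUE, tInitial = NA_real_, cooling = 0.9,
                     proposalsPerVisit = 3L, proposalWidth = 0.1,
                     tFloor = 1e-12) {
  new("SAConfig", enabled = enabled, tInitial = tInitial, cooling = cooling,
      proposalsPerVisit = as.integer(proposalsPerVisit),
      proposalWidth = proposalWidth, tFloor = tFloor)
}

setMethod("show", "OpticalSystem", function(object) {
  cat("OpticalSystem: lambda", object@wavelengthUm, "um, NA",
      object@objectiveNA, ", mag", object@magnification, "x\n")
  cat("  camera pixel", object@cameraPixelUm, "um (object-space",
      pixelPitchUm(object), "um),", object@bitDepth, "bit,",
      object@dynamicRangeDb, "dB\n")
  cat("  pupil cutoff", signif(cutoffFrequency(object), 4), "cycles/um\n")
})

setMethod("show", "LEDArrayGeometry", function(object) {
  n <- 2L * object@halfExtent + 1L
  cat("LEDArrayGeometry:", n, "x", n, "LEDs, pitch", object@pitchMm,
      "mm, standoff", object@standoffMm, "mm\n")
  if (any(object@offsetMm != 0) || object@rollDeg != 0)
    cat("  misalignment: offset (", object@offsetMm[1], ",",
        object@offsetMm[2], ") mm, roll", object@rollDeg, "deg\n")
})

setMethod("show", "IlluminationPlan", function(object) {
  e <- object@entries
  cat("IlluminationPlan:", nrow(e), "LEDs, exposures {",
      paste(sort(unique(e$exposure_ms)), collapse = ", "), "} ms\n")
})

setMethod("show", "ComplexField", function(object) {
  cat(class(object), ":", nrow(object@data), "x", ncol(object@data),
      "complex field, pitch", object@pixelPitchUm, "um\n")
})

setMethod("show", "LRStack", function(object) {
  shp <- if (length(object@images)) dim(object@images[[1]]) else c(0, 0)
  cat("LRStack:", length(object@images), "images of", shp[1], "x", shp[2],
      if (object@normalized) "(normalized)" else "(raw codes)", "\n")
})

setMethod("show", "ReconResult", function(object) {
  cat("ReconResult:", nrow(object@hrSpectrum), "x", ncol(object@hrSpectrum),
      "HR field,", object@sweeps, "sweeps, final cost",
      signif(utils::tail(object@trace, 1), 4), "\n")
})

#' @export
setMethod("length", "LRStack", function(x) length(x@images))

#' Per-image metadata of a stack
#' @param stack an [LRStack-class]
#' @export
stackMeta <- function(stack) stack@meta

#' Images of a stack as a list of matrices
#' @param stack an [LRStack-class]
#' @export
stackImages <- function(stack) stack@images

#' Saturation masks of a stack
#' @param stack an [LRStack-class]
#' @export
stackSatMask <- function(stack) stack@satMask

#' Plan entries as a data.frame
#' @param plan an [IlluminationPlan-class]
#' @export
planEntries <- function(plan) plan@entries

#' Recovered HR field of a reconstruction
#' @param res a [ReconResult-class]
#' @export
hrField <- function(res) res@hrField

#' Recovered per-image intensity factors
#' @param res a [ReconResult-class]
#' @export
reconFactors <- function(res) res@factors

#' Per-sweep data-fidelity cost trace
#' @param res a [ReconResult-class]
#' @export
reconTrace <- function(res) res@trace

#' Chart element metadata
#' @param chart a [ResolutionChart-class]
#' @export
chartElements <- function(chart) chart@elements
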