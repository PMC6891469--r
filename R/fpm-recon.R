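# Alternating-projection FPM reconstruction: iterative sub-aperture
# amplitude-replacement stitching in Fourier space. For each LED the current
# HR spectrum is windowed at the illumination wave vector and masked by the
# pupil; the resulting model image keeps its phase but takes the measured
# amplitude; the corrected sub-spectrum is written back. Sweeping all LEDs
# repeatedly until self-consistency synthesizes an aperture of
# (objective NA + illumination NA).

# Choose the HR grid: Nyquist for the synthetic aperture unless forced.
chooseUpsampling <- function(sys, geom, nLr, cfg) {
  if (!is.na(cfg@upsamplingFactor)) return(cfg@upsamplingFactor)
  naSyn <- sys@objectiveNA + illuminationNA(geom, "radial")
  hrPitchMax <- sys@wavelengthUm / (2 * naSyn)
  max(2L, as.integer(ceiling(pixelPitchUm(sys) / hrPitchMax)))
}

#' Initialize the HR spectrum from the on-axis image
#'
#' Spectrum of the band-limited upsampled square root of the normalized
#' on-axis intensity (zero phase): the spectrum of sqrt(I) on the LR grid is
#' embedded at the center of the HR grid. Falls back to the stack mean (with a
#' message) when no on-axis image is present. Deterministic.
#'
#' @param stack a normalized [LRStack-class]
#' @param upsamplingFactor integer >= 1
#' @return list(spectrum = complex matrix, dk = frequency spacing cycles/um)
#' @export
initializeSpectrum <- function(stack, upsamplingFactor) {
  e <- stack@meta
  i0 <- which(e$m == 0L & e$n == 0L)
  img <- if (length(i0) == 1L) {
    stack@images[[i0]]
  } else {
    message("no on-axis image in stack; initializing from the stack mean")
    Reduce(`+`, stack@images) / length(stack@images)
  }
  nLr <- nrow(img)
  nHr <- nLr * as.integer(upsamplingFactor)
  sLr <- ft2(matrix(as.complex(sqrt(pmax(img, 0))), nLr, nLr))
  spec <- matrix(0 + 0i, nHr, nHr)
  rows <- windowIndices(nHr, nLr, 0L)
  spec[rows, rows] <- sLr * (nHr / nLr)^2
  # HR pitch = LR pitch / factor, so dk = 1 / (nHr * hrPitch) = 1 / (nLr * lrPitch)
  list(spectrum = spec, dk = 1 / (nLr * stack@pixelPitchUm))
}

#' Extract one sub-aperture as a low-resolution complex image
#'
#' Windows the DC-centered HR spectrum at the bin nearest `fLed / dk`, masks
#' it with the pupil and inverse-transforms to the LR grid. Normalization is
#' such that a spectrum produced from a unit-amplitude field yields a
#' unit-amplitude image on axis.
#'
#' @param spec complex HR spectrum (DC centered)
#' @param dk frequency spacing of the spectrum (cycles/um)
#' @param fLed illumination wave vector (fx, fy), cycles/um
#' @param pupil a [PupilMask-class] on the LR grid
#' @return complex LR image
#' @export
extractSubaperture <- function(spec, dk, fLed, pupil) {
  nHr <- nrow(spec)
  nLr <- nrow(pupil@mask)
  rows <- windowIndices(nHr, nLr, freqToBin(fLed[[2]], dk))
  cols <- windowIndices(nHr, nLr, freqToBin(fLed[[1]], dk))
  if (is.null(rows) || is.null(cols))
    stop("shifted pupil for wave vector (", signif(fLed[[1]], 4), ", ",
         signif(fLed[[2]], 4), ") cycles/um exceeds the HR grid; increase ",
         "the upsampling factor")
  ift2(spec[rows, cols] * pupil@mask, norm = nHr^2)
}

#' Amplitude replacement (phase-retrieval projection)
#'
#' Keeps the model's phase and substitutes the measured amplitude:
#' `sqrt(measured) * exp(i * arg(model))`. Saturated pixels keep the model
#' value (they carry no radiometric information); pixels where the model is 0
#' take phase 0.
#'
#' @param modelLr model complex image
#' @param measured measured intensity image (>= 0)
#' @param satMask logical saturation mask or NULL
#' @return complex image with the measured amplitude
#' @export
amplitudeReplace <- function(modelLr, measured, satMask = NULL) {
  if (any(measured < 0)) stop("measured intensity must be >= 0")
  m <- Mod(modelLr)
  phase <- modelLr
  nz <- m > 0
  phase[nz] <- modelLr[nz] / m[nz]
  phase[!nz] <- 1 + 0i                     # zero model -> phase 0 convention
  out <- sqrt(measured) * phase
  if (!is.null(satMask)) out[satMask] <- modelLr[satMask]
  out
}

#' Write an updated low-resolution image back into the HR spectrum
#'
#' Transforms the updated LR image, masks it with the pupil and overwrites the
#' corresponding window of the spectrum at pixels inside the pupil support;
#' pixels outside the pupil are unchanged.
#'
#' @param spec complex HR spectrum (DC centered)
#' @param updatedLr updated complex LR image
#' @param fLed illumination wave vector (fx, fy), cycles/um
#' @param pupil a [PupilMask-class] on the LR grid
#' @param dk frequency spacing (cycles/um)
#' @return the updated spectrum
#' @export
updateSpectrum <- function(spec, updatedLr, fLed, pupil, dk) {
  nHr <- nrow(spec)
  nLr <- nrow(updatedLr)
  rows <- windowIndices(nHr, nLr, freqToBin(fLed[[2]], dk))
  cols <- windowIndices(nHr, nLr, freqToBin(fLed[[1]], dk))
  if (is.null(rows) || is.null(cols))
    stop("shifted pupil for wave vector (", signif(fLed[[1]], 4), ", ",
         signif(fLed[[2]], 4), ") cycles/um exceeds the HR grid")
  w <- ft2(updatedLr) * (nHr / nLr)^2
  sub <- spec[rows, cols]
  inside <- pupil@mask > 0
  sub[inside] <- w[inside]
  spec[rows, cols] <- sub
  spec
}

#' FPM reconstruction with optional SA intensity correction
#'
#' Runs repeated sweeps over all LEDs; each visit extracts the model
#' sub-aperture image, (optionally) refines the image's intensity factor by
#' simulated annealing, replaces the amplitude with the factor-corrected
#' measurement and writes the sub-spectrum back. Stops after `maxSweeps`
#' sweeps or when the relative change of the data-fidelity cost (mean over
#' LEDs of the relative L2 amplitude residual) falls below `relTol`.
#'
#' @param stack a normalized [LRStack-class]
#' @param sys an [OpticalSystem-class]
#' @param geom a [LEDArrayGeometry-class]
#' @param cfg a [ReconConfig-class]
#' @param sa an [SAConfig-class]; `saConfig(enabled = FALSE)` (or NULL) runs
#'   conventional FPM
#' @return a [ReconResult-class]
#' @examples
#' \donttest{
#' sys <- opticalSystem(sensorShape = c(64L, 64L))
#' geom <- ledArrayGeometry(halfExtent = 4L, pitchMm = 12, standoffMm = 90)
#' plan <- illuminationPlan(geom, ringMap = rep(100, 5))
#' obj <- phaseObject(12, 1, 128L, pixelPitchUm(sys) / 2, seed = 7)
#' stack <- simulateStack(obj, sys, geom, plan, cam = idealCameraModel())
#' res <- fpmReconstruct(normalizeStack(stack, idealCameraModel()), sys, geom,
#'                       reconConfig(upsamplingFactor = 2L))
#' }
#' @export
fpmReconstruct <- function(stack, sys, geom, cfg = reconConfig(), sa = NULL) {
  if (!stack@normalized)
    stop("stack must be normalized first (see normalizeStack)")
  if (is.null(sa)) sa <- saConfig(enabled = FALSE)
  e <- stack@meta
  nLr <- nrow(stack@images[[1]])
  k <- chooseUpsampling(sys, geom, nLr, cfg)
  init <- initializeSpectrum(stack, k)
  spec <- init$spectrum
  dk <- init$dk
  pupil <- pupilMask(sys, c(nLr, nLr), dk)
  fLed <- lapply(seq_len(nrow(e)),
                 function(i) waveVector(e$m[i], e$n[i], geom, sys))
  ord <- switch(cfg@updateOrder,
    center_out_spiral = order(pmax(abs(e$m), abs(e$n)), atan2(e$n, e$m)),
    raster = order(e$n, e$m))
  onAxis <- which(e$m == 0L & e$n == 0L)
  factors <- rep(1, nrow(e))
  set.seed(cfg@seed)
  temperature <- sa@tInitial
  trace <- numeric(0)
  for (sweep in seq_len(cfg@maxSweeps)) {
    num <- 0; den <- 0
    warmDeltas <- numeric(0)
    for (i in ord) {
      model <- extractSubaperture(spec, dk, fLed[[i]], pupil)
      meas <- stack@images[[i]]
      sat <- stack@satMask[[i]]
      if (!any(sat)) sat <- NULL
      if (sa@enabled && !(i %in% onAxis)) {
        ref <- saRefineFactor(factors[i], meas, model, sat, temperature, sa)
        factors[i] <- ref$c
        if (is.na(temperature)) warmDeltas <- c(warmDeltas, ref$deltas)
      }
      target <- applyFactor(meas, factors[i])
      sqm <- sqrt(pmax(target, 0))
      resid <- sqm - Mod(model)
      if (!is.null(sat)) { resid[sat] <- 0; sqm[sat] <- 0 }
      num <- num + sqrt(sum(resid^2))
      den <- den + sqrt(sum(sqm^2))
      updated <- amplitudeReplace(model, pmax(target, 0), sat)
      spec <- updateSpectrum(spec, updated, fLed[[i]], pupil, dk)
    }
    cost <- num / max(den, .Machine$double.eps)
    if (!is.finite(cost))
      stop("reconstruction diverged: non-finite data-fidelity cost at sweep ",
           sweep)
    trace <- c(trace, cost)
    if (sa@enabled) {
      if (is.na(temperature)) {
        temperature <- max(stats::median(warmDeltas), sa@tFloor)
      } else {
        temperature <- max(temperature * sa@cooling, sa@tFloor)
      }
    }
    if (sweep > 1L) {
      prev <- trace[sweep - 1L]
      if (abs(prev - cost) <= cfg@relTol * max(prev, .Machine$double.eps))
        break
    }
  }
  hrPitch <- stack@pixelPitchUm / k
  field <- complexField(ift2(spec, norm = length(spec)), hrPitch)
  new("ReconResult", hrField = field, hrSpectrum = spec, dk = dk,
      factors = factors, trace = trace, sweeps = length(trace))
}
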