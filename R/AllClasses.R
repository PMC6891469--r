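#' @import methods
NULL

#' Optical system description
#'
#' Wavelength, objective numerical aperture, magnification and camera pixel
#' pitch of a coherent imaging platform. The objective is modelled as an ideal
#' circular pupil of cutoff frequency `NA / lambda` (cycles/um); the
#' object-space sampling of the camera is `camera_pixel / magnification`.
#'
#' @slot wavelengthUm illumination wavelength (um)
#' @slot objectiveNA objective numerical aperture, in (0, 1)
#' @slot magnification lateral magnification (> 0)
#' @slot cameraPixelUm physical camera pixel pitch (um)
#' @slot bitDepth nominal ADC bit depth (>= 8)
#' @slot dynamicRangeDb nominal sensor dynamic range (dB)
#' @slot sensorShape sensor size as (rows, cols) in pixels
#' @name OpticalSystem-class
#' @rdname OpticalSystem
#' @exportClass OpticalSystem
setClass("OpticalSystem",
  representation(
    wavelengthUm = "numeric",
    objectiveNA = "numeric",
    magnification = "numeric",
    cameraPixelUm = "numeric",
    bitDepth = "integer",
    dynamicRangeDb = "numeric",
    sensorShape = "integer"
  )
)

setValidity("OpticalSystem", function(object) {
  msg <- character()
  if (!(object@wavelengthUm > 0)) msg <- c(msg, "wavelengthUm must be > 0")
  if (!(object@objectiveNA > 0 && object@objectiveNA < 1))
    msg <- c(msg, "objectiveNA must lie in (0, 1)")
  if (!(object@magnification > 0)) msg <- c(msg, "magnification must be > 0")
  if (!(object@cameraPixelUm > 0)) msg <- c(msg, "cameraPixelUm must be > 0")
  if (object@bitDepth < 8L) msg <- c(msg, "bitDepth must be >= 8")
  if (object@dynamicRangeDb < 0) msg <- c(msg, "dynamicRangeDb must be >= 0")
  if (length(object@sensorShape) != 2L || any(object@sensorShape < 1L))
    msg <- c(msg, "sensorShape must be two positive integers")
  if (length(msg)) msg else TRUE
})

#' LED array geometry
#'
#' Square LED grid indexed by (m, n) with `|m|, |n| <= halfExtent`, placed at
#' `standoffMm` below the sample plane. Lateral misalignment (`offsetMm`) and
#' in-plane rotation (`rollDeg`) can be injected to emulate imperfect
#' alignment.
#'
#' @slot halfExtent integer; indices run -halfExtent..halfExtent
#' @slot pitchMm LED pitch (mm)
#' @slot standoffMm sample-to-array distance (mm)
#' @slot offsetMm length-2 lateral misalignment (mm)
#' @slot rollDeg in-plane rotation of the array (degrees)
#' @name LEDArrayGeometry-class
#' @rdname LEDArrayGeometry
#' @exportClass LEDArrayGeometry
setClass("LEDArrayGeometry",
  representation(
    halfExtent = "integer",
    pitchMm = "numeric",
    standoffMm = "numeric",
    offsetMm = "numeric",
    rollDeg = "numeric"
  )
)

setValidity("LEDArrayGeometry", function(object) {
  msg <- character()
  if (object@halfExtent < 0L) msg <- c(msg, "halfExtent must be >= 0")
  if (!(object@pitchMm > 0)) msg <- c(msg, "pitchMm must be > 0")
  if (!(object@standoffMm > 0)) msg <- c(msg, "standoffMm must be > 0")
  if (length(object@offsetMm) != 2L) msg <- c(msg, "offsetMm must have length 2")
  if (length(msg)) msg else TRUE
})

#' Illumination plan
#'
#' Ordered LED firing sequence with per-entry exposure time and PWM duty
#' cycle. Entries are stored as a data.frame with columns `m`, `n`,
#' `exposure_ms`, `duty_cycle`.
#'
#' @slot entries data.frame(m, n, exposure_ms, duty_cycle)
#' @name IlluminationPlan-class
#' @rdname IlluminationPlan
#' @exportClass IlluminationPlan
setClass("IlluminationPlan", representation(entries = "data.frame"))

setValidity("IlluminationPlan", function(object) {
  e <- object@entries
  need <- c("m", "n", "exposure_ms", "duty_cycle")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(paste(e$m, e$n))) msg <- c(msg, "LED indices must be unique")
  if (any(e$exposure_ms <= 0)) msg <- c(msg, "exposure_ms must be > 0")
  if (any(e$duty_cycle <= 0 | e$duty_cycle > 1))
    msg <- c(msg, "duty_cycle must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pupil mask on a centered frequency grid
#'
#' Binary circular low-pass filter of the objective: weight 1 at frequencies
#' strictly inside the cutoff radius `NA / lambda`, 0 outside (hard disk, no
#' apodization). The DC bin sits at matrix index (n/2 + 1, n/2 + 1).
#'
#' @slot mask numeric matrix of weights in [0, 1]
#' @slot dk frequency grid spacing (cycles/um)
#' @slot cutoff pupil cutoff frequency (cycles/um)
#' @name PupilMask-class
#' @rdname PupilMask
#' @exportClass PupilMask
setClass("PupilMask",
  representation(mask = "matrix", dk = "numeric", cutoff = "numeric"))

setValidity("PupilMask", function(object) {
  msg <- character()
  if (!(object@dk > 0)) msg <- c(msg, "dk must be > 0")
  if (any(object@mask < 0 | object@mask > 1)) msg <- c(msg, "weights must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Sampled 2-D complex transmission function
#'
#' Amplitude/phase field of an object or reconstructed image on a square,
#' even-sided grid with object-space pixel pitch `pixelPitchUm`. Pixel (i, j)
#' is at object-space coordinates
#' `x = (j - 1 - n/2) * pitch`, `y = (i - 1 - n/2) * pitch`,
#' so the spatial origin coincides with the FFT DC pixel (n/2 + 1).
#'
#' @slot data complex matrix (square, even side)
#' @slot pixelPitchUm object-space pixel pitch (um)
#' @name ComplexField-class
#' @rdname ComplexField
#' @exportClass ComplexField
setClass("ComplexField",
  representation(data = "matrix", pixelPitchUm = "numeric"))

setValidity("ComplexField", function(object) {
  d <- object@data
  msg <- character()
  if (!is.complex(d) && !is.numeric(d)) msg <- c(msg, "data must be numeric or complex")
  if (nrow(d) != ncol(d)) msg <- c(msg, "field must be square")
  if (nrow(d) %% 2L != 0L) msg <- c(msg, "side length must be even")
  if (any(!is.finite(Re(d))) || any(!is.finite(Im(as.complex(d)))))
    msg <- c(msg, "field must be finite")
  if (!(object@pixelPitchUm > 0)) msg <- c(msg, "pixelPitchUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Resolution chart: a ComplexField plus element metadata
#'
#' A composite bar chart with a record of where each bar element sits, its
#' period, orientation, bar count and polarity, so profiles can be extracted
#' automatically.
#'
#' @slot elements data.frame(period_um, orientation, x_um, y_um, n_bars, dark)
#' @name ResolutionChart-class
#' @rdname ResolutionChart
#' @exportClass ResolutionChart
setClass("ResolutionChart", contains = "ComplexField",
  representation(elements = "data.frame"))

#' Industrial camera model
#'
#' Converts ideal intensity to digital codes: expected photoelectrons are
#' `intensity * factor * exposure_ms * duty * photonBudget`, followed by
#' Poisson shot noise, Gaussian read noise, gain `(2^bitDepth - 1)/fullWell`,
#' clipping to the code range and (optionally) integer quantization.
#'
#' @slot photonBudget photoelectrons per (ms x duty) at unit ideal intensity
#' @slot readNoiseE read noise (electrons RMS)
#' @slot bitDepth ADC bit depth
#' @slot fullWell full-well capacity (electrons); codes clip at 2^bitDepth - 1
#' @slot shotNoise logical; apply Poisson shot noise
#' @slot quantize logical; round codes to integers
#' @name CameraModel-class
#' @rdname CameraModel
#' @exportClass CameraModel
setClass("CameraModel",
  representation(
    photonBudget = "numeric",
    readNoiseE = "numeric",
    bitDepth = "integer",
    fullWell = "numeric",
    shotNoise = "logical",
    quantize = "logical"
  )
)

setValidity("CameraModel", function(object) {
  msg <- character()
  if (!(object@photonBudget > 0)) msg <- c(msg, "photonBudget must be > 0")
  if (object@readNoiseE < 0) msg <- c(msg, "readNoiseE must be >= 0")
  if (object@bitDepth < 1L) msg <- c(msg, "bitDepth must be >= 1")
  if (!(object@fullWell > 0)) msg <- c(msg, "fullWell must be > 0")
  if (length(msg)) msg else TRUE
})

#' Low-resolution intensity stack
#'
#' Ordered intensity images (raw digital codes or normalized intensities) with
#' per-image acquisition metadata and saturation masks.
#'
#' @slot images list of numeric matrices, one per plan entry, common shape
#' @slot meta data.frame(m, n, exposure_ms, duty_cycle) aligned with images
#' @slot satMask list of logical matrices flagging clipped pixels
#' @slot pixelPitchUm object-space pitch of the camera grid (um)
#' @slot normalized logical; TRUE once exposure/duty scaling has been removed
#' @name LRStack-class
#' @rdname LRStack
#' @exportClass LRStack
setClass("LRStack",
  representation(
    images = "list",
    meta = "data.frame",
    satMask = "list",
    pixelPitchUm = "numeric",
    normalized = "logical"
  )
)

setValidity("LRStack", function(object) {
  msg <- character()
  if (length(object@images) != nrow(object@meta))
    msg <- c(msg, "image count must equal plan length")
  if (length(object@satMask) != length(object@images))
    msg <- c(msg, "satMask count must equal image count")
  if (length(object@images)) {
    dims <- vapply(object@images, function(x) paste(dim(x), collapse = "x"), "")
    if (length(unique(dims)) != 1L) msg <- c(msg, "all images must share one shape")
  }
  if (length(msg)) msg else TRUE
})

#' Reconstruction configuration
#'
#' @slot upsamplingFactor integer >= 1; HR grid side = LR side x factor.
#'   `NA` selects the smallest factor giving Nyquist sampling of the synthetic
#'   aperture (objective NA + radial illumination NA).
#' @slot maxSweeps maximum full passes over the LED set
#' @slot relTol stop when the relative change of the data-fidelity cost
#'   between sweeps falls below this
#' @slot updateOrder "center_out_spiral" (low frequencies first) or "raster"
#' @slot seed integer seed for any stochastic component (SA proposals)
#' @name ReconConfig-class
#' @rdname ReconConfig
#' @exportClass ReconConfig
setClass("ReconConfig",
  representation(
    upsamplingFactor = "integer",
    maxSweeps = "integer",
    relTol = "numeric",
    updateOrder = "character",
    seed = "integer"
  )
)

setValidity("ReconConfig", function(object) {
  msg <- character()
  if (!is.na(object@upsamplingFactor) && object@upsamplingFactor < 1L)
    msg <- c(msg, "upsamplingFactor must be >= 1")
  if (object@maxSweeps < 1L) msg <- c(msg, "maxSweeps must be >= 1")
  if (!(object@relTol >= 0)) msg <- c(msg, "relTol must be >= 0")
  if (!object@updateOrder %in% c("center_out_spiral", "raster"))
    msg <- c(msg, "updateOrder must be 'center_out_spiral' or 'raster'")
  if (length(msg)) msg else TRUE
})

#' Simulated-annealing configuration for intensity-factor correction
#'
#' @slot enabled logical; when FALSE the reconstruction is conventional FPM
#' @slot tInitial initial temperature in cost units; `NA` auto-sets it to the
#'   median absolute cost change of the first sweep's proposals
#' @slot cooling geometric cooling factor in (0, 1), applied once per sweep
#' @slot proposalsPerVisit proposals per LED visit
#' @slot proposalWidth half-width of the uniform log-step proposal
#' @slot tFloor temperature floor
#' @name SAConfig-class
#' @rdname SAConfig
#' @exportClass SAConfig
setClass("SAConfig",
  representation(
    enabled = "logical",
    tInitial = "numeric",
    cooling = "numeric",
    proposalsPerVisit = "integer",
    proposalWidth = "numeric",
    tFloor = "numeric"
  )
)

setValidity("SAConfig", function(object) {
  msg <- character()
  if (!(object@cooling > 0 && object@cooling < 1))
    msg <- c(msg, "cooling must lie in (0, 1)")
  if (object@proposalsPerVisit < 1L) msg <- c(msg, "proposalsPerVisit must be >= 1")
  if (object@proposalWidth < 0) msg <- c(msg, "proposalWidth must be >= 0")
  if (object@tFloor < 0) msg <- c(msg, "tFloor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Reconstruction result
#'
#' @slot hrField recovered high-resolution [ComplexField-class]
#' @slot hrSpectrum final HR spectrum (complex matrix, DC centered)
#' @slot dk frequency spacing of the HR spectrum (cycles/um)
#' @slot factors recovered per-image intensity factors (all 1 when SA is off)
#' @slot trace per-sweep data-fidelity cost
#' @slot sweeps number of sweeps actually run
#' @name ReconResult-class
#' @rdname ReconResult
#' @exportClass ReconResult
setClass("ReconResult",
  representation(
    hrField = "ComplexField",
    hrSpectrum = "matrix",
    dk = "numeric",
    factors = "numeric",
    trace = "numeric",
    sweeps = "integer"
  )
)

setValidity("ReconResult", function(object) {
  msg <- character()
  if (any(object@factors <= 0)) msg <- c(msg, "factors must be positive")
  if (length(msg)) msg else TRUE
})
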