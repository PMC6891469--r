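# Coherent forward model plus the industrial-camera radiometric chain.

# Integer upsampling ratio between the object grid and the camera grid.
upsamplingRatio <- function(obj, sys) {
  k <- pixelPitchUm(sys) / obj@pixelPitchUm
  if (abs(k - round(k)) > 1e-9)
    stop("object pitch ", obj@pixelPitchUm,
         " um must integer-divide the camera object-space pitch ",
         pixelPitchUm(sys), " um")
  as.integer(round(k))
}

#' Ideal low-resolution intensity under one LED
#'
#' Coherent image of the object under tilted plane-wave illumination with wave
#' vector `fLed`: the object spectrum is windowed at +`fLed` by the circular
#' pupil and inverse-transformed onto the camera grid (object-space pixel =
#' camera pixel / magnification). Downsampling is ideal band-limited sampling
#' (spectral cropping); the result is a continuous-scale intensity image, unit
#' intensity for a unit-amplitude object on axis.
#'
#' @param obj object [ComplexField-class], simulated at the HR pitch
#' @param sys an [OpticalSystem-class]
#' @param fLed illumination wave vector (fx, fy) in cycles/um
#' @return numeric intensity matrix on the camera grid
#' @export
simulateLRIntensity <- function(obj, sys, fLed) {
  k <- upsamplingRatio(obj, sys)
  nHr <- nrow(obj@data)
  nLr <- nHr %/% k
  if (nLr < 2L || nLr %% 2L != 0L)
    stop("object field (", nHr, " px) too small for the camera patch at ratio ", k)
  dk <- 1 / (nHr * obj@pixelPitchUm)
  S <- ft2(obj@data)
  P <- pupilMask(sys, c(nLr, nLr), dk)
  px <- freqToBin(fLed[[1]], dk)
  py <- freqToBin(fLed[[2]], dk)
  rows <- windowIndices(nHr, nLr, py)
  cols <- windowIndices(nHr, nLr, px)
  if (is.null(rows) || is.null(cols))
    stop("sub-aperture at wave vector (", signif(fLed[[1]], 4), ", ",
         signif(fLed[[2]], 4), ") cycles/um falls outside the object spectrum")
  w <- S[rows, cols] * P@mask
  psi <- ift2(w, norm = nHr^2)
  Mod(psi)^2
}

#' Draw per-LED intensity inconsistency factors
#'
#' Independent lognormal factors with median 1 and log-scale `sigma`, one per
#' plan entry, modelling LED-to-LED brightness differences, angular falloff
#' and sensor response nonlinearity. Deterministic for a given seed.
#'
#' @param plan an [IlluminationPlan-class]
#' @param sigma lognormal log-scale (>= 0); 0 gives all factors 1
#' @param seed integer seed
#' @return numeric vector of positive factors, one per plan entry
#' @export
drawFactors <- function(plan, sigma = 0.2, seed = 1L) {
  stopifnot(sigma >= 0)
  nLed <- nrow(plan@entries)
  set.seed(seed)
  stats::rlnorm(nLed, meanlog = 0, sdlog = sigma)
}

# Ideal intensity -> digital codes for one image.
cameraForward <- function(ideal, factor, exposureMs, duty, cam) {
  electrons <- ideal * factor * exposureMs * duty * cam@photonBudget
  if (cam@shotNoise) {
    # rpois overflows for large lambda; normal approximation is exact enough
    # far above the quantization step there
    big <- electrons > 1e6
    e2 <- electrons
    e2[!big] <- stats::rpois(sum(!big), electrons[!big])
    if (any(big))
      e2[big] <- stats::rnorm(sum(big), electrons[big], sqrt(electrons[big]))
    electrons <- e2
  }
  if (cam@readNoiseE > 0)
    electrons <- electrons + stats::rnorm(length(electrons), 0, cam@readNoiseE)
  maxCode <- 2^cam@bitDepth - 1
  codes <- electrons * maxCode / cam@fullWell
  if (cam@quantize) codes <- round(codes)
  codes <- matrix(pmin(pmax(codes, 0), maxCode), nrow(ideal), ncol(ideal))
  list(codes = codes, sat = codes >= maxCode)
}

#' Simulate a full low-resolution acquisition stack
#'
#' Renders every plan entry through the coherent forward model and the camera
#' chain: ideal intensity x brightness factor x exposure x duty -> expected
#' photoelectrons -> Poisson shot noise -> Gaussian read noise -> gain ->
#' clipping to the code range -> quantization. Clipped pixels are flagged in
#' the saturation masks. Deterministic for a given seed.
#'
#' @param obj object [ComplexField-class] at the HR pitch
#' @param sys an [OpticalSystem-class]
#' @param geom a [LEDArrayGeometry-class]
#' @param plan an [IlluminationPlan-class]
#' @param factors per-entry intensity factors, see [drawFactors()]
#' @param cam a [CameraModel-class]
#' @param seed integer seed for the noise draws
#' @return an [LRStack-class] of raw digital codes
#' @export
simulateStack <- function(obj, sys, geom, plan, factors = NULL,
                          cam = cameraModel(), seed = 1L) {
  e <- plan@entries
  if (is.null(factors)) factors <- rep(1, nrow(e))
  stopifnot(length(factors) == nrow(e), all(factors > 0))
  set.seed(seed)
  images <- vector("list", nrow(e))
  masks <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    f <- waveVector(e$m[i], e$n[i], geom, sys)
    ideal <- simulateLRIntensity(obj, sys, f)
    out <- cameraForward(ideal, factors[i], e$exposure_ms[i], e$duty_cycle[i], cam)
    images[[i]] <- out$codes
    masks[[i]] <- out$sat
  }
  meta <- e
  meta$factor_true <- factors
  new("LRStack", images = images, meta = meta, satMask = masks,
      pixelPitchUm = pixelPitchUm(sys), normalized = FALSE)
}

#' Radiometric normalization of a raw stack
#'
#' Inverts the acquisition scaling so all images share one radiometric scale:
#' codes -> electrons (inverse gain) -> intensity, dividing by
#' (photon budget x exposure x duty). In the noiseless, unit-factor limit the
#' result equals the ideal intensity. Saturation masks are carried forward.
#'
#' @param stack a raw [LRStack-class]
#' @param cam the [CameraModel-class] used during acquisition
#' @return a normalized [LRStack-class]
#' @export
normalizeStack <- function(stack, cam = cameraModel()) {
  if (stack@normalized) return(stack)
  e <- stack@meta
  if (is.null(e$exposure_ms) || is.null(e$duty_cycle) ||
      any(is.na(e$exposure_ms)) || any(is.na(e$duty_cycle)))
    stop("stack metadata must provide exposure_ms and duty_cycle for every image")
  maxCode <- 2^cam@bitDepth - 1
  images <- vector("list", length(stack@images))
  for (i in seq_along(stack@images)) {
    scale <- e$exposure_ms[i] * e$duty_cycle[i] * cam@photonBudget
    images[[i]] <- stack@images[[i]] * cam@fullWell / maxCode / scale
  }
  new("LRStack", images = images, meta = e, satMask = stack@satMask,
      pixelPitchUm = stack@pixelPitchUm, normalized = TRUE)
}
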