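# Geometric and Fourier-optics description of the LED-array platform.

#' LED center position in sample-centered coordinates
#'
#' In-plane position (m, n) * pitch, rotated by the array roll angle, shifted
#' by the lateral offset, at height z = standoff. Units are mm.
#'
#' @param m,n integer LED indices along x and y
#' @param geom a [LEDArrayGeometry-class]
#' @return numeric (x_mm, y_mm, z_mm)
#' @examples
#' geom <- ledArrayGeometry()
#' ledPosition(0, 0, geom)   # on-axis LED: (0, 0, 93)
#' ledPosition(15, 0, geom)  # edge LED: (37.5, 0, 93)
#' @export
ledPosition <- function(m, n, geom) {
  m <- unname(m); n <- unname(n)
  h <- geom@halfExtent
  if (abs(m) > h || abs(n) > h)
    stop("LED index (", m, ", ", n, ") outside array of half-extent ", h)
  th <- geom@rollDeg * pi / 180
  x0 <- m * geom@pitchMm
  y0 <- n * geom@pitchMm
  c(x = cos(th) * x0 - sin(th) * y0 + geom@offsetMm[1],
    y = sin(th) * x0 + cos(th) * y0 + geom@offsetMm[2],
    z = geom@standoffMm)
}

#' Illumination wave vector of one LED
#'
#' Spatial-frequency shift of the sub-aperture captured under illumination by
#' LED (m, n), evaluated for the center of the imaged field patch (plane-wave
#' approximation). The direction cosines of the plane wave travelling from the
#' LED at (x, y, z) to the field center are (-x, -y)/r, so
#' `(fx, fy) = (-x, -y) / (r * lambda)` with `r = sqrt(x^2 + y^2 + z^2)`.
#' The captured sub-aperture is centered at +(fx, fy); the simulator and the
#' reconstructor share this convention.
#'
#' @inheritParams ledPosition
#' @param sys an [OpticalSystem-class]
#' @return numeric (fx, fy) in cycles/um
#' @export
waveVector <- function(m, n, geom, sys) {
  p <- ledPosition(m, n, geom)
  r <- sqrt(sum(p^2))
  c(fx = -p[["x"]] / r / sys@wavelengthUm,
    fy = -p[["y"]] / r / sys@wavelengthUm)
}

#' Maximum illumination NA of the array
#'
#' `mode = "axial"`: maximum |sin theta| over LEDs on the array axes (the
#' figure usually quoted for a square array); `mode = "radial"`: maximum over
#' all LEDs (reached at a corner).
#'
#' @param geom a [LEDArrayGeometry-class]
#' @param mode "axial" or "radial"
#' @return dimensionless NA
#' @examples
#' illuminationNA(ledArrayGeometry())            # ~0.374, quoted as 0.37
#' illuminationNA(ledArrayGeometry(), "radial")  # ~0.495 (corner LED)
#' @export
illuminationNA <- function(geom, mode = c("axial", "radial")) {
  mode <- match.arg(mode)
  h <- geom@halfExtent
  if (h == 0L && all(geom@offsetMm == 0)) return(0)
  idx <- if (mode == "axial") {
    rbind(cbind(-h:h, 0L), cbind(0L, -h:h))
  } else {
    as.matrix(expand.grid(m = -h:h, n = -h:h))
  }
  sin_th <- apply(idx, 1L, function(mn) {
    p <- ledPosition(mn[1], mn[2], geom)
    sqrt(p[["x"]]^2 + p[["y"]]^2) / sqrt(sum(p^2))
  })
  max(sin_th)
}

#' Binary circular pupil mask
#'
#' Hard disk of radius NA/lambda on a DC-centered frequency grid with spacing
#' `dk`: pixels whose center is strictly inside the cutoff get weight 1, all
#' others 0 (ideal circular pupil, no apodization).
#'
#' @param sys an [OpticalSystem-class]
#' @param gridShape (rows, cols) of the frequency grid
#' @param dk frequency grid spacing (cycles/um)
#' @return a [PupilMask-class]
#' @export
pupilMask <- function(sys, gridShape, dk) {
  stopifnot(dk > 0)
  cutoff <- cutoffFrequency(sys)
  rows <- gridShape[1]; cols <- gridShape[2]
  if (rows * dk < 2 * cutoff || cols * dk < 2 * cutoff)
    stop("frequency grid (", rows, " x ", cols, ", dk = ", dk,
         ") too small to contain the pupil disk of radius ", cutoff)
  fy <- (seq_len(rows) - (rows %/% 2L + 1L)) * dk
  fx <- (seq_len(cols) - (cols %/% 2L + 1L)) * dk
  m <- outer(fy^2, fx^2, "+") < cutoff^2
  new("PupilMask", mask = m + 0, dk = dk, cutoff = cutoff)
}

#' Spectral overlap ratio of adjacent sub-apertures
#'
#' Area fraction of one pupil disk shared with the disk of the nearest
#' neighboring LED, for the wave-vector step at the array center (closed-form
#' circle-circle intersection). Sufficient overlap (commonly >= ~60%) is the
#' usual convergence criterion for the phase-retrieval stitching.
#'
#' @param sys an [OpticalSystem-class]
#' @param geom a [LEDArrayGeometry-class]
#' @return fraction in [0, 1]
#' @export
overlapRatio <- function(sys, geom) {
  cutoff <- cutoffFrequency(sys)
  f0 <- waveVector(0L, 0L, geom, sys)
  f1 <- waveVector(min(1L, geom@halfExtent), 0L, geom, sys)
  d <- sqrt(sum((f1 - f0)^2))
  if (d >= 2 * cutoff) return(0)
  u <- d / (2 * cutoff)
  (2 * acos(u) - 2 * u * sqrt(1 - u^2)) / pi
}

#' Default ring-wise exposure map (ms)
#'
#' Exposure time per LED ring (ring = max(|m|, |n|)): the central 7 x 7 block
#' (rings 0-3) at 100 ms, the five rings around it (rings 4-8) at 150 ms, the
#' six rings around the central 19 x 19 block (rings 9-14) at 450 ms, and the
#' outermost ring (15) at 700 ms. Returned as a numeric vector indexed by
#' ring + 1.
#'
#' @return numeric vector of length 16, exposure in ms per ring 0..15
#' @export
defaultRingExposureMap <- function() {
  c(rep(100, 4), rep(150, 5), rep(450, 6), 700)
}

#' Exposure time for one LED under a ring-wise map
#'
#' @inheritParams ledPosition
#' @param ringMap numeric vector; entry `ring + 1` is the exposure (ms) for
#'   ring = max(|m|, |n|)
#' @return exposure time (ms)
#' @examples
#' exposureForLED(0, 0)    # 100 ms (central block)
#' exposureForLED(5, 0)    # 150 ms
#' exposureForLED(15, 15)  # 700 ms (outermost ring)
#' @export
exposureForLED <- function(m, n, ringMap = defaultRingExposureMap()) {
  ring <- max(abs(m), abs(n))
  if (ring + 1L > length(ringMap))
    stop("ring ", ring, " not covered by the exposure map (length ",
         length(ringMap), ")")
  ringMap[ring + 1L]
}

#' Build an illumination plan
#'
#' Orders the LEDs center-out (by ring, then angle) and attaches the ring-wise
#' exposure time and a duty cycle to each entry.
#'
#' @param geom a [LEDArrayGeometry-class]
#' @param ringMap ring-wise exposure map, see [exposureForLED()]
#' @param maxRing restrict the plan to rings 0..maxRing (default: whole array)
#' @param dutyCycle PWM duty cycle, recycled over entries
#' @return an [IlluminationPlan-class]
#' @examples
#' plan <- illuminationPlan(ledArrayGeometry())
#' nrow(planEntries(plan))  # 961 images for the full 31 x 31 array
#' @export
illuminationPlan <- function(geom, ringMap = defaultRingExposureMap(),
                             maxRing = geom@halfExtent, dutyCycle = 1) {
  h <- min(geom@halfExtent, maxRing)
  g <- expand.grid(m = -h:h, n = -h:h)
  ring <- pmax(abs(g$m), abs(g$n))
  keep <- ring <= maxRing
  g <- g[keep, ]; ring <- ring[keep]
  ord <- order(ring, atan2(g$n, g$m))
  g <- g[ord, ]; ring <- ring[ord]
  expo <- vapply(seq_len(nrow(g)),
                 function(i) exposureForLED(g$m[i], g$n[i], ringMap), 0)
  e <- data.frame(m = g$m, n = g$n, exposure_ms = expo,
                  duty_cycle = rep_len(dutyCycle, nrow(g)))
  rownames(e) <- NULL
  new("IlluminationPlan", entries = e)
}
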