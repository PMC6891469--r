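# Ground-truth complex objects: bar resolution targets and smooth transparent
# phase objects.

# Object-space pixel-center coordinate of 1-based index i on an n-grid:
# the spatial origin coincides with the FFT DC pixel (n/2 + 1).
gridCoord <- function(i, n, pitch) (i - 1 - n %/% 2) * pitch

# Inverse: fractional 1-based index of coordinate x.
coordToIndex <- function(x, n, pitch) x / pitch + n %/% 2 + 1

# Bar pattern indicator at coordinates u (um), for bars of width period/2
# spaced period, n_bars bars centered on u = 0. Hard edges: a pixel is inside
# a bar iff its center is (partial-pixel bars round to whole pixels).
barIndicator <- function(u, periodUm, nBars) {
  extent <- (nBars - 1) * periodUm + periodUm / 2
  u0 <- u + extent / 2                      # left edge of the first bar
  inBar <- (u0 %% periodUm) < periodUm / 2
  inBar & u0 >= 0 & u0 < extent
}

#' Bar resolution target
#'
#' Unit-background amplitude object with `nBars` bars of width `periodUm / 2`
#' spaced `periodUm`, centered in the field; zero phase. Bars are dark
#' (amplitude 0) by default, emulating chrome-on-glass charts; edges are hard,
#' so resolvability depends only on the imaging model.
#'
#' @param periodUm bar period (um); one line pair = one period
#' @param nBars number of bars (>= 1)
#' @param orientation "vertical" (bars vary along x) or "horizontal"
#' @param shape side length of the square field (pixels, even)
#' @param pitchUm object-space pixel pitch (um)
#' @param dark logical; TRUE for dark bars on a bright background
#' @return a [ComplexField-class]
#' @examples
#' tgt <- barTarget(1000 / 465, 3, "vertical", 64L, 0.575) # 465 pairs/mm
#' range(amplitude(tgt))
#' @export
barTarget <- function(periodUm, nBars, orientation = c("vertical", "horizontal"),
                      shape, pitchUm, dark = TRUE) {
  orientation <- match.arg(orientation)
  if (nBars < 1) stop("nBars must be >= 1")
  if (periodUm < 2 * pitchUm)
    stop("period ", periodUm, " um is below the grid Nyquist limit ",
         2 * pitchUm, " um")
  n <- as.integer(shape[1])
  u <- gridCoord(seq_len(n), n, pitchUm)
  ind <- barIndicator(u, periodUm, nBars)
  line <- if (dark) 1 - ind else 0 + ind
  a <- if (orientation == "vertical") {
    matrix(line, nrow = n, ncol = n, byrow = TRUE) # varies along columns (x)
  } else {
    matrix(line, nrow = n, ncol = n)               # varies along rows (y)
  }
  complexField(a + 0i, pitchUm)
}

#' Composite USAF-like resolution chart
#'
#' Embeds several bar elements into one unit-amplitude field and records their
#' positions, periods and polarity for automated profile extraction. Elements
#' are listed coarsest-first in the returned metadata.
#'
#' @param elements data.frame with columns `period_um`, `orientation`
#'   ("vertical"/"horizontal"), `x_um`, `y_um` (element center, object-space um
#'   relative to the field center) and optionally `n_bars` (default 3)
#' @param shape side length of the square field (pixels, even)
#' @param pitchUm object-space pixel pitch (um)
#' @param dark logical; dark bars on bright background
#' @return a [ResolutionChart-class]
#' @export
usafLikeTarget <- function(elements, shape, pitchUm, dark = TRUE) {
  n <- as.integer(shape[1])
  a <- matrix(if (dark) 1 else 0, n, n)
  if (is.null(elements) || nrow(elements) == 0L) {
    el <- data.frame(period_um = numeric(), orientation = character(),
                     x_um = numeric(), y_um = numeric(), n_bars = integer(),
                     dark = logical())
    return(new("ResolutionChart", complexField(a + 0i, pitchUm), elements = el))
  }
  if (is.null(elements$n_bars)) elements$n_bars <- 3L
  boxes <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    extent <- (e$n_bars - 1) * e$period_um + e$period_um / 2
    barLen <- extent                         # square elements
    along <- gridCoord(seq_len(n), n, pitchUm)
    if (e$orientation == "vertical") {
      ind <- barIndicator(along - e$x_um, e$period_um, e$n_bars)
      rows <- abs(along - e$y_um) <= barLen / 2
      block <- outer(rows, ind, "&")
      boxes[[i]] <- c(e$x_um - extent / 2, e$x_um + extent / 2,
                      e$y_um - barLen / 2, e$y_um + barLen / 2)
    } else {
      ind <- barIndicator(along - e$y_um, e$period_um, e$n_bars)
      cols <- abs(along - e$x_um) <= barLen / 2
      block <- outer(ind, cols, "&")
      boxes[[i]] <- c(e$x_um - barLen / 2, e$x_um + barLen / 2,
                      e$y_um - extent / 2, e$y_um + extent / 2)
    }
    fov <- n * pitchUm / 2
    if (any(abs(boxes[[i]]) > fov))
      stop("element ", i, " (period ", e$period_um, " um) does not fit inside the field")
    a[block] <- if (dark) 0 else 1
  }
  for (i in seq_len(nrow(elements))) for (j in seq_len(i - 1L)) {
    b1 <- boxes[[i]]; b2 <- boxes[[j]]
    if (b1[1] < b2[2] && b2[1] < b1[2] && b1[3] < b2[4] && b2[3] < b1[4])
      stop("elements ", j, " and ", i, " overlap")
  }
  el <- elements[order(-elements$period_um), , drop = FALSE]
  el$dark <- dark
  rownames(el) <- NULL
  new("ResolutionChart", complexField(a + 0i, pitchUm), elements = el)
}

#' Smooth transparent phase object
#'
#' Unit amplitude everywhere; the phase is band-limited Gaussian noise
#' (Gaussian-smoothed in the Fourier domain at the requested feature scale)
#' rescaled to [0, maxPhaseRad]. Emulates an unstained biological specimen
#' such as a tissue section: contrast lives in the optical path length, not in
#' absorption. Deterministic for a given seed.
#'
#' @param featureScaleUm characteristic lateral feature size (um)
#' @param maxPhaseRad peak phase (radians, in (0, pi])
#' @param shape side length of the square field (pixels, even)
#' @param pitchUm object-space pixel pitch (um)
#' @param seed integer seed
#' @return a [ComplexField-class]
#' @export
phaseObject <- function(featureScaleUm, maxPhaseRad, shape, pitchUm, seed = 1L) {
  if (!(maxPhaseRad > 0 && maxPhaseRad <= pi))
    stop("maxPhaseRad must lie in (0, pi]")
  if (featureScaleUm <= pitchUm)
    stop("featureScaleUm must exceed the pixel pitch")
  n <- as.integer(shape[1])
  set.seed(seed)
  noise <- matrix(stats::rnorm(n * n), n, n)
  f <- (seq_len(n) - (n %/% 2 + 1)) / (n * pitchUm)
  sigma_f <- 1 / (2 * pi * featureScaleUm)       # Gaussian low-pass
  w <- exp(-outer(f^2, f^2, "+") / (2 * sigma_f^2))
  smooth <- Re(ift2(ft2(noise) * w))
  ph <- smooth - min(smooth)
  ph <- ph / max(ph) * maxPhaseRad
  complexField(exp(1i * ph), pitchUm)
}
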