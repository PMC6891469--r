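# Quantitative evaluation: line profiles, bar resolvability, smallest
# resolved period, background ripple, complex RMSE against ground truth.

#' Line profile through an intensity image
#'
#' Bilinear-interpolated samples along a segment given in object-space um
#' (coordinates relative to the field center, see [ComplexField-class]).
#'
#' @param image numeric intensity matrix (rows = y, cols = x)
#' @param pitchUm pixel pitch of the image (um)
#' @param from,to length-2 (x_um, y_um) segment endpoints
#' @param nSamples number of samples along the segment
#' @return numeric profile of length `nSamples`
#' @export
lineProfile <- function(image, pitchUm, from, to, nSamples = 128L) {
  n <- nrow(image)
  t <- seq(0, 1, length.out = nSamples)
  xs <- from[1] + t * (to[1] - from[1])
  ys <- from[2] + t * (to[2] - from[2])
  ci <- coordToIndex(xs, ncol(image), pitchUm)
  ri <- coordToIndex(ys, n, pitchUm)
  if (any(ci < 1 | ci > ncol(image) | ri < 1 | ri > n))
    stop("profile segment falls outside the image")
  r0 <- pmin(floor(ri), n - 1); c0 <- pmin(floor(ci), ncol(image) - 1)
  fr <- ri - r0; fc <- ci - c0
  image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    image[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    image[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    image[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Alternating local extrema of a profile (plateaus collapsed to their
# midpoint; endpoints included). Returns data.frame(index, value, type) with
# type +1 for maxima, -1 for minima.
profileExtrema <- function(p) {
  keep <- c(TRUE, diff(p) != 0)
  idx <- which(keep)
  v <- p[keep]
  n <- length(v)
  if (n < 2L)
    return(data.frame(index = 1L, value = p[1], type = 1L)[0, ])
  s <- sign(diff(v))
  type <- integer(n)
  type[1] <- -s[1]
  type[n] <- s[n - 1]
  if (n >= 3L) for (i in 2:(n - 1)) {
    if (s[i - 1] > 0 && s[i] < 0) type[i] <- 1L
    if (s[i - 1] < 0 && s[i] > 0) type[i] <- -1L
  }
  sel <- type != 0L
  data.frame(index = idx[sel], value = v[sel], type = type[sel])
}

# Persistence simplification of an alternating extrema sequence: repeatedly
# merge the adjacent max/min pair with the lowest Michelson contrast until
# every remaining pair reaches `minContrast`. Insignificant ripples (noise,
# coherent ringing inside a bar or gap) disappear; genuine bars survive.
simplifyExtrema <- function(ex, minContrast) {
  repeat {
    n <- nrow(ex)
    if (n < 2L) return(ex)
    hi <- pmax(ex$value[-n], ex$value[-1])
    lo <- pmin(ex$value[-n], ex$value[-1])
    contr <- (hi - lo) / (hi + lo)
    contr[!is.finite(contr)] <- 0
    i <- which.min(contr)
    if (contr[i] >= minContrast) return(ex)
    ex <- ex[-c(i, i + 1L), , drop = FALSE]
  }
}

#' Bar resolvability of a line profile
#'
#' TRUE when the profile contains at least `nBars` local extrema of the bar
#' polarity after contrast-based simplification: adjacent peak/valley pairs
#' whose Michelson contrast `(max - min) / (max + min)` falls below
#' `minContrast` are merged away (they are ripples, not structure), and every
#' surviving bar-polarity extremum then sits at contrast `>= minContrast`
#' against its neighbors. For bright bars (`feature = "peaks"`) the bars are
#' maxima; for dark bars on a bright background (`feature = "valleys"`) they
#' are minima, with the same rule applied symmetrically.
#'
#' @param profile numeric intensity profile
#' @param nBars number of bars the element contains (>= 2)
#' @param minContrast Michelson contrast threshold in (0, 1)
#' @param feature "peaks" (bright bars) or "valleys" (dark bars)
#' @return logical
#' @export
resolvable <- function(profile, nBars, minContrast = 0.2,
                       feature = c("peaks", "valleys")) {
  feature <- match.arg(feature)
  stopifnot(nBars >= 2, minContrast > 0, minContrast < 1)
  ex <- simplifyExtrema(profileExtrema(profile), minContrast)
  if (nrow(ex) < 3L) return(FALSE)
  want <- if (feature == "peaks") 1L else -1L
  sum(ex$type == want) >= nBars
}

# Profile across one chart element: perpendicular to the bars, through the
# element center, length 1.5x the element extent, ~8 samples per period.
elementProfile <- function(image, pitchUm, element) {
  extent <- (element$n_bars - 1) * element$period_um + element$period_um / 2
  half <- 0.75 * extent
  if (element$orientation == "vertical") {
    from <- c(element$x_um - half, element$y_um)
    to <- c(element$x_um + half, element$y_um)
  } else {
    from <- c(element$x_um, element$y_um - half)
    to <- c(element$x_um, element$y_um + half)
  }
  nS <- max(64L, as.integer(ceiling(2 * half / element$period_um * 8)))
  lineProfile(image, pitchUm, from, to, nS)
}

#' Smallest resolved bar period of a chart image
#'
#' Extracts a profile across every chart element (perpendicular to the bars,
#' through the element center, 1.5x the element extent) and returns the
#' smallest period that passes [resolvable()]; `Inf` when none does.
#'
#' @param image a [ComplexField-class] (evaluated on its intensity) or a plain
#'   intensity matrix
#' @param elements chart metadata, see [chartElements()]
#' @param minContrast Michelson contrast threshold
#' @param pitchUm pixel pitch; required when `image` is a plain matrix
#' @return smallest resolved period (um), or Inf
#' @export
smallestResolvedPeriod <- function(image, elements, minContrast = 0.2,
                                   pitchUm = NULL) {
  if (is(image, "ComplexField")) {
    pitchUm <- image@pixelPitchUm
    img <- intensity(image)
  } else {
    if (is.null(pitchUm)) stop("pitchUm is required for a plain matrix image")
    img <- image
  }
  if (is.null(elements) || nrow(elements) == 0L) stop("chart has no elements")
  best <- Inf
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    prof <- elementProfile(img, pitchUm, e)
    feat <- if (isTRUE(e$dark)) "valleys" else "peaks"
    if (resolvable(prof, e$n_bars, minContrast, feat))
      best <- min(best, e$period_um)
  }
  best
}

#' Background ripple (coefficient of variation)
#'
#' Standard deviation over mean of the intensity in a blank region: 0 for a
#' perfectly flat background, growing with reconstruction artifacts such as
#' the ripples left by uncorrected LED brightness inconsistency.
#'
#' @param image intensity matrix or [ComplexField-class]
#' @param region logical matrix selecting the blank pixels
#' @return dimensionless std/mean
#' @export
backgroundRipple <- function(image, region) {
  if (is(image, "ComplexField")) image <- intensity(image)
  if (!any(region)) stop("blank region is empty")
  v <- image[region]
  stats::sd(v) / mean(v)
}

#' Blank-region mask for a resolution chart
#'
#' Pixels farther than `marginUm` from every element's bounding box.
#'
#' @param chart a [ResolutionChart-class]
#' @param marginUm clearance around each element (um)
#' @return logical matrix
#' @export
chartBlankRegion <- function(chart, marginUm = 5) {
  n <- nrow(chart@data)
  p <- chart@pixelPitchUm
  u <- gridCoord(seq_len(n), n, p)
  blank <- matrix(TRUE, n, n)
  for (i in seq_len(nrow(chart@elements))) {
    e <- chart@elements[i, ]
    extent <- (e$n_bars - 1) * e$period_um + e$period_um / 2
    halfx <- extent / 2 + marginUm
    halfy <- extent / 2 + marginUm
    inx <- abs(u - e$x_um) <= halfx
    iny <- abs(u - e$y_um) <= halfy
    blank[outer(iny, inx, "&")] <- FALSE
  }
  blank
}

#' Relative complex RMSE up to a global phase/scale
#'
#' Minimizes `||alpha * recovered - truth||` over one complex scalar `alpha`
#' (the global phase and scale are not observable in FPM) and returns the
#' minimized norm divided by `||truth||`.
#'
#' @param recovered,truth [ComplexField-class] objects or complex matrices of
#'   equal shape
#' @return dimensionless relative error in [0, 1+]
#' @export
rmseComplex <- function(recovered, truth) {
  a <- if (is(recovered, "ComplexField")) recovered@data else recovered
  b <- if (is(truth, "ComplexField")) truth@data else truth
  if (!all(dim(a) == dim(b))) stop("fields must have equal shapes")
  denom <- sum(Mod(a)^2)
  alpha <- if (denom > 0) sum(Conj(a) * b) / denom else 0 + 0i
  sqrt(sum(Mod(alpha * a - b)^2) / sum(Mod(b)^2))
}
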