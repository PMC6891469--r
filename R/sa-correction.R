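# Per-image intensity-factor correction by simulated annealing, embedded in
# the reconstruction loop. Each low-resolution image i carries an unknown
# multiplicative brightness factor c_i; the annealer refines c_i against the
# current model image before each amplitude replacement. Factors are
# identifiable only up to a global scale, so the on-axis LED's factor is
# pinned to 1 (gauge fixing) and all others are relative to it.

#' Brightness-mismatch cost of one image
#'
#' Sum over unmasked pixels of `(sqrt(measured / c) - |model|)^2`: the squared
#' amplitude-domain residual between the factor-corrected measurement and the
#' current model image. Comparing amplitudes (not intensities) matches the
#' geometry of the amplitude-replacement projection.
#'
#' @param measured measured intensity image (>= 0)
#' @param modelLr model complex image from the current spectrum estimate
#' @param c positive intensity factor
#' @param satMask logical matrix; TRUE pixels are excluded (saturated)
#' @return non-negative cost; 0 when every pixel is masked
#' @export
brightnessCost <- function(measured, modelLr, c, satMask = NULL) {
  if (!(c > 0)) stop("intensity factor must be > 0")
  if (any(measured < 0)) stop("measured intensity must be >= 0")
  r <- sqrt(measured / c) - Mod(modelLr)
  if (!is.null(satMask)) r[satMask] <- 0
  sum(r^2)
}

#' Metropolis acceptance rule
#'
#' Accepts every downhill move; uphill moves are accepted with probability
#' `exp(-deltaCost / T)`.
#'
#' @param deltaCost proposed cost change
#' @param temperature current temperature (> 0)
#' @return logical
#' @export
metropolisAccept <- function(deltaCost, temperature) {
  if (deltaCost <= 0) return(TRUE)
  if (!(temperature > 0)) return(FALSE)
  stats::runif(1) < exp(-deltaCost / temperature)
}

#' One annealing visit for one image's intensity factor
#'
#' Performs `proposalsPerVisit` multiplicative proposals
#' `c' = c * exp(eps)`, `eps ~ uniform(-w, w)`, accepting by the Metropolis
#' rule at the given temperature. The chain walks through accepted states
#' (including uphill ones, which is what lets it escape poor factors early
#' on) but the returned factor is the best accepted state of the visit, so a
#' visit never ends worse than it started. With `temperature = NA` the visit
#' is greedy (downhill only) and the
#' absolute cost changes of all proposals are returned so the caller can
#' auto-set the initial temperature.
#'
#' @param c current factor
#' @param measured measured intensity image
#' @param modelLr model complex image
#' @param satMask logical saturation mask or NULL
#' @param temperature current SA temperature; NA for a greedy warm-up visit
#' @param sa an [SAConfig-class]
#' @return list(c = updated factor, deltas = |cost changes| of the proposals)
#' @export
saRefineFactor <- function(c, measured, modelLr, satMask, temperature, sa) {
  modelAmp <- Mod(modelLr)
  sqm <- sqrt(measured)
  if (!is.null(satMask)) { sqm[satMask] <- 0; modelAmp[satMask] <- 0 }
  costOf <- function(ci) sum((sqm / sqrt(ci) - modelAmp)^2)
  cost <- costOf(c)
  cBest <- c; costBest <- cost
  deltas <- numeric(sa@proposalsPerVisit)
  for (p in seq_len(sa@proposalsPerVisit)) {
    if (sa@proposalWidth == 0) { deltas[p] <- 0; next }
    cNew <- c * exp(stats::runif(1, -sa@proposalWidth, sa@proposalWidth))
    costNew <- costOf(cNew)
    d <- costNew - cost
    deltas[p] <- abs(d)
    ok <- if (is.na(temperature)) d <= 0 else metropolisAccept(d, temperature)
    if (ok) {
      c <- cNew; cost <- costNew
      if (cost < costBest) { cBest <- c; costBest <- cost }
    }
  }
  list(c = cBest, deltas = deltas)
}

#' Apply an intensity factor to a measured image
#'
#' Divides the measurement by its factor, putting it on the common radiometric
#' scale used as the amplitude-replacement target.
#'
#' @param measured measured intensity image
#' @param c positive factor
#' @return corrected intensity image
#' @export
applyFactor <- function(measured, c) {
  if (!(c > 0)) stop("intensity factor must be > 0")
  measured / c
}
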