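# Independent oracles, deliberately written without the package's internal
# helpers: explicit index arithmetic, explicit spatial convolution.

# Circular disk indicator built by explicit looping (no vectorized outer).
oracleDisk <- function(n, dk, cutoff) {
  m <- matrix(0, n, n)
  ctr <- n / 2 + 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    f2 <- ((i - ctr) * dk)^2 + ((j - ctr) * dk)^2
    if (f2 < cutoff^2) m[i, j] <- 1
  }
  m
}

# Coherent image by direct circular spatial convolution with the PSF
# (inverse transform of the pupil), equal grids, on-axis illumination.
oracleLowpassIntensity <- function(objData, pitchUm, na, lambdaUm) {
  n <- nrow(objData)
  dk <- 1 / (n * pitchUm)
  disk <- oracleDisk(n, dk, na / lambdaUm)
  # PSF: unshift the DC-centered disk by explicit modular re-indexing,
  # then one inverse FFT (the transform itself is not what is under test)
  unshift <- matrix(0 + 0i, n, n)
  ctr <- n / 2 + 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ii <- ((i - ctr) %% n) + 1
    jj <- ((j - ctr) %% n) + 1
    unshift[ii, jj] <- disk[i, j]
  }
  psf <- stats::fft(unshift, inverse = TRUE) / n^2
  out <- matrix(0 + 0i, n, n)
  for (a in seq_len(n)) {
    rowIdx <- ((a - seq_len(n)) %% n) + 1
    for (b in seq_len(n)) {
      colIdx <- ((b - seq_len(n)) %% n) + 1
      out[a, b] <- sum(objData * psf[rowIdx, colIdx])
    }
  }
  Mod(out)^2
}

# One full raster-order amplitude-replacement sweep, straight-line
# re-implementation with explicit window index arithmetic.
oracleSweep <- function(spec, dkVal, images, fxs, fys, diskMask) {
  nHr <- nrow(spec)
  nLr <- nrow(images[[1]])
  cHr <- nHr / 2 + 1
  cLr <- nLr / 2 + 1
  shiftIdx <- function(n) c((n / 2 + 1):n, 1:(n / 2))
  for (i in seq_along(images)) {
    px <- round(fxs[i] / dkVal)
    py <- round(fys[i] / dkVal)
    rows <- (cHr + py - cLr) + 1:nLr
    cols <- (cHr + px - cLr) + 1:nLr
    w <- spec[rows, cols] * diskMask
    lr <- stats::fft(w[shiftIdx(nLr), shiftIdx(nLr)], inverse = TRUE) / nHr^2
    amp <- Mod(lr)
    ph <- ifelse(amp > 0, lr / amp, 1 + 0i)
    upd <- matrix(sqrt(images[[i]]) * ph, nLr, nLr)
    wNew <- stats::fft(upd)[shiftIdx(nLr), shiftIdx(nLr)] * (nHr / nLr)^2
    sub <- spec[rows, cols]
    sub[diskMask > 0] <- wNew[diskMask > 0]
    spec[rows, cols] <- sub
  }
  spec
}

# Monte-Carlo disk-intersection: fraction of one pupil disk shared with a
# disk displaced by `d`, radius `r`.
oracleOverlapMC <- function(d, r, nPts = 2e5, seed = 1) {
  set.seed(seed)
  th <- runif(nPts, 0, 2 * pi)
  rad <- r * sqrt(runif(nPts))
  x <- rad * cos(th); y <- rad * sin(th)
  mean((x - d)^2 + y^2 < r^2)
}
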