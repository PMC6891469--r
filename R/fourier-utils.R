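# FFT plumbing shared by the simulator and the reconstructor.
# Convention: spectra are stored DC-centered (fftshift applied), with the DC
# bin at matrix index (n/2 + 1, n/2 + 1) for even n. Frequencies are in
# cycles/um; 2*pi factors live inside stats::fft only. Rows index y / fy,
# columns index x / fx.

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  x[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  x[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

# Field -> DC-centered spectrum (unnormalized forward transform).
ft2 <- function(x) fftshift2(stats::fft(x))

# DC-centered spectrum -> field. `norm` is the normalization divisor; by
# default the grid size, making ift2(ft2(x)) == x.
ift2 <- function(s, norm = length(s)) {
  stats::fft(ifftshift2(s), inverse = TRUE) / norm
}

# Row/column index sets of an n_lr-sized window in an n_hr-sized DC-centered
# spectrum, centered `offset` bins (rows or cols) away from DC.
windowIndices <- function(nHr, nLr, offset) {
  centerHr <- nHr %/% 2L + 1L
  centerLr <- nLr %/% 2L + 1L
  idx <- (centerHr + offset - centerLr) + seq_len(nLr)
  if (idx[1] < 1L || idx[nLr] > nHr) return(NULL)
  idx
}

# Integer bin offset of a wave vector on a grid with spacing dk.
freqToBin <- function(f, dk) as.integer(round(f / dk))
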