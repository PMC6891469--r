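Package: FPtycho
Title: Fourier Ptychography Microscopy Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward simulation and reconstruction toolkit for Fourier
    ptychography microscopy (FPM) on low-cost platforms built around an
    LED-array illuminator and an industrial camera. Models the acquisition
    geometry (LED positions, illumination wave vectors, pupil masks,
    spectral overlap, ring-wise exposure schedules), renders low-resolution
    intensity stacks with per-LED brightness inconsistency, shot and read
    noise, saturation and quantization, reconstructs the high-resolution
    complex field by alternating-projection sub-aperture stitching in
    Fourier space, and corrects per-image intensity factors with a
    simulated-annealing step embedded in the reconstruction loop.
    Includes synthetic resolution targets and phase objects plus
    quantitative evaluation (line profiles, bar resolvability, smallest
    resolved period, background ripple, complex RMSE).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
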