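# FPtycho

Simulation and reconstruction toolkit for **Fourier ptychography microscopy
(FPM)** on low-cost platforms: an LED array provides angle-varied plane-wave
illumination, an industrial camera with limited dynamic range records one
low-resolution (LR) intensity image per LED, and a phase-retrieval algorithm
stitches the images together in Fourier space into one high-resolution (HR)
complex image — amplitude *and* phase — whose resolution is set by the
*synthetic* aperture `NA_obj + NA_ill` rather than by the objective alone.

The package is aimed at people building or studying such platforms who need a
faithful end-to-end model of the acquisition chain (LED geometry, ring-wise
exposure schedules, PWM duty cycles, per-LED brightness inconsistency, shot
and read noise, saturation, quantization) and a reference implementation of
the reconstruction, including the simulated-annealing (SA) correction of
per-image intensity factors that low-cost hardware makes necessary.

## The model

A thin object with complex transmission `f(x, y)` illuminated by a plane wave
with wave vector `(km, kn)` and imaged through an objective with circular
pupil `P` (radius `NA/λ` in frequency units) yields the LR image

```
ψ(km, kn) = Ψ(kx, ky) · P(kx − km, ky − kn),      I = |F⁻¹[ψ]|²
```

where `Ψ = F[f]`. Each LED therefore samples one circular sub-aperture of the
object spectrum, centered at the illumination spatial frequency
`(sin θx, sin θy)/λ`. Reconstruction alternates, for every LED, between

1. extracting the current sub-aperture estimate and transforming it to an LR
   image (keeping its phase),
2. replacing its amplitude with the square root of the measured intensity,
3. transforming back and overwriting the sub-aperture inside the pupil
   support,

sweeping all LEDs until self-consistent. Because real LEDs differ in
brightness and the sensor response is not perfectly linear, each image `i`
carries an unknown multiplicative factor `c_i`; a simulated-annealing step
embedded in the loop refines `c_i` against the current model image
(cost `Σ (√(I_i/c_i) − |model|)²`, Metropolis acceptance, geometric cooling)
before each amplitude replacement. Without this correction the HR background
shows characteristic ripples; with it they are removed.

## Worked example

Simulate the default platform (31 × 31 LED array at 2.5 mm pitch, 93 mm from
the sample, λ = 633 nm, 2× / NA 0.1 telecentric objective, 3.45 μm 10-bit
camera, ring-wise exposures 100/150/450/700 ms) imaging a four-element bar
chart, then reconstruct and evaluate:

```r
library(FPtycho)
cfg <- validateRunConfig()          # the default platform configuration
report <- runPipeline(cfg, outDir = "fpm-run")
#> geometry: illumination NA axial 0.374 / radial 0.495, overlap ratio 0.829
report$metrics
#> $sweeps                       10
#> $final_cost                   0.1181
#> $smallest_resolved_period_um  1.6
#> $background_ripple            0.03259
#> $rmse_complex                 0.06547
```

Read: the LED array provides an illumination NA of 0.374 on-axis (0.495 at
the corners) and adjacent sub-apertures overlap by 83%, comfortably above the
phase-retrieval requirement. The raw camera images cannot resolve anything
finer than the coherent cutoff `λ/NA ≈ 6.3 μm`; after ten reconstruction
sweeps with SA factor correction, the 1.6 μm bars of the synthetic chart are
resolved at Michelson contrast ≥ 0.2, the blank background has a residual
ripple (std/mean) of 3.3%, and the recovered complex field differs from the
ground-truth chart by 6.5% relative RMSE (global phase/scale removed). All
artifacts (TIFF stacks, recovered factors, per-element metrics CSV, JSON run
report) are written under `fpm-run/`.

The same pipeline is available from a shell:

```sh
Rscript inst/scripts/fpm.R all --out fpm-run          # defaults
Rscript inst/scripts/fpm.R simulate --config run.yaml # custom platform
```

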