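---
title: "Fourier ptychography with an industrial camera: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier ptychography with an industrial camera: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FPtycho)
```

## Scope

FPtycho models the full acquisition and reconstruction chain of a Fourier
ptychography microscope built from an LED-array illuminator, a fixed-NA
objective and an industrial camera, and evaluates reconstructions
quantitatively. This vignette explains the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic experiments do
and do not demonstrate about real data. Hardware control, physical alignment
procedures, aberrated pupils and LED-position self-calibration are out of
scope.

## Imaging model

The object is a sampled 2-D complex transmission function on a square grid
(`ComplexField`). Illumination by the LED at array index $(m, n)$ is treated
as a plane wave over the imaged patch (the patch is small compared to the
LED standoff), with spatial frequency

$$ (f_x, f_y) = \frac{(-x, -y)}{r\,\lambda}, \qquad
   r = \sqrt{x^2 + y^2 + z^2}, $$

where $(x, y, z)$ is the LED position relative to the patch center
(`waveVector`). The sign convention — the captured sub-aperture is centered at
$+(f_x, f_y)$ — is shared by the simulator and the reconstructor; a global
flip would be self-consistent and invisible in intensities. Frequencies are
cycles/μm throughout; $2\pi$ factors live only inside the transforms.

The objective is an ideal circular pupil of cutoff $\mathrm{NA}/\lambda$
(0.158 cycles/μm for the default NA 0.1 at 633 nm). Pixels whose center lies
strictly inside the cutoff get weight 1, all others 0; there is no
apodization and no aberration (`pupilMask`). For one LED the ideal camera
intensity is

$$ I = \bigl|\mathcal{F}^{-1}\{\Psi(k)\,P(k - k_{mn})\}\bigr|^2 $$

evaluated on the camera grid. The object is simulated on a finer grid (the
reconstruction pitch) and downsampled by cropping the spectrum — ideal
band-limited sampling, which is exact for a coherent model whose passband
fits in the cropped window. Area-integrating pixels are not modelled.

## Camera and exposure model

The industrial camera is characterized by a full well of $10^5$ electrons,
giving a full-scale shot-noise SNR of $\sqrt{10^5} \approx 316$
($20\log_{10} \approx 50$ dB, matching the nominal dynamic-range figure of
the sensor class being emulated), 10-bit quantization, and 50 e⁻ RMS read
noise. The photon budget (700 e⁻ per ms of exposure per unit ideal
intensity) puts a unit-intensity pixel at ~70% of full well for the 100 ms
central exposure — the headroom a practitioner would leave. Each image is
rendered as

ideal intensity × factor × exposure × duty → Poisson shot noise → Gaussian
read noise → gain → clip to $[0, 2^{10}-1]$ → integer codes,

with clipped pixels flagged in a saturation mask (`simulateStack`). All of
these are configurable (`cameraModel`); `idealCameraModel()` keeps the
radiometric chain and the clipping but removes noise and quantization for
algorithm-consistency experiments.

Low dynamic range is compensated the way such platforms do it: exposure
times follow a ring-wise schedule — 100 ms for the central 7 × 7 LED block
(rings 0–3), 150 ms for the five rings around it (4–8), 450 ms for the next
six rings (9–14) and 700 ms for the outermost ring — and `normalizeStack`
divides each image by (exposure × duty × photon budget), restoring one
common radiometric scale before reconstruction. The published description of
this schedule is internally inconsistent about where the 450 ms group starts
(its second group ends at ring 8 but the third is described as surrounding a
19 × 19 block); the default map assigns the ambiguous ring 9 to the 450 ms
group, and the map is a plain numeric vector the user can replace. Duty
cycles default to 1 because only exposure times are published.

Per-LED brightness inconsistency — differing LED dies, angular falloff,
sensor nonlinearity — is modelled as one multiplicative factor per image,
drawn i.i.d. lognormal with median 1 (`drawFactors`). The default log-scale
σ = 0.2 produces the visible background ripple that motivates the
correction; it is a plausible magnitude for unbinned consumer LED arrays,
chosen once for all experiments.

## Reconstruction

`fpmReconstruct` implements the alternating-projection stitching loop:
initialize the HR spectrum from the band-limited upsampled square root of
the on-axis image with zero phase; then for each LED extract the shifted,
pupil-masked sub-aperture, transform to an LR image, replace its amplitude
by the (factor-corrected) measured amplitude, transform back, and overwrite
the sub-aperture inside the pupil support. Saturated pixels keep the model
value: they carry no radiometric information. Sub-aperture centers snap to
the nearest HR frequency bin; sub-pixel shifts are not refined, matching the
discrete windowing of the model. Zero-valued model pixels take phase 0 at
replacement (an arbitrary but fixed tie-break).

Tunables, with defaults:

* `upsamplingFactor` — HR/LR grid ratio; `NA` auto-selects the smallest
  integer giving Nyquist sampling of the synthetic aperture
  $\mathrm{NA}_{obj} + \mathrm{NA}_{ill}^{radial}$, and is logged.
* `updateOrder` — `center_out_spiral` (default; low frequencies first, the
  standard choice because the bright-field images carry most of the energy)
  or `raster` (used when comparing against the straight-line oracle).
* `maxSweeps` 10, `relTol` 1e-3 — the published algorithm states only
  "until self-consistent"; these are declared defaults, not inferred ones.
  The convergence metric is the mean over LEDs of the relative L2 difference
  between measured and model amplitudes; the loop stops when its relative
  change drops below `relTol`. A non-finite cost aborts with an error.

## Simulated-annealing intensity correction

Each image's factor $c_i$ is refined inside the loop, just before its
amplitude replacement, by a short Metropolis random search on the cost
$\sum (\sqrt{I_i/c_i} - |\text{model}|)^2$ over unmasked pixels (amplitudes,
not intensities, to match the geometry of the replacement step; an intensity
cost is a config option away in `brightnessCost`). Each visit makes 3
multiplicative proposals $c' = c\,e^{\varepsilon}$,
$\varepsilon \sim U(-0.1, 0.1)$; downhill moves are always accepted, uphill
moves with probability $e^{-\Delta E/T}$; the *best accepted* state is
returned, so a visit never ends worse than it began while the chain can
still traverse uphill. The temperature is auto-initialized to the median
absolute cost change of the first sweep's proposals (that sweep itself runs
greedily, since no temperature exists yet) and cooled by ×0.9 per sweep with
a floor. The published flow chart gives no schedule constants; all of these
are declared defaults and configurable (`saConfig`).

The forward model is invariant to one global brightness scale (all $c_i$
times $g$, HR amplitude times $\sqrt{g}$), so factors are identifiable only
up to that scale. The on-axis factor is pinned to 1 as a nominal anchor, but
with hundreds of images the equilibrium scale is set collectively, so
recovered factors should always be compared as ratios (both sets normalized
by their medians), which is how the package's experiments report them.

## Synthetic samples and what the experiments show

`barTarget`/`usafLikeTarget` build chrome-on-glass-style charts: dark bars
(amplitude 0) of width period/2 on a unit background, hard-edged, with a
pixel belonging to a bar iff its center does — so resolvability is governed
by the imaging model, not by generator anti-aliasing, at the cost of
rounding partial-pixel bars to whole pixels. Elements are parameterized by
their period directly rather than by USAF group/element labels, whose
line-pair frequencies vary between quoted conventions; the bundled chart uses
periods of 6.6, 4.4, 2.19 (465 line pairs/mm) and 1.6 μm. `phaseObject` builds a
transparent specimen: unit amplitude, band-limited Gaussian-noise phase
scaled to a chosen maximum — a stand-in for unstained tissue.

These synthetic objects are deliberately simple: they have no thick-specimen
scattering, no partial coherence, no fixed-pattern sensor noise, no LED
position errors (the geometry accepts offset/roll misalignment terms, but the
experiments keep them zero), and the phase target is smooth rather than
histologically structured. Passing the package's experiments therefore shows
that the algorithm chain is internally consistent and robust to the modelled
error sources — brightness inconsistency, shot/read noise, quantization,
saturation — not that any particular real specimen will reconstruct equally
well.

## Evaluation

`lineProfile` extracts bilinear-interpolated profiles; for a chart element
the profile runs perpendicular to the bars through the element center, 1.5×
the element extent, ~8 samples per period. `resolvable` counts bar-polarity
extrema after a persistence-style simplification: adjacent extrema pairs
with Michelson contrast $(\max-\min)/(\max+\min)$ below the threshold are
merged away (they are noise or coherent ringing, not structure), and the
element is resolved when at least `n_bars` bar extrema survive. The default
threshold 0.2 sits below the classical two-point Rayleigh contrast (~0.26)
but is strict enough to reject noise; published resolvability judgements are
visual, so this numeric criterion is this package's operationalization, and
every experiment states the threshold it used. `smallestResolvedPeriod`
scans a chart's elements; `backgroundRipple` is the coefficient of variation
over a blank region; `rmseComplex` removes one global complex scalar (the
unobservable phase/scale gauge) before computing the relative error.

## Problem sizes

The bundled experiments use a 64 × 64-pixel camera patch, LED rings 0–9
(361 images) and an upsampling factor of 3 (192 × 192 HR grid) — the
smallest configuration whose synthetic aperture (illumination NA 0.32
radial) comfortably spans the 2.19 μm chart element while every shifted
pupil still fits the HR grid. The full 31 × 31 array (961 images, as
acquired by the platform being modelled) runs in the default pipeline
configuration in about a minute. Sweeps are fixed at 10 with `relTol = 0` in
the experiments so runs are exactly reproducible for a given seed.

## Known limitations

* Ideal binary pupil only: no aberration recovery or embedded pupil
  estimation; platform aberrations will appear as unmodelled residuals.
* Plane-wave-per-patch approximation: large fields of view must be
  reconstructed patch-wise.
* Spectral-cropping downsampling assumes the camera pixels sample, not
  integrate; fine pixel-scale effects are ignored.
* The SA correction absorbs only per-image scalar brightness; spatially
  varying illumination inside one image is not modelled.
* Factors, and the HR field, are recovered up to one global complex
  scale/phase; all reported metrics are gauge-invariant.
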