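---
title: "Methods: characterizing FGS imaging systems with fgsqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing FGS imaging systems with fgsqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgsqc)
```

## Why a characterization pipeline

Open-field fluorescence-guided surgery (FGS) systems overlay the emission
of a near-infrared contrast agent (dominantly indocyanine green, ICG;
excitation near 780 nm, emission near 820 nm) on a white-light video of
the surgical field. Systems from different vendors differ in excitation
sources, collection optics, sensors, and display processing, and these
differences are invisible to a surgeon unless they are quantified the
same way on every system. `fgsqc` implements a standardized nine-test
characterization over tissue-mimicking fluorescent phantoms: excitation
band (peak and FWHM), illumination power density (bookkept, not
measured), spatial resolution and sharpness, field-of-view (FOV)
uniformity, spatial distortion, depth of field (DOF), concentration
sensitivity, imaging depth, and signal-to-background ratio (SBR).

Because physical phantoms and instruments are not required to exercise
the analysis code, the package also contains a synthetic phantom
generator with a parametric camera model and recorded ground truth.
Every metric in the package is validated against that ground truth.

## The metrics

### Excitation band

A spectrometer trace is reduced to its peak wavelength and full width at
half maximum (FWHM, nm). The baseline is estimated as the median of the
lowest decile of intensities and subtracted; this is robust to dark
signal and neutral-density offsets and costs nothing when the trace is
already baseline-free. Half-maximum crossings are located by linear
interpolation between the bracketing samples on each side of the peak.
No smoothing is applied by default because any smoothing widens an
estimated FWHM; a 3-point moving median is available for traces with
isolated hot samples. Ties at the maximum resolve to the centroid of the
maximal plateau so the result is deterministic. Peak and FWHM are
invariant to intensity scaling, so raw and max-normalized spectra give
identical results; whether the input was normalized is recorded.

### Resolution, sharpness, and depth of field

A USAF-1951 element at `(group, element)` has spatial frequency
`lp/mm = 2^(group + (element - 1) / 6)` and single-line width
`1000 / (2 * lp/mm)` micrometres. Contrast is scored per element as a
contrast transfer function

```
CTF(%) = 100 * (max(r) - min(r)) / (max(r) + min(r))
```

where `max(r)` and `min(r)` are the means of the top and bottom 20% of
pixel values in the element region — percentile extrema rather than
single pixels, which makes the score robust to isolated noise. Two
documented decisions matter here:

* A background-threshold mask (default 0.2 of the image maximum, valid
  range 0.1–0.4) localizes and validates the target extent, but does
  *not* remove pixels from the percentile statistics: dark bars
  legitimately fall below any such threshold, and removing them would
  make the contrast ratio meaningless. The threshold actually used and
  the masked fraction are recorded in every result.
* Horizontal and vertical bar blocks are scored separately and averaged
  (`orientation = "mean"`), for the sharpness curve and the DOF curve
  alike, so astigmatic blur is not hidden.

The sharpness curve scores the nine-element set at 1.0–6.35 lp/mm and
reports a resolving limit: the highest frequency with mean CTF at or
above a criterion (default 40%). The DOF curve scores only the 1.0 lp/mm
element across a stack of frames at signed defocus distances `z`
(negative = closer to the lens) and reports the widest contiguous
interval of sampled `z` with CTF at or above 60%, ties broken toward the
interval containing the plane of focus. An empty interval is a reported
outcome, not an error.

Percentile-extrema CTF has a known behavior worth stating: once blur is
strong enough that the bar pattern is gone, the score does not fall to
zero but to a floor (roughly 20–30% on these fixtures) produced by the
intensity envelope of the element block itself, and for elements whose
bars approach the pixel pitch the score can fluctuate non-monotonically.
The resolving-limit criterion (40%) sits above this floor, and the tests
assert monotonicity only over well-sampled elements (bars of at least
2 px).

### FOV uniformity

The illumination-detection uniformity profile is the column-mean of a
horizontal band of rows centered mid-image (50 rows above and below by
default), normalized to its maximum, with both axes normalized for
display. Summary statistics: the fraction of columns at or above 0.9,
the profile minimum, and the center-to-edge ratio. Pixels occluded by
burned-in vendor overlays can be masked; masked pixels are zeroed for
display, excluded from the column means, and fully masked columns are
interpolated from neighbors and flagged.

The synthetic generator vignettes with a radial quadratic
`V(r) = 1 - v * (r / r_max)^2` (with `r_max` the half-diagonal), the
simplest single-parameter model spanning the profile shapes seen on real
systems. `estimate_vignette()` inverts this model analytically from the
profile minimum, accounting for the band's vertical extent and for the
normalization of the profile to its center maximum; recovery is within
0.02 of truth noise-free and within 0.05 at the generator's default
noise.

### Spatial distortion

Dots of a fluorescent dot-grid phantom are detected along the two dot
rows nearest mid-height (auto-detected from the row-mean profile, or
supplied explicitly). Each band's column-mean profile yields local
maxima with prominence at least 0.2 of the profile range and minimum
separation of half the median spacing; positions are refined to subpixel
accuracy by 3-point parabolic interpolation, because pixel-quantized
peaks alias spacing estimates on coarse grids. Successive differences of
positions are normalized by the *maximum* spacing, so an undistorted
grid reads exactly 1 and distortion reads below 1; this reproduces the
conventional presentation of such plots. The summary index is
`1 - min(spacings_norm)`, plus a flag for the FOV side that deviates
most. When both bands return the same dot count their position series
are averaged; otherwise the richer band is used.

The generator displaces the lattice with the Brown radial model
`r_d = r_u (1 + k1 r_u^2 + k2 r_u^4)` in half-diagonal units; barrel
distortion (`k1 < 0`) compresses edge spacings exactly as the analysis
reports.

### Well panels: sensitivity, imaging depth, SBR

Well plates are quantified as the mean and standard deviation over each
1 cm well disk, normalized per panel to the maximum well mean. Well
statistics use a disk inset 3 px from the declared radius — the usual
plate-assay guard against rim pixels that optical blur mixes with the
background; the declared radius remains the geometric boundary used by
the SBR test. The QD800 well (a quantum-dot control excited by visible
room light, not an ICG signal) is reported separately and excluded from
the normalization.

* **Limit of detection.** The lowest concentration whose mean exceeds
  the control mean plus `k` control standard deviations; `k = 3` by
  default, the conventional limit-of-detection choice, and recorded.
* **Saturation.** A well is saturated when its raw mean reaches 99% of
  full scale, or when it sits on a plateau (means differing by less
  than 1% of full scale) connected to such a well. Restricting the
  plateau rule to the top of the series is deliberate: on a 16-bit
  scale the dim end of a geometric concentration series also differs by
  less than 1% of full scale, and flagging it would mistake darkness
  for saturation.
* **Imaging depth.** The deepest well above the same `k`-sigma
  criterion, plus an optional attenuation fit: a log-linear regression
  of `mean - floor` on depth over detectable, non-saturated wells whose
  negative inverse slope is the attenuation length `d_att` (mm). The
  fit is skipped, with a reason, below three usable wells.
* **SBR.** Signal power is the mean of squared pixel values over the
  well disk; background power the same over the annulus from the well
  radius to 1.5 times it ("half a radius more than the well"), and
  `SBR = 10 log10(signal / background)` dB, averaged over the 2, 3, and
  4 mm depth wells by convention. Powers are area-normalized
  (means, not sums) so that disk/annulus geometry does not enter the
  ratio; with equal areas this is identical to a ratio of summed
  squares. The dB value is invariant to global intensity scaling.

## The synthetic generator and its camera model

All fixtures pass through one fixed forward model:
**scene → defocus blur → vignette × gain → Poisson–Gaussian noise →
optional LUT → bit-depth quantization**, where quantization clamps at
full scale and thereby implements sensor saturation. Defocus blur is
Gaussian with `sigma(z) = sigma0 + s * |z|`; linear growth of blur with
distance from focus is the only property the DOF test needs, so no
optical prescription is modelled. Noise is
`Poisson(latent * p) / p + N(0, read_sd)`; both terms can be zeroed for
exact tests. Every render is a pure function of its parameters and seed,
and the ground-truth sidecar written next to each fixture is sufficient
to re-render it bit-identically.

The default study conditions, chosen once and used throughout the tests:

| Quantity | Default | Rationale |
|---|---|---|
| Camera | 16-bit, `sigma0` 0.8 px, slope 0.6 px/cm, vignette 0.05, read noise 96 DN, Poisson scale 0.125 | a well-corrected system with visible but benign noise |
| Concentration series | 1000/300/100/30/10/3/1 nM + 0 nM control + QD800 | the standard sensitivity-plate series |
| Well gain | 256 DN/nM, floor 640 DN | pegs the 1000 and 300 nM wells at full scale, as real systems saturate at the top of this series |
| Designed LoD | 3 nM | follows from gain, floor, and noise under the 3-sigma rule |
| Depth series | 0.5, 1, 1.5, 2, 3, 4, 5, 6 mm + 6 mm control | eight overburden steps spanning 0.5–6 mm |
| Depth signal | `I0` 24000 DN, `d_att` 1.1 mm | places the 3-sigma detectability boundary at 4 mm, the depth at which such systems reliably recover signal |
| Dot grid | 5 × 9 dots, 40 px pitch, Gaussian dots (sigma 2 px) | subpixel-recoverable centers |
| Spectrum | center 780 nm, sigma 1.25 nm (FWHM 2.94 nm) | an ICG-band diode source |
| USAF scale | 20 px/mm, elements 1.0–6.35 lp/mm | coarsest bars 10 px, finest 1.57 px |

What the generator emulates: defocus, vignetting, radial distortion,
shot and read noise, quantization, saturation, display LUTs, and the
phantom geometries above. What it does not: physically based light
transport in turbid media (phantom optical properties such as
`mu_a ~ 0.018 mm^-1`, `mu_s' ~ 1.4 mm^-1` are carried as metadata only,
never mapped to intensity), fluorophore photochemistry, color-overlay
rendering, or anthropomorphic geometry. Passing tests therefore
demonstrate that the *analysis* is correct under a faithful sensor
model, not that any physical system meets a specification.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based, row-major, origin top-left; rectangles
  are half-open. Circle membership is by pixel-index center.
* Percentile counts for CTF round up (at least one pixel per side), by
  value rank with stable ordering, so tiny regions stay deterministic.
* An all-dark CTF region returns a flagged degenerate result
  (`ctf = NA`), not an error; a DOF stack in which no frame reaches the
  criterion returns an empty range.
* In-focus plateaus of equal width resolve toward the interval
  containing `z = 0`, matching the intent of a focus test.
* `lm()` performs the attenuation fit; `d_att` is `-1/slope` of
  `log(mean - floor)` on depth.
* Videos: acquisition conventions take a single frame at position
  1/totalframes, i.e. the first frame; this build reads TIFF/PNG/JPEG
  frames (JPEG flagged lossy in provenance) and rejects MP4 with an
  instructive error because no video decoder is bundled. Extract the
  first frame to TIFF/PNG upstream.
* On-disk images are 16-bit TIFF with DN stored over the full container
  scale, so any sensor depth up to 16 bits round-trips bit-identically;
  the true sensor depth travels in the layout/ground-truth sidecar and
  overrides the container-inferred depth on load.

## Problem sizes

The test-suite fixtures are deliberately desk-scale: images of roughly
240 × 400 to 400 × 400 px, 15-frame DOF stacks, 20-seed panels for the
detection-rate checks. The full suite and a complete nine-test protocol
run each finish in seconds; the sizes are chosen to keep property-based
checks cheap while leaving every geometric quantity (bar widths, well
radii, dot pitches) comfortably oversampled.

## Known limitations

* The CTF floor of percentile extrema under heavy blur (above) means
  CTF values below ~30% are not comparable across targets with
  different block geometry; the resolving-limit criterion avoids this
  regime.
* `estimate_vignette()` assumes the radial-quadratic model; on profiles
  from other falloff shapes it returns a best-effort equivalent
  strength.
* Dot detection assumes dots resolvable as distinct column-profile
  peaks; overlapping dots (pitch below ~4 sigma of the dot footprint)
  will merge.
* Multiple vendor display modes (LUTs) are treated as separate systems:
  one report per mode, compared side by side with `compare_reports()`.
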