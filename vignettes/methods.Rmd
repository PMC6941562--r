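---
title: "Methods: colour-threshold morphometry of infarcted hearts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour-threshold morphometry of infarcted hearts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomorph)
```

## The measurement problem

In small-animal models of myocardial infarction the heart is serially
sectioned from apex to base (here every 300 µm), trichrome-stained and
imaged. Collagen — the scar replacing infarcted muscle, and the fine
interstitial fibrosis between surviving fibres — stains blue to
blue-gray; viable myocardium stains red; the slide background is
near-white. The quantities of interest are ratios of pixel counts:
infarct size per section and per volume, collagen content of the scar,
and fibrosis of the remote wall. `cardiomorph` computes all of them
from an explicit per-pixel colour classification, so every reported
percentage can be audited back to pixel counts.

## The classifier

Each pixel carries an 8-bit RGB triple (plus optional alpha). The
class tests, applied in a configurable precedence order with the first
match winning, are:

| class | test | default parameters |
|---|---|---|
| background | `min(R,G,B) >= background_min_channel`, or alpha = 0 | 230 |
| collagen | `B >= R + blue_margin` and `B >= G`; **or** `max−min <= gray_spread` with all channels in `[gray_low, gray_high]` | 20; 15, [90, 200] |
| muscle | `R >= B + red_margin` | 20 |
| other tissue | always (fallback) | — |

Assumptions: staining is reasonably uniform across the batch (all
sections stained together), illumination is white-balanced, and the
image is 8-bit RGB — there is no colour deconvolution and no second
colour space. The two-sided gray window is the operational encoding of
the blue-to-gray hue gradient of scar collagen: washed-out collagen
desaturates toward gray while never becoming red-dominant, so a
low-spread mid-intensity pixel is counted as collagen. The window is
deliberately bounded above (200) so that it can never leak into the
background class, and below (90) to exclude dark nuclei and debris.

No published threshold constants exist for this staining workflow;
the defaults above were fixed once, from the colour geometry of
trichrome palettes (saturated blue ≈ (30, 30, 200), scar-margin
blue-gray ≈ (140, 140, 170), muscle red ≈ (200–220, 40–90, 40–90),
slide ≈ (245, 245, 245)), and every constant is user-configurable via
`threshold_scheme()` or a YAML file. The margins (20) are half the
smallest channel separation between palettes, which leaves symmetric
headroom for stain variation on both sides.

Numerical determinism: the precedence order (default background >
collagen > muscle > other) is the only tie-break; the vectorised
segmenter paints classes in reverse precedence so the first matching
class wins, and it is tested pixel-for-pixel against a naive scalar
loop. Fully transparent pixels are always background, whatever the
precedence — segmentations with transparent backgrounds must re-import
losslessly.

Optional cleanup: `min_object_px` removes tissue-class connected
components below a size threshold. It is off by default because raw
pixel counting is the primary measurement — single-pixel blue speckles
*are* the interstitial fibrosis signal and must not be eroded.

## Morphometry

For section *i* let θᵢ be its tissue area (all non-background pixels)
and ϑᵢ its infarcted area (collagen pixels — of the scar ROI when one
is supplied, of the whole section otherwise). `other_tissue` counts
toward θ but toward neither collagen nor muscle: total tissue area
visibly exceeds the blue plus unambiguously-red area, and discarding
ambiguous pixels from the denominator would inflate every percentage.

* per-section infarct size: 100 · ϑᵢ / θᵢ;
* average infarct size: unweighted mean over measured sections;
* volumetric infarct size: 100 · Σ ϑᵢ·nᵢ / Σ θᵢ·nᵢ, with nᵢ the slab
  thickness in pixels per spacing interval (default 1). With uniform n
  the weight cancels exactly, which the tests assert; the volumetric
  value equals the area-weighted mean of the per-section percentages
  and differs from the plain average whenever infarct burden correlates
  with section size (apical infarcts: volumetric < average).

Scar collagen content is collagen / tissue within the scar ROI;
interstitial fibrosis is collagen / tissue within the remote ROI. The
fibrosis numerator is deliberately the *collagen* (blue) class even
though the quantity characterises the red remote wall: fibrosis is
collagen deposited between red fibres, so blue pixels inside the
remote ROI are the signal and the red muscle is the denominator's
bulk. A red-based numerator would measure muscle, not fibrosis.

Missing measurements (a section with no scar ROI, or an unmeasurable
apex tip) are `NA` and are skipped by all averages — never imputed as
zero, since a zero is a real measurement ("no fibrosis") and `NA` is
not. Reported percentages are rounded half-even to 2 decimals at the
report-writing stage only; all computation keeps full precision.

Degenerate inputs: a zero tissue area makes the per-section fraction
undefined and raises an error rather than returning 0/0; an empty
series is an error; an all-background stack reports 0 % infarct.

## The voxel stack

Serial class maps are assembled apex-to-base into a 3D label array,
each section replicated into `z_step_px` slabs. Registration is
centroid translation only — each section is shifted in whole pixels so
its tissue centroid lands on the canvas centre. Rotation, scaling and
elastic registration were considered and rejected: translation is the
only transform that provably preserves every per-class pixel count
(padding is background), so the stack's voxel arithmetic stays exactly
consistent with the per-section morphometry, which the tests assert as
an identity. The stack is for visual control (scar geometry, ligature
level) and volumetric cross-checking, not for sub-pixel anatomy.

Slices export as RGBA PNGs with transparent background plus a JSON
sidecar (slab thickness, spacing, offsets, colour legend), and
re-import reproduces the label array exactly.

## The phantom generator

`phantom_spec()` paints an annular left-ventricular wall on a
near-white canvas: a blue wedge of configurable angle stands in for
the scar (transmural or outer-half-wall), the remaining wall is red
muscle, and single blue pixels sprinkled over the muscle at a
configurable density emulate interstitial fibrosis. Colours are drawn
from palettes spanning saturated blue to blue-gray and deep to light
red, with optional per-channel integer jitter. Ground truth counts the
rasterised pixels during painting, so there is no rasterisation
tolerance in any comparison.

The jitter bound (≤ 4 intensity units) is not cosmetic: the collagen
palette's worst-case blue-over-red excess is 29 after integer
rounding, so jitter of ±4 on both channels still leaves ≥ 21 > 20 =
`blue_margin`. Within that bound segmentation recovers ground truth
*exactly*, by construction — the acceptance tests assert identity, not
closeness, over 100 random 256×256 phantoms.

Series generation tapers the radii linearly (default: sections grow
toward the base, the usual anatomy) and shrinks the wedge angle to
zero at the base, mimicking an apical infarct. Default study geometry:
256×256 px canvas, outer radius 70 px, wall half the radius, 150°
apical wedge, 2 % fibrosis density — a mid-sized mouse heart at low
magnification.

What the phantom does **not** emulate: out-of-focus blur, chromatic
shading, staining batch effects, tissue folds and tears, and the
continuous colour mixtures of real stained tissue. Passing the phantom
round trip therefore demonstrates that the counting, morphometry,
stacking and reporting machinery is exact downstream of
classification; it does not validate the default thresholds against
real slides, which should always be spot-checked visually via the
overlay images.

## Problem sizes in the test suite

The suite segments ~150 images of 32–256 px square (the 100-phantom
round trip dominates), runs the full pipeline on 2–5-section series at
96–256 px, and completes in well under a minute; the acceptance script
re-runs the 100-phantom round trip and a 5-section end-to-end series
in a few seconds. These sizes were chosen as the smallest at which
every geometric regime (transmural/non-transmural, empty and full
wedge, tapered series) is exercised.

## Known limitations

* Thresholds are global per run; strongly variable staining across a
  batch needs per-batch scheme tuning (all sections of one heart
  should be stained together).
* RGB-only classification cannot separate overlapping chromogens the
  way colour deconvolution can; it is intended for well-separated
  trichrome palettes.
* Centroid alignment does not correct rotation between sections; the
  stack is count-exact but visually approximate for twisted hearts.
* JPEG input is supported but lossy; count-exact round trips are only
  guaranteed for PNG (and 8-bit TIFF) inputs and outputs.
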