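---
title: "Multi-scale tiled inference for small-lesion detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale tiled inference for small-lesion detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammotile)
```

## The problem

Full-field digital mammograms are very large images (nominally
3328 × 4096 px at a 50–100 µm pixel pitch) in which the clinically
decisive finding — an early cancer — may be a mass under 1 cm in
diameter, i.e. well under 1 % of the image area.  Any detector with a
bounded receptive field faces a three-way tension:

* **Resolution.**  Downsampling the image to fit the detector destroys
  the fine detail (sharp margins, spiculations) that makes small masses
  detectable at all.
* **Scale.**  At full resolution, a large mass no longer fits inside
  the receptive field, so its shape and margins are never seen whole.
* **Context.**  A crop that covers only a small patch of breast cannot
  use surrounding-tissue cues; a crop that sees the whole breast can.

`mammotile` implements the inference-side machinery that resolves this
tension without touching the detector itself: the image is rescaled to
a pyramid (X, 0.5X, 0.25X by default), each level is cut into
systematic full-coverage strips of fixed length (1024 px at nominal
geometry — a quarter of the long axis), the detector runs per strip,
per-strip boxes are remapped into the full-resolution frame, and the
per-scale prediction sets are combined by Weighted Box Fusion (WBF).
Evaluation is by free-response ROC (FROC) with the center-in-box hit
criterion standard in mammography CAD.

## Pipeline geometry

A coordinate frame is `(scale s, tile offset)`; a box coordinate `c` in
a tile maps to `(c + offset) / s` at full resolution.  The transform is
exactly invertible, and all modules exchange boxes either in the
full-resolution frame or with an explicit frame attached.  Boxes are
0-based, half-open `[min, max)`, y-down, stored as doubles (remapping
by `1/s` produces fractional pixels; rounding happens only at
rasterization).

Tiling is by full-width strips along the long axis: offsets advance by
`tile_len` and the final strip is anchored at `L − tile_len`, so strips
may overlap but no pixel is ever uncovered — the coverage guarantee is
property-tested over randomized geometries rather than assumed.  With
the nominal geometry the per-scale tile counts are 4 / 2 / 1: the
single 0.25X tile sees the whole breast (maximum context), the four X
tiles each see a quarter (least context).

Downscaling uses area averaging (anti-aliased, exact on constants);
upsampling is bilinear.  Within a scale, duplicate detections across
overlapping strip seams are removed by NMS at IoU 0.5 (configurable,
and separate from cross-scale fusion, which operates on the per-scale
sets).

## Fusion

Greedy NMS discards all but the best box of an overlapping group.  WBF
instead averages: processing detections in descending score order, each
either joins the fused cluster with which it has the highest IoU above
the threshold (0.55 by default; NMS uses 0.5 — both conventional) or
founds a new cluster.  A cluster's fused coordinates are the
score-weighted means of its members' coordinates, and its score is the
mean member score rescaled by `min(N, T)/T`, where `N` is the cluster
size and `T` the number of prediction sources (scales).  The rescale
variant `N/T` (capped at 1) is available by flag; the literature uses
both and the choice does not affect ranking within fixed cluster sizes.
Ties during greedy processing are broken by larger area, then input
order, making both fusers deterministic.  "NMS with thresholds" is
interpreted as a score floor applied before NMS; the floor is a
configuration value.

## Evaluation

A prediction detects a lesion iff its box **center** lies inside the
ground-truth box — overlap alone does not count, and the test suite
pins the overlapping-but-center-outside counterexample.  By default,
several predictions hitting one lesion count as one hit and no false
positives, one prediction inside several (nested) ground-truth boxes
credits all of them, and lesion-free images enlarge the
false-positives-per-image (FPI) denominator; all three conventions are
switchable, since published evaluation protocols rarely state them.
The FROC curve is computed exactly, sweeping thresholds over the unique
prediction scores; `sensitivity_at_fpi()` uses the conservative step
readout (no interpolation), so it never over-credits.  Correctness is
established against exhaustive brute-force matchers and sweepers, not
against reimplementations sharing code with the pipeline.

## The phantom world

The clinical datasets behind this design are private, so the package
ships a seeded generator of mammography-like phantoms: a half-ellipse
breast flush with one lateral edge (40–70 % of image area), filled with
Gaussian-low-pass parenchymal texture (σ = 8 px at nominal resolution,
amplitude 3 % of the 16-bit dynamic range around a 35 % mid-gray — the
simplest stationary texture that gives a classical detector a realistic
false-positive floor), on a near-zero dark field.  Masses are
raised-cosine tapered discs: physical diameter in mm converts to pixels
via the pixel spacing (`mm_to_px`), the center intensity is raised by
`lesion_contrast` × dynamic range (default 0.3), and edges fall
smoothly to zero at the disc radius, mimicking the soft margins of real
masses.  Optional spiculations add 4–8 thin radial lines of length 1–2
radii.  Ground-truth boxes are tight on the disc support; placement is
by rejection sampling inside the breast with a minimum pairwise center
distance of three lesion diameters.  Output is bit-identical for a
fixed spec and seed.

What the phantom does **not** model: X-ray physics, anatomy-correlated
clutter (ducts, vessels, pectoral muscle), microcalcification clusters,
multi-view pairing, vendor post-processing.  A green directional test
therefore establishes that the *pipeline geometry* behaves as designed
under a controlled image model — not that any clinical sensitivity
would be attained.

## The reference detector

The pluggable detector contract is a pure function
`(image, config) → scored boxes in the tile frame`.  The shipped
reference is a difference-of-Gaussians blob detector over a geometric
sigma ladder bounded to `[sigma_min, sigma_max]`, with strict 3×3×3
scale-space maxima, boxes of half-side `2σ`, and the monotone squash
`score = r/(r + 0.02)` mapping responses into [0, 1] (any monotone map
is equivalent for ranking-based evaluation).  The bounded band is the
receptive-field analog: a structure whose effective width falls outside
the band is invisible at that scale, which is exactly what makes
multi-scale processing necessary, and makes the resolution / scale /
context phenomena reproducible with a deterministic CPU detector
instead of a trained network.

A tapered disc of physical diameter D mm has an effective Gaussian
width of ≈ 0.75·D px per mm-to-px unit; the default band [2.5, 7] px
with threshold 0.12 was calibrated once, before the acceptance tests
were written, so that 4–9 mm lesions respond at full resolution in the
quarter-scale test world while the parenchymal noise floor (≈ 0.09–0.12)
stays mostly below threshold, and 20–32 mm masses respond only at
0.25X.  These defaults were then frozen.

## Scaled-down test world

All end-to-end tests and the directional acceptance checks run on a
quarter-scale world: 832 × 1024 px at 280 µm spacing with
`tile_len = 256`.  Physical lesion sizes (mm) and every geometric ratio
— including the 4 / 2 / 1 per-scale tile counts — are identical to the
nominal world; only the pixel budget shrinks (16×), keeping the full
5-seed directional suite within a CPU-minutes budget.

## Ablation harnesses as re-inference experiments

The original ablations retrain a network per arm; here they are
**re-inference** experiments with one fixed detector, which isolates
the pipeline-geometry claims from training effects — a deliberate
reinterpretation, and the harness asserts that all arms of an ablation
share images, ground truth, detector, fusion and evaluation settings
(via configuration hashes), differing only in the manipulated factor.

* **Resolution:** the negated arm rebuilds every pyramid level by
  upsampling the 0.25X image (to exactly the proposed arm's level
  dimensions), run on a sub-centimetre mix: down-up resampling
  attenuates small-lesion responses more than it attenuates the
  (already coarse) texture, so the negated arm loses sensitivity.
* **Scale:** a full-resolution-only arm on a mixed-size set misses the
  large masses that exceed the band at X.
* **Context:** with resolution fixed (all levels from the upsampled
  0.25X base), each scale is evaluated separately, pre-fusion.  The
  harness dataset uses 20–32 mm masses, whose extent fits the band only
  at the 0.25X (single-tile, maximum-context) arm — the desk-scale
  analog of a mass visible in its entirety only when the crop carries
  enough context.  With a purely local detector this is the mechanism
  by which the context gradient manifests; seam truncation at tile
  borders contributes secondarily.
* **Per-scale analysis:** lesions hit at exactly one scale ("hit" =
  any above-threshold detection whose center rule fires) are averaged
  by annotated size per scale; with the bounded band, the
  full-resolution-exclusive mean (≈ 5 mm) sits far below the
  0.25X-exclusive mean (≈ 30 mm).  Multi-lesion images are averaged
  per lesion, not per image.

## Numerical and degenerate-input choices

* Gaussian kernels are truncated at 3.5σ with replicate padding.
* The sigma ladder is padded by one level below and two above the band
  so every in-band sigma is an interior scale-space layer.
* `rescale(image, 1)` and zero-offset remaps are exact identities.
* An all-background image yields an empty foreground mask (the caller
  decides); cropping it is an error, as is a zero-lesion ground truth
  in FROC (sensitivity undefined).
* Box CSV round-trips use 17 significant digits, preserving doubles
  exactly; images round-trip bit-exactly through 16-bit PGM (binary P5
  or ASCII P2 — no pre-installed R package writes 16-bit PNG/TIFF, so
  PGM is the supported on-disk format).
* All library randomness flows through explicit seeds and restores the
  caller's RNG state; inference itself contains no randomness, so
  pipeline reruns are byte-identical.

## Known limitations

The phantom's stationarity makes the false-positive floor milder than
clinical parenchyma; the reference detector has no notion of margin
morphology, so spiculation is texture to it; strips are 1-D (full-width)
rather than 2-D grids, sufficient for the implemented geometry but not
for arbitrarily wide images; and the directional checks are majority
votes over 5 seeds, not confidence-interval statements.
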