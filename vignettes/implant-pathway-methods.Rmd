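---
title: "Deriving implant pathways from oriented tooth boxes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving implant pathways from oriented tooth boxes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantpath)
```

## Problem and model

A single-tooth edentulous gap on a dental panoramic radiograph (DPR) is
flanked by two teeth whose inclinations constrain where an implant can go.
Given oriented bounding boxes (OBBs) of those two teeth — center $(c_x,
c_y)$, sides $w \le h$, rotation $\theta$ — the package derives the implant
pathway in three steps:

1. **Long axes.** Each tooth's long axis is the line through its box center
   along the longer side; its direction is $\theta + 90^\circ \pmod{180}$.
   This is the standard clinical angulation reference.
2. **Auxiliary lines.** From each box, the lateral edge line facing the gap
   (the long-side edge nearer the other tooth) is extended, written in
   canonical implicit form $Ax + By + C = 0$ with $A^2 + B^2 = 1$.
3. **Internal bisector.** The bisector equation
   $(A_1x + B_1y + C_1) = \pm (A_2x + B_2y + C_2)$ (denominators are 1 in
   canonical form) yields two perpendicular candidates; the one whose
   direction lies inside the wedge spanned by the two long-axis directions
   is the pathway. Parallel auxiliary lines yield their midline.

The pathway's direction therefore equals the angular mean of the two axis
directions on the short arc: for axis directions $\theta_1, \theta_2$ with
wedge span below $90^\circ$ it is $(\theta_1 + \theta_2)/2$ on that branch.
The entry point is the intersection of the pathway with the crest segment
joining the two gap-facing crown-side box corners; the rendered segment is
centered there.

```{r example}
pw <- derive_pathway(tooth_pair(oriented_box(89.5, 127.5, 36, 120, 5),
                                oriented_box(165.5, 127.5, 36, 120, 175)))
pw
```

## Conventions (fixed once, used everywhere)

* Image coordinates: 0-based, pixel centers at integer coordinates, x
  rightward, **y downward**.
* Angles: degrees, measured from the $+x$ axis towards $+y$, reduced
  modulo 180. A vertical tooth axis is $90^\circ$; its box has $\theta = 0$.
* Lines: canonical implicit form with $A > 0$, or $A = 0, B > 0$. The sign
  convention makes equality testing and the $\pm$ bisector branches
  deterministic; the canonical scaling makes the implicit form evaluate to
  signed point-line distance.
* Boxes: the $(w,h,\theta) \leftrightarrow (h,w,\theta+90^\circ)$ ambiguity
  is resolved by storing $h \ge w$; squares fitted from corners resolve
  $\theta$ to $[0, 90^\circ)$. Without this, a corner round trip could not
  recover unique parameters.

## Design choices where the construction was open

* **Edges, not axes, feed the bisector.** The gap-facing lateral edge lines
  bound the mesiodistal corridor the implant must clear, so they are the
  default auxiliary lines; `derive_pathway(use_edges = FALSE)` switches to
  the central long axes. Both give the same *direction* (edges are parallel
  to axes); they differ in the pathway's lateral position.
* **"Internal" bisector** is defined by wedge containment. When the wedge
  spans exactly $90^\circ$, both candidates qualify; the tie breaks toward
  the more vertical candidate and the result is flagged (`wedge_tie`).
* **Square boxes** make "long axis" ill-defined; the $h$-axis is used with a
  warning.
* **Parallel teeth** are a legitimate configuration, so parallel auxiliary
  lines return their midline with a `parallel` flag rather than failing.
* **Entry point**: the crest segment between the two gap-facing crown-side
  corners is the most conservative definition consistent with overlay
  figures showing entry dots at the coronal gap boundary; the pathway is not
  constrained to pass through the gap midpoint.

## Enhancement stack

The bilateral filter discretizes the double-Gaussian weighted mean with a
spatial kernel (`sigma_spatial`, default 3 px) and an intensity kernel
(`sigma_range`, default 30 levels); the window radius is
$\lceil 3\sigma_s \rceil$ (over 99% of kernel mass), boundaries are
reflect-padded, and outputs are rounded half-up then clipped so results are
bit-reproducible. Neither sigma is prescribed by the application; the
defaults are ordinary choices for 8-bit radiographic crops and every entry
point accepts overrides. With `sigma_range` large the filter provably
reduces to a plain truncated-Gaussian blur, which the tests exploit as an
independent check alongside a brute-force per-pixel reference.

Histogram equalization follows the integer CDF mapping
$s_k = (L-1)\sum_{j\le k} p(r_j)$ with $L = 256$: monotone by construction,
maps a constant image to 255, and the two-level half/half worked example to
128 and 255 (127.5 rounds up).

Composite "HE:BF" images are per-pixel weighted blends with
`ratio_he = 0.3` by default. The phrase "blending at varying degrees" could
also mean mixing whole images within a training set; both readings are
implemented (`blend_images()` per pixel; `enhance --mode mixed` assigns the
HE fraction of images deterministically by seed), per-pixel being the
default.

Augmentation semantics — the published ranges name percentages but not
operators, so the package fixes: brightness = multiplicative scale
$1 + p/100$ ($p \in [-25, 25]$); exposure = gamma transform with exponent
$1 - p/100$ on normalized intensity ($p \in [-15, 15]$); noise = additive
Gaussian with $\sigma = |p|\% \cdot 255$ ($p \in [-15, 15]$). All draws are
seeded; `augment_dataset()` doubles an image directory deterministically.

## Evaluation

Rotated IoU clips one rectangle against the other (Sutherland–Hodgman) and
is cross-checked in the tests against a vertex-enumeration + convex-hull
oracle — a genuinely different algorithm. Matching is greedy one-to-one in
descending confidence with IoU ties broken by ground-truth index. True
negatives are undefined in open-image detection, so TN = 0 and the accuracy
formula degenerates to $TP/(TP+FP+FN)$ — stated explicitly because
detection "accuracy" is otherwise ambiguous. AP uses the all-points
precision envelope by default (11-point available); which interpolation the
original evaluation framework used is not stated anywhere, so both are
exposed.

Per-image pathway agreement is the unsigned angle between line directions,
in $[0, 90^\circ]$; the summary statistic is the plain arithmetic mean. The
reference six-image comparison labels these values "MSE", but they are
degrees whose average matches a plain mean, so the package names the
quantity what it computes: mean absolute angular deviation.

## Synthetic scenes: what they emulate and what they do not

`generate_scene()` renders two tooth-shaped objects (rotated rounded
rectangles with a mild 25% root taper) at intensity 160 with ±10% per-tooth
jitter on a level-60 background plus additive Gaussian noise (default sd 8),
flanking a 40 px gap in a 256×256 crop — the geometry of a single-tooth
edentulous ROI at low contrast. Tooth axis angles default to the 75–105°
band, the realistic range of mesiodistal inclination for teeth neighbouring
a gap; wider leans at this gap width would physically collide. The emitted
labels are the exact rendered rectangles and the emitted pathway is the
analytic internal bisector, so label-path recovery is exact (to floating
point) and image-path recovery isolates the box-fitting error.

These scenes deliberately omit overlapping roots, alveolar bone texture,
spine shadows and exposure gradients. Passing the recovery properties shows
the geometry and fitting machinery are correct, not that a detector will
reach the same accuracy on clinical DPRs; detector-grade precision/recall
on real data is outside what synthetic fixtures can certify.

Box re-estimation from images thresholds midway between the intensity
extremes, labels connected components (`EBImage::bwlabel`), keeps the two
largest, and fits minimum-area rectangles (rotating calipers over the
convex hull), widening extents by 1 px for the pixel-center footprint.

## Numerical notes

* Canonicalization snaps $|A| < 10^{-12}$ to $A = 0$ so the sign rule never
  flips on rounding noise.
* Parallelism in `angle_bisectors()` is detected on canonical coefficients
  at $10^{-9}$; identical lines are a degenerate-geometry error.
* Label files store normalized coordinates at 6 decimals. This quantizes
  corner positions by $\sim 2.6\times10^{-4}$ px at 256 px, worth about
  $10^{-4}$ degrees of axis angle on a 120 px tooth — the file-based
  round-trip tolerance is set accordingly ($10^{-3}$ degrees), while
  in-memory box recovery is exact to $10^{-9}$.
* Rectangularity of label corners is validated in pixel space when the
  image size is known; with unknown size only the scale-invariant
  parallelogram property can be checked, since anisotropic normalization
  maps rotated rectangles to parallelograms.

## Problem sizes used in the shipped checks

The test and acceptance runs use 10,000 random line pairs for bisector
properties, 10,000 random box pairs for IoU cross-checking, 200 synthetic
scenes (noise sd 10) for pathway recovery, 50 random 16×16 images for the
bilateral-filter reference comparison, and 100 random images for the
equalization monotonicity property — sizes chosen so the whole suite
exercises every branch in well under a minute per module while keeping the
sampling error of the stochastic checks far below their thresholds.

## Known limitations

The analysis is strictly 2-D: panoramic projection hides bucco-lingual
angulation, bone density and anatomical structures, so derived pathways are
preliminary orientations, not surgical plans. Only single-tooth gaps with
two present neighbours are supported; multi-tooth spans have no defined
tooth pair. The synthetic generator is a geometric fixture, not a
radiograph simulator.
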