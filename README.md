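# implantpath

Planning a dental implant for a single-tooth edentulous gap starts from the
orientation of the two neighbouring teeth: the implant should enter the gap
along a direction that clears both roots and splits the corridor between
them. `implantpath` implements this construction for 2-D dental panoramic
radiographs (DPRs), taking as input the *oriented bounding boxes* (OBBs) a
tooth detector emits for the two adjacent teeth and returning the implant
pathway as a line, an entry point and an angle. The detector itself is a
pluggable boundary — the package consumes its standard normalized label
format, and ships a synthetic scene generator so the entire pipeline is
testable without clinical images or trained weights.

It is aimed at researchers building or evaluating DPR analysis pipelines:
image-enhancement preprocessing, pathway derivation, detection scoring and
angular-deviation comparison against clinician annotations are all covered.

## The construction

Each adjacent tooth is represented by an OBB with center, sides `w ≤ h` and
rotation θ; its **long axis** (the clinical angulation reference) is the line
through the center along the `h` side. Two **auxiliary lines** are extended
along the gap-facing lateral OBB edges, written in implicit form

```
A1·x + B1·y + C1 = 0,    A2·x + B2·y + C2 = 0
```

with canonical coefficients (`A² + B² = 1`). Their angle bisectors solve

```
(A1·x + B1·y + C1) / √(A1² + B1²) = ± (A2·x + B2·y + C2) / √(A2² + B2²)
```

giving two mutually perpendicular candidates; the **internal** bisector —
the one whose direction lies inside the wedge spanned by the two long-axis
directions — is the implant pathway orientation. Parallel teeth (a
legitimate clinical configuration) yield the midline. The entry point is
where the pathway crosses the crest segment joining the two gap-facing,
crown-side box corners.

Around this core the package provides:

* **Enhancement** — bilateral filtering (edge-preserving double-Gaussian
  smoothing), global histogram equalization via the CDF mapping, per-pixel
  HE:BF compositing (default ratio 0.3), and brightness / exposure / noise
  augmentation for dataset doubling.
* **Evaluation** — rotated IoU by convex polygon clipping, greedy one-to-one
  detection matching, precision / recall / accuracy, AP and mAP50, and
  angular-deviation reports against reference pathways.
* **I/O** — normalized OBB (`class x1 y1 … y4`) and HBB (`class cx cy w h`)
  label text dialects, pathway JSON, ground-truth endpoint sidecars,
  PNG/TIFF grayscale images, and an overlay renderer (green pathway, yellow
  and blue auxiliary lines).
* **Synthetic scenes** — two tooth-shaped bright objects with known axis
  angles flanking a darker gap on a noisy low-contrast background, with
  exact labels and analytic ground-truth pathways.

## Worked example

```r
library(implantpath)

# two adjacent teeth as a detector would report them
left  <- oriented_box(cx =  89.5, cy = 127.5, w = 36, h = 120, theta = 5)    # axis 95 deg
right <- oriented_box(cx = 165.5, cy = 127.5, w = 36, h = 120, theta = 175)  # axis 85 deg
pw <- derive_pathway(tooth_pair(left, right))
summary(pw)
#> Implant pathway summary
#>   tooth axis directions : 95.000, 85.000 deg
#>   wedge span            : 10.000 deg
#> <implant pathway>
#>   angle      : 90.000 deg
#>   line       : +1.000000*x +0.000000*y -127.500000 = 0
#>   entry point: (127.50, 69.30)
```

The mirror-symmetric pair (axes 95° and 85°) yields the vertical pathway
`x = 127.5` at 90°, entering at the crest between the two crowns — exactly
the internal bisector of the two auxiliary edge lines.

End to end from pixels, on a synthetic scene:

```r
sc  <- generate_scene(scene_spec(theta = c(98, 84), noise_sd = 10, seed = 42))
fit <- fit_boxes_from_image(sc$image)          # threshold + min-area rectangles
est <- derive_pathway(tooth_pair(fit[[1]], fit[[2]]))
sprintf("truth %.3f vs estimated %.3f deg", sc$truth$angle_deg, est$angle_deg)
#> "truth 91.000 vs estimated 90.967 deg"
```

Comparing a set of predicted pathways against clinician annotations:

```r
angular_deviation_report(deviations = c(3.59, 1.29, 1.01, 0.41, 0.80, 2.12))
#> <angular deviation report> n = 6
#>   per-image (deg): 3.590, 1.290, 1.010, 0.410, 0.800, 2.120
#>   mean 1.537 deg   max 3.590 deg
```

## Command line

A thin wrapper (`inst/exec/implantpath`, or `ipath_main()` in-process)
exposes the pipeline stages:

```sh
implantpath synth    --n 50 --seed 1 --out data/
implantpath enhance  --in data/ --out enh/ --ratio-he 0.3
implantpath pathway  --labels data/ --image-size 256x256 --out paths/
implantpath eval-angle --pred paths/ --truth data/truth.json --out report.json
implantpath overlay  --image data/scene_001.png --labels data/scene_001.txt --out ov.png
```

Every run writes a `run_manifest.json` with the resolved configuration;
numeric JSON output is fixed to 6 decimals so identical configurations give
byte-identical artifacts.

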