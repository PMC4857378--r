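---
title: "Measuring posture on a rotating platform: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring posture on a rotating platform: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotapose)
```

## The measurement problem

Photogrammetric posture evaluation measures spinal curvature and body
alignment from photographs or video frames. A single 2D image, however,
only measures truly in the plane perpendicular to the camera axis: any
structure off that plane is foreshortened (parallax error), and a chord at
angular offset $\varphi$ from the profile plane projects to roughly
$L\,|\cos\varphi|$ of its true length $L$. Filming a subject on a slowly
rotating platform sidesteps the problem statistically: many frames with the
subject *practically in the same position* but at slightly different
angles are selected and the measurement averaged, so single-view bias turns
into a spread that the mean suppresses.

`rotapose` implements the computational side of that workflow:

1. **Calibration** — fiducial marks on a support of known dimensions anchor
   a pixel-to-centimetre map (`fit_calibration()`).
2. **Per-frame metrics** — curvature indices, distances, angles, areas from
   annotated landmarks (`measure_frame()`).
3. **Aggregation** — summary and accumulated (running) statistics across
   the selected frames (`aggregate_metrics()`).
4. **Stabilization** — the accumulated coefficient-of-variation rule that
   says how many frames are enough (`repetitions_needed()`).
5. **Simulation** — a pinhole turntable model to validate the averaging
   strategy on known geometry (`turntable_scene()`).

## Calibration model

The map from pixels $(u, v)$ to centimetres $(x, y)$ is
$w = A p + t$ with a $2\times2$ block $A$ and offset $t$, fitted by least
squares in world space (QR decomposition). The transform family is a design
choice the acquisition itself does not dictate; we default to a **full
affine** map when at least three non-collinear marks are available because
it is the weakest family that tolerates a tilted camera and independent
horizontal/vertical scales, and fall back to a **similarity** transform
(rotation + isotropic scale) with exactly two marks. `family =
"similarity"` forces the 4-parameter fit at any mark count.

Numerical guards: duplicate pixel marks and collinear configurations are
rejected (collinearity = smallest singular value of the centred pixel
matrix below $10^{-8}$ times the largest — a scale-free test); the fitted
block must be invertible. The residual RMS (cm) is reported so an operator
can spot a bad marking session. Pixel coordinates are continuous, 0-based,
origin top-left with `v` downward; world `y` points up and the fitted block
absorbs the flip. Lens distortion is out of scope: consumer camcorder
optics at the working distances involved contribute far less error than
manual landmark annotation, and correcting them would require a
calibration target the protocol does not include.

## Curvature index

For a spinal curve bounded by its upper and lower limit vertebrae, with $x$
the chord ("straight") between them and $f$ the perpendicular distance
("arrow") from the curve apex to that chord,

$$\mathrm{CI} = \frac{f}{x} \times 100 .$$

Being a ratio of lengths, CI is invariant under rigid motion and uniform
scaling — calibration scale cancels exactly, which the test suite verifies
as a property. We take $f$ to the *infinite line* through the limit
vertebrae: for anatomically plausible curves the apex projects inside the
chord, where line and segment distances coincide, and the line distance is
the standard "arrow" of flexicurve-style indices. `clamp_to_segment =
TRUE` switches to the segment distance for degenerate annotations. Angles
are reported as unsigned interior angles in $[0^\circ, 180^\circ]$, areas
by the shoelace formula; no rounding is applied to any metric until
reporting.

## Accumulated statistics and stabilization

Given per-frame values $v_1, \dots, v_n$ of one metric:

* running mean $\bar{X}(k) = \tfrac1k \sum_{i\le k} v_i$;
* **accumulated SD** $\sigma_{acc}(k)$ = the *sample* SD (denominator
  $k-1$) of the running means $\bar{X}(1), \dots, \bar{X}(k)$, defined as 0
  at $k=1$ — a measure of how much the running estimate is still drifting;
* accumulated CV $= 100\,\sigma_{acc}(k)/\bar{X}(k)$.

The accumulated-SD definition deserves emphasis: published accumulated-CV
tables in this area rarely spell it out, and several plausible candidates
exist (SD of the raw first $k$ values, SD of means, standard error). Only
the SD-of-running-means reading reproduces the published checkpoint cells
of the benchmark series embedded in this package (e.g. width $k=4$: 0.025,
$k=5$: 0.050), so that is the definition implemented, stated here
prominently rather than buried in code. Likewise the sample ($n-1$)
denominator is forced by the benchmark's bottom row (width SD 0.22
matches 0.216, not the $n$ version 0.212).

### Rounding policy

Printed tables compute their CV from *printed* (already rounded) operands.
The default `"printed-table"` policy therefore rounds mean and SD half-up
to two decimals before forming $100\,\mathrm{SD}/\mathrm{mean}$, and rounds
the CV to two decimals; `"exact"` computes the full-precision ratio. On the
benchmark data the two policies agree within 0.05 percentage points.
Half-up rounding (not banker's) is used because round-half-even breaks
several benchmark cells. The benchmark's own accumulated-CV column is not
internally consistent cell-by-cell (some entries cannot be derived from
their printed operands under any rounding we tried); the per-frame raw
columns are treated as authoritative and the derived statistics are
computed, not transcribed.

### Repetitions needed

The default **terminal-plateau** rule returns the smallest $k \ge 2$ such
that the accumulated CV, rounded to two decimals, is identical from $k$
through the last frame — the reading a practitioner takes off the printed
accumulated-CV table. On the benchmark height series this yields 26, the
published stabilization count:

```{r}
fx <- rectangle_validation()
acc <- accumulated_stats(fx$heights)
repetitions_needed(acc)
```

The published *width* stabilization figure (18) is **not** reproduced: the
width CV series under this policy plateaus from $k=11$, and no rule we
examined (plateau variants, windowed thresholds, either rounding policy)
lands on 18. The discrepancy is documented rather than patched; the
alternative `delta-threshold(epsilon, window)` rule is provided for
sensitivity analyses. Similarly, the benchmark narrative quotes
measurement errors of "about 1 % (height) and 0.3 % (width)" whose
computational basis we could not recover — the literal mean-vs-truth
percent errors of the series are 0.08 % and 0.05 % — so `percent_error()`
implements only the literal definition.

## The turntable simulator

The simulator is the package's validation instrument: a rigid set of 3D
landmarks in a body-fixed frame (origin on the rotation axis, Y up, Z
toward the camera at angle 0) rotates at constant platform speed and is
imaged by a fixed pinhole camera.

Parameters and defaults, chosen to mirror a realistic rig:

| parameter | default | meaning |
|---|---|---|
| `platform_rpm` | 0.7 | platform speed (rev/min), slow enough for comfortable standing |
| `frame_rate` | 30 | camera acquisition rate (Hz) |
| `camera_distance` | 300 | axis-to-pinhole distance (cm) |
| `focal_px` | 1500 | pinhole focal length (px); 5 px/cm at 300 cm |
| `image_size` | 2048 × 1536 | 3-megapixel consumer CCD class sensor |
| `noise_sd_px` | 0 | isotropic Gaussian annotation jitter (px) |
| `occlusion_depth` | 0 | cm behind the axis plane before a landmark is dropped |

At 0.7 rpm and 30 Hz one revolution yields
$\lfloor 30 \cdot 60 / 0.7 \rfloor = 2571$ frames, about 0.14° apart —
a ±2° selection window around the target angle comfortably supplies the 26
frames the measurement protocol averages. (Hardware descriptions sometimes
state the same speed as "one turn per 1.5 min", i.e. 0.67 rpm; the two are
inconsistent and we standardize on 0.7 rpm.)

Design choices: principal point at the image centre and square pixels (the
minimal model that produces parallax and foreshortening); visibility by a
half-space test — a landmark is dropped once its rotated position lies more
than `occlusion_depth` cm behind the vertical plane through the rotation
axis, a crude stand-in for body self-occlusion (set it near the body
half-depth so both ends of a sagittal chord survive at profile); annotation
error as seeded isotropic Gaussian pixel noise, because manual clicking
error, not sensor noise, dominates this kind of data. Angle convention: 0°
= facing the camera, 90° = right profile, increasing counter-clockwise
seen from above. Frame selection orders candidates by circular angular
distance to the target, breaking ties toward the earlier frame, and
truncates to `max_frames` (default 26).

What the simulator deliberately does **not** model: postural sway and
posture drift between frames (a real subject moves; the benchmark rigid
rectangle does not), soft-tissue deformation and marker slippage, lens
distortion, lighting and detection failure. Passing simulator-based tests
therefore demonstrates that the geometry and statistics pipeline is
correct, and that frame averaging suppresses annotation noise and parallax
under rigid motion — not that human measurements will reach rectangle-level
precision. The benchmark data themselves show the gap: a rigid object
yields CVs below 2.5 %, while curvature indices of a living subject show
far larger spreads.

`generate_rectangle_fixture()` reproduces the criterion-validity setup
end-to-end: a 25 × 15 cm rectangle facing the camera, 30 frames, seeded
corner jitter, plus four noise-free calibration marks in the same plane.
With zero noise the fitted calibration recovers the dimensions exactly
(the rectangle lies in the plane through the axis where the pinhole map is
an exact similarity); with noise, the 30-frame mean falls within three
standard errors of truth in the seeded tests.

## Numerical conventions and degenerate inputs

* Half-up decimal rounding via `round_half_up()`, with a $10^{-9}$ guard
  absorbing binary representation error on printed ties.
* Insufficient data (fewer than 2 marks, values, or frames) raises errors;
  a metric missing from some frames is skipped *for that metric* with a
  reported skip count, and a metric observed fewer than twice is flagged
  insufficient rather than failing the whole report.
* A single measurement has accumulated SD and CV defined as 0.
* Landmark files may use decimal commas (annotation tools in pt-BR
  locales); all writers emit dots, and write with 17 significant digits so
  read–write round trips are lossless.

## Problem sizes in the test suite

The suite validates against the embedded 30-frame benchmark (instant),
property tests with 10–30 random replicates per invariant, Monte-Carlo
area oracles at 2–4 × 10⁴ samples, and simulator runs of one revolution at
0.7–30 rpm; the complete suite runs in well under a minute on a laptop
core, which we consider the right budget for a methods package of this
size.

## Limitations

Landmark annotation itself (clicking on frames) and video decoding are out
of scope — the package consumes already-extracted coordinates. Only planar
(single-camera) calibration is supported; measurements of structures far
from the calibrated plane remain subject to depth scaling that averaging
over a narrow angular window reduces but does not remove. The
stabilization rule is a pragmatic reading of accumulated-CV tables, not an
inferential procedure; for formal precision statements, use the summary
SD and standard errors directly.
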