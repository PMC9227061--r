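---
title: "Methods: simulated multiwell imaging station"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated multiwell imaging station}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and design

`platescope` reimplements, in software, the full control and analysis
stack of an automated multiwell bright-field imaging station built on a
Cartesian 3D-printer chassis: a camera and a micropipette tip move over
two multiwell plates, a peristaltic pump fills wells, per-well RGBW LEDs
illuminate samples, and a single-board computer autofocuses, captures and
analyzes micrographs and videos of motile microalgae. The hardware itself
is replaced by a *virtual device* that honors the same contract the
automation engine would use against a physical transport (move, pump,
light, capture), so every procedure — autofocus, cell counting, motility
quantification, scripted runs — executes and is tested entirely offline.

The package deliberately separates four layers:

1. **geometry** (`plate_layout`, `well_to_stage`): pure coordinate
   arithmetic;
2. **simulation** (`scene`, `render_model`, `virtual_device`): the ground
   truth world and its imaging;
3. **analysis** (`autofocus`, `analyze_image`, `track_cell`,
   `flow_field`): algorithms that only ever see images, never the truth;
4. **orchestration** (`validate_script`, `execute_script`): the JSON
   automation layer driving any device implementing the contract.

Analysis code is scored against the simulator's exported ground truth;
nothing in layer 3 peeks at layer 2's state.

# Plate geometry

Plates sit in portrait orientation (short edge along stage X), two per
holder. Well addresses are 0-based, `x` being a single column index that
continues across plates (0–2 on plate 1 and 3–5 on plate 2 for 12-well
plates) and `y` the row index; (0,0) is the top-left well of plate 1.
This is the convention every automation script uses.

Physical constants default to the ANSI/SLAS microplate footprint
(127.76 × 85.48 mm) with pitches 26.01 / 19.3 / 9.0 mm for 12- / 24- /
96-well plates; the A1 offset defaults to centering the well grid on the
footprint. All are configurable per `plate_format`. The gap between the
two plate footprints (10 mm) is a holder design choice, also
configurable. Stage coordinates are millimetres in the machine frame,
origin at home; every generated coordinate is validated against the
220 × 220 mm bed.

A custom-position JSON file (for non-standard holders) overrides the
pitch arithmetic entirely and must cover every addressable well; the
global manual offset still applies on top of it.

# The virtual device

**Stage.** Moves are exact; positional noise enters only at homing, where
each axis acquires a Gaussian origin error with per-axis sd 37 / 14 / 9 µm
(X/Y/Z) — the measured homing repeatability of the physical chassis class
this emulates. This matches how such machines behave: lead screws are
repeatable, end-stop switches are not. Axis speeds default to 50 mm/s
(XY) and 5 mm/s (Z); they affect only reported durations, never
positions. The Z homing error is the reason an autofocus exists at all,
and the simulation reproduces that: captures render at the *true* camera
height, so the autofocus transparently compensates the homing offset.

**Pump.** A requested volume V is dispensed as V·(1 + ε) with
ε ~ N(0, 0.035) — the 3.5% relative error of the 3D-printed peristaltic
pump at 1 mL. Purging pushes one purge volume (1 mL default) through the
line first.

**LEDs.** Four channels (r, g, b, w), 0–255 each. The background gray
level of a rendered frame follows the channel mix with a small ambient
floor so unlit frames remain renderable.

**Camera and scene.** The scene is a set of cells (position µm, radius,
velocity, color) in a liquid column. Cells are drawn as dark disks
(bright-field convention) with a logistic edge profile whose softness
grows linearly with the camera's defocus distance
(`blur_scale` px/mm, default 8) plus a depth penalty
(`depth_penalty` px/mm of depth below the liquid surface, default 3).
The depth penalty encodes the optical design choice that the instrument
images the *top* liquid layer: it guarantees the global sharpness maximum
over camera heights is the height focusing the shallowest cells, which is
what the real autofocus exploits. Out-of-focus cells also lose contrast
(`1/(1 + 0.6·σ_extra)`), as real defocused objects do. iid Gaussian sensor
noise (default sd 2 gray levels) is added to all channels.

**Photoresponse.** While any trigger channel (blue or white by default)
is lit, cell speed decays as `exp(-t/τ)` and positions follow the closed
form `x(t) = x₀ + v·τ·(1 − e^{−t/τ})`; red light leaves motion untouched.
τ is not stated by the motility-arrest observations this models (only
that cells stop within 300 s of white light); the default τ = 60 s makes
the 300 s speed factor e⁻⁵ ≈ 0.7%, i.e. arrest is complete on that
timescale. Illumination is treated as constant since the LEDs were last
changed — the device clock tracks that — which is exact for the scripted
capture patterns used here.

**Determinism.** Each device instance owns a private RNG stream (seeded
at construction, saved/restored around every draw), so identical seeds
give bit-identical runs regardless of the caller's RNG state.

# Autofocus

The focus measure is the population variance of the 3×3 discrete
Laplacian of the grayscale image — the standard "variance of Laplacian"
score: zero on constant images, invariant to brightness offsets, and
strictly decreasing with Gaussian blur. The kernel and statistic are
package choices; the operator itself is the classic five-point Laplacian.

The search is the instrument's two-phase ladder, parameterized by
`focus_params()`:

* phase 1: start 0.5 mm above the theoretical focus (computed from the
  known dispensed volume as column height = V / well area, focus at the
  column top), descend 10 × 0.1 mm, scoring each level — 1 mm of travel;
* phase 2: re-center 0.05 mm above the coarse argmax, descend 10 ×
  0.01 mm;
* result: global argmax over all 20 evaluations.

Numerical choices: ties break toward the *highest* camera position
(preferring the upper liquid layer); phase 2 re-captures rather than
reusing coincident phase-1 scores (scores differ under sensor noise);
all heights clamp to the stage's z travel. For any unimodal sharpness
profile whose peak lies at least one coarse step inside the swept range,
the fine grid covers the coarse argmax ± 0.05 mm, so the result is within
one fine step (0.01 mm) of the true peak; the suite verifies this against
exhaustive fine-grid search on 100 seeded stacks.

# Cell analysis

**Calibration.** µm/px comes from a graduated reference slide: the image
is projected perpendicular to the graduations (the projection angle is
searched over ±10° for maximal profile contrast, absorbing slide
rotation), graduations are detected as profile dips exceeding half the
profile range (with an absolute 20-gray-level contrast floor), and the
median spacing of adjacent dip centroids converts the known division to
µm/px. Rescaling to a new resolution multiplies by the vertical-pixel
ratio — the same optics spread over fewer rows.

**Segmentation.** Grayscale (Rec.601 luma) → inverted binary threshold
(dark cells become foreground; Otsu's method chooses the threshold when
none is given) → a morphological pass to connect nearby pixels and close
cells. The pass is *closing* (dilate-then-erode) by default: closing
realizes the stated intent — bridging small gaps and filling cells —
without the systematic size inflation a net dilation would add to every
measured bounding box (2 px per iteration). A pure-dilation mode
(`morph = "dilate"`) is available.

**Measurement.** Connected components below `min_area` px² are discarded
as debris. Survivors are measured by axis-aligned bounding box and
centroid, converted to µm. When the grayscale image and threshold are
available, box edges are localized to sub-pixel precision by linearly
interpolating the gray profile across the outermost foreground pixels at
the threshold value; this removes the ~1 px quantization bias of raw
pixel counts and is what makes the "diameters within 1 px of truth"
check pass with margin. Mean RGB is averaged under the component. The
CSV export is one row per cell (id, centroid, width/height µm, area µm²,
RGB), deterministic in id.

# Motility

No R package provides optical flow, so the estimators are implemented
here.

**Sparse (single-cell) flow** is pyramidal iterative Lucas–Kanade:
3-level image pyramid ([1,2,1]/4 smoothing, 2× decimation), windowed
structure tensor with bilinear sub-pixel sampling, Newton iterations to
0.005 px. A point is untrackable when its window leaves the frame, its
structure tensor is degenerate, or the window's mean squared gradient is
below 9 (gray/px)² — the texture gate that stops pure sensor noise from
"tracking". Tracks add a forward–backward consistency check (1 px): the
track terminates, flagged, when the round trip misses. The default
window half-size (7 px) suits cells up to ~14 px across; for larger
organisms the window must at least reach the cell boundary from the
seed point (the interior of a large uniform cell carries no gradient),
so `win` is a user parameter.

**Dense (whole-field) flow** evaluates the same LK estimator on a
regular stride grid (default 16 px) between consecutive frames, with the
same texture gate plus the forward–backward check (dropping occlusions
and cells wrapping at the frame edge). The design decision to use
grid-sampled LK rather than a polynomial-expansion dense method: for the
translational cell motion measured here the two give the same vectors,
and windowed LK is exact, compact and fast in pure R. Speeds convert as
px/frame × µm/px × fps; doubling the calibration doubles reported speeds,
doubling the frame rate for the same physical motion leaves them
unchanged (both verified in the suite). Reported per track are the mean
per-step speed and the net-displacement speed (the two common but
different "swimming speed" conventions).

# Automation

Scripts are JSON objects (`name`, `pos`, optional `sampling`, `volume`,
`capture`, `light`, `delay`, `trash`). Validation returns errors naming
the missing/malformed key, warns on unknown keys, and broadcasts
singleton `volume`/`light`/`delay` to all wells (any other length must
match `pos`). `delay[i]` is the wait *after* completing well i, so the
final entry is conventionally 0; `delay` may be omitted entirely
(default 0). Only the active well is lit, and illumination is applied at
that well's turn.

Execution per well: set light → move tip over the well (tip = camera
position + fixed tool offset, default +30 mm in X) → purge/dispense when
sampling → move camera over the well → settle delay (default 1 s,
configurable; liquid needs to still after a Y move) → autofocus and
capture when capturing (image `<name>X<x>Y<y>.png`, raw 0-based indices)
→ scripted delay. Afterwards: all LEDs off, park at the safe position
(camera to the far corner at full height, bed advanced), report elapsed
time, image names and dispensed volumes.

The runtime estimator mirrors the executor's travel plan with per-action
constants (`timing_model`). `timing_model_for_device` derives the
constants from a device instance, measuring one autofocus on a clone
started from the working focus height (so the one-off approach move is
not charged per well) and including the dominant parking cost — raising
the camera 228 mm at 5 mm/s. With a matched model, simulated/estimated
ratios sit within a few percent for all bundled scripts; the suite holds
the ratio to ±10%.

# What the synthetic data does and does not show

The generators emulate: non-overlapping disk-like cells of 5–12 µm
(configurable up to *E. gracilis* scale), a single settled layer or a
distributed column, uniform random headings with constant speeds,
light-triggered exponential arrest, defocus blur, sensor noise, and
graduated slides with optional rotation. Defaults sit at the instrument's
nominal working point: 0.5 µm/px, 30 fps, 3.5% pump error, 37/14/9 µm
homing noise.

They do not emulate: cell shape beyond disks (no flagella, no
elongation), intensity texture inside cells, z-swimming (motion along z
appears in reality as blur change, not displacement — speeds here are
2-D projections), occlusion/crossing trajectories, aggregation dynamics
(arrest is per-cell, aggregates don't form), agitation after liquid
handling (reduced to a fixed settle delay), and photorealistic optics
(no PSF/diffraction). Passing tests therefore demonstrate the
correctness of the geometry, control flow, search and measurement
algorithms under the stated noise models — not robustness to real
micrograph artifacts such as debris, uneven illumination or biofilm.

Problem sizes in the test suite are chosen for sub-second renders:
96–256 px frames, 3–25 cells, 6–60 frame videos, 100 autofocus stacks;
the full suite and the acceptance script run in a few minutes on one
CPU.

# Known limitations and open choices

* Multi-well LED state: only the active well's color is modeled (the
  96-well holder, which uses a global white panel, is treated as a
  single global white channel).
* Dense-flow summaries weight cells by the number of grid points they
  cover; large cells count more than small ones.
* No data association: one seed, one track; identity is lost on
  occlusion (the forward–backward gate terminates instead of guessing).
* The estimator assumes the executor's travel plan; a custom execution
  order would need a matching plan.
* `delay` semantics, the tool offset sign, the plate gap and all timing
  constants are configurable package choices where the instrument design
  leaves them open.
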