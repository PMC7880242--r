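---
title: "Methods: multimodal multiphoton analysis with mmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal multiphoton analysis with mmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmd)
```

`mmd` analyses co-registered multiphoton time-lapse data: a cell channel
(TPF), a collagen channel (SHG) and a single-depth FLIM lifetime map that
share one lateral coordinate frame. This vignette documents the methods,
their assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## Data model and conventions

All volumetric data is held as 4D arrays indexed `[t, z, y, x]`, one array
per channel, with identical shape across channels — the *co-registration
contract*. A pixel coordinate therefore refers to the same physical
location in every modality, which is what makes cell-centered SHG tiles
and shared ROIs meaningful.

Conventions, fixed once and used everywhere:

* Indices are 1-based and ROI bounds inclusive (the R convention).
* Physical positions are `(index - 1) * spacing` µm; **all distances are
  computed in µm**, never in index space. With a 5 µm axial step and
  ~1 µm lateral pixels, index-space Euclidean distance would weight the
  axes arbitrarily.
* Angles are degrees, counter-clockwise from +x, with the image-row axis
  negated ("y up"). Fiber orientations are axial (mod 180°); migration
  directions are full-circle (mod 360°).
* Metadata defaults: 5 µm axial step, 5 min frame interval — typical
  volumetric-mosaic acquisition values. The lateral pixel size depends on
  the scan optics and must always be supplied.

TIFF stacks are stored as 16-bit samples with a per-file power-of-two
intensity scale recorded in a JSON sidecar. Power-of-two scaling is exact
in binary floating point, and the synthetic generators quantise their
output onto the 16-bit grid, so writing and re-reading any fixture is
bit-exact. (16 bits also matches the depth of real multiphoton digitizers.)

## 3D segmentation and tracking

Segmentation is deliberately simple: voxels strictly above a threshold are
grouped into 26-connected components; components smaller than `min_voxels`
are dropped; each survivor's unweighted mean voxel position is its
centroid. Parameters:

| parameter | default | rationale |
|---|---|---|
| `threshold` | Otsu per volume | robust contrast split for bright cells on dim background; numeric override for reproducible batch settings |
| `min_voxels` | 27 (≈ 3³) | suppresses shot-noise specks at ~1 µm lateral sampling |
| `connectivity` | 26 | full 3D neighbourhood; 6 and 18 available |

Linking is strict adjacent-frame nearest neighbour in physical µm. Two
policies are exposed because the classic rule has a known failure mode in
dense fields (two cells claiming the same target):

* `independent-nearest` — each track independently takes its closest
  detection; the literal minimum-distance rule, and the definition our
  brute-force test oracle implements.
* `one-to-one-greedy` (default) — all candidate pairs sorted by distance,
  each detection claimed at most once.

Distance ties are broken by the lowest candidate label so reruns are
deterministic. The gate (`gate_um`) defaults to none; when cells can
disappear mid-movie a gate of roughly 3× the median per-frame displacement
is a sensible starting point. Tracks that lose their cell terminate; there
is no gap closing, splitting, merging, or probabilistic (Kalman/LAP)
assignment — strict nearest neighbour is the method under study.

Motility statistics follow directly from centroids: instantaneous velocity
(step length / frame interval), net displacement (first-to-last distance,
*not* path length), migration direction (four-quadrant arctangent of the
net lateral displacement, flipped-y convention), per-frame population
counts with fractional change relative to the first frame, and polar
direction histograms (undefined-direction tracks are excluded and
counted).

## Collagen alignment by Fourier eccentricity

For each tracked detection, a `tile_size`² window (default 200², clipped
at image borders, never padded) is cut from the SHG slice nearest the
cell's z. The alignment score is computed as:

1. subtract the tile mean (mandatory by default — the raw spectrum is
   DC-dominated and the binary mask would collapse to a point);
2. apply a Hann window (default on; suppresses edge-discontinuity streaks
   in the spectrum);
3. 2D FFT, centred magnitude;
4. binary mask at `threshold_frac` × max magnitude;
5. moment-based ellipse fit of the mask (second-order central moments
   with the standard 1/12 per-pixel correction);
6. report eccentricity e = c/a and the FT major-axis angle; the inferred
   fiber orientation is that angle + 90°, since spectral energy
   concentrates perpendicular to image stripes.

`threshold_frac` is the one genuinely sensitive knob. The method
description it implements leaves the value open, so it was chosen here on
synthetic fiber fields of known concentration: at 0.5 the mask retains
only the spectral peak (tens of pixels), making the eccentricity noisy and
saturated near 1 for all but isotropic fields; at 0.2 the mask retains the
central lobe (hundreds of pixels) and the mean eccentricity is stable and
strictly increasing across von Mises κ ∈ {0, 1, 4, 16}. The default is
therefore **0.2**; the parameter remains user-settable and the sensitivity
should be kept in mind when comparing absolute eccentricities between
studies.

Analysis is 2D per slice by design: the axial resolution of multiphoton
mosaics (µm-scale steps) is far coarser than lateral resolution, so 3D
fiber tracing is out of scope, as is re-implementing curvelet fiber
extraction — tiles are exported for such external tools instead. Edge
tiles with less than half their nominal area inside the image are flagged
(`low_valid_fraction`), as are degenerate (constant) tiles and masks under
5 pixels; flagged rows never abort a batch.

## Area-based FLIM statistics

Lifetime estimates are meaningless at near-zero photon counts, so all
statistics exclude pixels below an intensity threshold (default: the 5th
percentile of nonzero intensity; zero-intensity pixels are always
excluded). A region's statistic is the **unweighted mean of its area
means**: it answers "what is the typical local lifetime here" without
letting a large area dominate. The pixel-pooled mean is emitted alongside;
the two coincide exactly when areas hold equal unmasked pixel counts.
Areas can be supplied explicitly or sampled as non-overlapping random
squares inside a region mask (seeded, bounded rejection sampling). FLIM
analysis is strictly 2D — the data is acquired at a single depth — and
decay fitting is upstream of this package: lifetime maps arrive
precomputed, in nanoseconds.

## The synthetic scene generator

The generator produces the three study-condition fixtures every analysis
is validated against, each with machine-readable ground truth:

* **Cell scenes** — soft-edged spheres (logistic edge, width 0.5 µm) of
  radius 7 µm (macrophage scale) on a Gaussian background (level 0.05,
  σ 0.02, cell amplitude 0.9), in a 6-frame, 5-slice, 200 × 200 px volume
  at 1 µm/px, 5 µm/slice, 5 min/frame. Motion models: common drift
  (default 2 µm/min toward 30°), independent fixed-step random walks with
  reflecting margins, or attraction toward a wound point; a birth schedule
  adds cells per frame for influx experiments. Initial packing enforces
  ≥ 25 µm separation, so default drift scenes satisfy the
  "per-frame displacement < half the minimum cell spacing" regime in which
  nearest-neighbour linking is provably recoverable. Cell depths are
  snapped to slice positions and held fixed: with a 5 µm axial step a cell
  centred between slices can drop below the minimum component size, which
  would conflate rendering artefacts with tracking errors.
* **Fiber fields** — anti-aliased line segments (default 60 per 200² px,
  length 120 px, Gaussian half-width 2 px) with axial orientations drawn
  from a von Mises distribution on the doubled circle; κ = 0 is isotropic,
  κ = 16 strongly aligned.
* **Lifetime maps** — per-region constant lifetime plus Gaussian noise
  (defaults: 1.2 ns vs 0.9 ns halves, σ = 0.05 ns), bright intensity
  inside regions with an optional dark-pixel fraction.

What the generator does *not* emulate: realistic point-spread functions,
photobleaching, breathing-motion jitter, cell shape change, fiber
curvature, spatially varying lifetime gradients. Passing tests therefore
demonstrate that the *algorithms* are implemented correctly and recover
known ground truth under idealised imaging; they do not certify
performance on real tissue, where segmentation thresholds and gates need
per-dataset tuning.

## Pipeline, determinism and problem sizes

`run_pipeline()` validates its config up front (unknown keys anywhere are
rejected), executes stages in dependency order, and writes every table
with a header carrying the package version, an md5 hash of the canonical
config (output directory excluded) and the seed. All randomness flows from
that one seed, so a rerun is byte-identical — verified by hashing the
outputs of two runs in the test suite. Stage failures abort with a
stage-named error and preserve partial outputs and the run log.

Test and acceptance workloads are sized for interactive use: tracking
oracle comparisons use up to 20 cells × 6 frames over 50 random scenes;
drift recovery uses 20 rendered scenes; eccentricity calibration uses 20
fiber fields per κ level; FLIM ordering uses 100 noisy maps. The full
suite runs in well under a minute on one core.

## Known limitations

* Nearest-neighbour linking has no motion model; fast cells in dense
  fields will swap identities. The one-to-one policy mitigates but does
  not eliminate this.
* Eccentricity values depend on `threshold_frac` and windowing; compare
  absolute values only within one parameter setting.
* Mosaic assembly is pure placement arithmetic (last-written-wins in
  overlaps); there is no registration, drift correction or blending.
* The ellipse fit uses all above-threshold spectrum pixels, not the
  largest connected blob; for multi-modal orientation distributions the
  single-ellipse summary is a deliberate simplification.
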