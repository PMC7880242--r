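# mmd — multimodal multiphoton analysis of 3D cellular dynamics

Intravital multiphoton microscopy can record, in one co-registered
experiment, where immune cells are and how they move (two-photon
fluorescence, TPF), how the surrounding collagen is organised (second
harmonic generation, SHG), and what metabolic state the tissue is in (NADH
fluorescence lifetime imaging, FLIM). `mmd` is a scriptable R toolkit for
analysing such datasets — for example time-lapse volumetric mosaics of
wounded skin in GFP-macrophage reporter mice — and for generating
ground-truthed synthetic versions of them so every step can be validated in
a closed loop.

## What it computes

**3D cell tracking.** Cells are segmented per time point by intensity
thresholding (Otsu by default) and 26-connected 3D component labelling;
each component gets a numerical tag and an unweighted 3D centroid, reported
in voxel indices and in physical µm. Tracks link each cell at time *t* to
the detection at *t* + 1 minimising the 3D Euclidean distance in µm,

&nbsp;&nbsp;&nbsp;&nbsp;d(i, j) = ‖**x**ᵢ(t) − **x**ⱼ(t+1)‖₂,

either independently per cell (the classic nearest-neighbour rule) or
one-to-one greedily (each detection claimed once; the default). From the
tracks come instantaneous velocity v(t) = ‖Δ**x**‖/Δt, net displacement
‖**x**(T) − **x**(1)‖, migration direction atan2(−Δy, Δx) (image rows grow
downward, so y is flipped to the mathematical convention), population
counts and polar direction histograms.

**Collagen alignment.** For every tracked cell a 200 × 200-pixel SHG tile
is cut at the slice nearest the cell's own depth. The tile's 2D Fourier
magnitude is thresholded at a fraction of its maximum and an ellipse is
fitted to the binary mask by second-order moments. The ellipse
eccentricity e = c/a ∈ [0, 1] scores local fiber alignment — near 0 for
isotropically oriented fibers, near 1 for strongly aligned ones — and the
fiber orientation is the FT major axis rotated 90°. Tiles can also be
exported as 16-bit grayscale TIFFs (plus a manifest) for external
curvelet-based fiber extraction tools.

**Area-based FLIM statistics.** On a single-depth NADH intensity/lifetime
image pair, mean lifetimes are computed over rectangular areas
(intensity-masked so photon-starved pixels never contribute), and a region
is summarised as the *unweighted mean of its area means* — e.g. five small
areas sampled at random near a wound edge versus five far from it.

A pipeline runner executes segment → track → collagen → FLIM from one YAML
config and joins everything into a single multimodal table keyed by
(track_id, t), suitable for cross-modality correlation.

## Worked example

Simulate a co-registered scene — 8 GFP-like cells drifting at 2 µm/min
toward 30°, an SHG fiber field concentrated around 40° (von Mises κ = 8),
and a two-region lifetime map (1.2 ns vs 0.9 ns, σ = 0.05 ns) — then run
the full pipeline on it:

```r
library(mmd)

cfg <- list(
  seed = 42, out_dir = "run",
  simulate = list(
    cells  = list(n_cells = 8, n_time = 6),
    fibers = list(kappa = 8, mean_angle_deg = 40),
    flim   = list(noise_sd = 0.05)),
  segmentation = list(), tracking = list(),
  collagen = list(), flim = list(n_areas = 5, area_size = 10))

res <- run_pipeline(cfg)
head(res$motility, 3)
#>   track_id n_points mean_velocity_um_min max_velocity_um_min
#> 1        1        6             2.004886            2.021773
#> 2        2        6             2.000971            2.009645
#> 3        3        6             1.999535            2.013412
#>   total_displacement_um direction_deg direction_defined
#> 1              50.12020      29.95736              TRUE
#> 2              50.02335      29.91168              TRUE
#> 3              49.98830      30.01060              TRUE
```

The recovered speeds (≈ 2 µm/min), directions (≈ 30°) and net displacement
(≈ 50 µm over five 5-min steps) match the generator's ground truth. The
FLIM region summary recovers the two-region contrast:

```r
res$flim$regions
#>     region mean_of_means_ns pooled_mean_ns n_areas_used masked_fraction
#> 1 Region 1        1.1990826      1.1990826            5               0
#> 2 Region 2        0.8984615      0.8984615            5               0
```

and, because cell speed and fiber structure are generated independently,
their correlation across the multimodal table is weak:

```r
unlist(correlate(res$table, "velocity_um_min", "eccentricity"))
#>    pearson   spearman          n
#> -0.2317592 -0.2173754 32.0000000
```

All CSV outputs in `run/` are stamped with the package version, a config
hash and the seed; rerunning with the same config and seed reproduces them
byte for byte.

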