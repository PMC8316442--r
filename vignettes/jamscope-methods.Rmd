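---
title: "Methods: quantifying monolayer dynamics and the jamming transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying monolayer dynamics and the jamming transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jamscope)
```

This vignette documents the models, estimators and numerical choices
behind `jamscope`, in the spirit of a methods section: what is computed,
under which assumptions, which knobs matter, and what the synthetic tests
do and do not establish about real data.

## The measurement problem

A confluent epithelium can behave as an active fluid (cells exchange
neighbours and migrate collectively) or as a solid (cells are caged by
their neighbours). The transition between the two — jamming — is gradual
in time and is diagnosed from two independent signatures:

* **dynamics** — how far tracked material points move over a lag
  (mean-squared displacement, MSD), what fraction stay within a cage-sized
  cutoff (self-overlap parameter Q), and how fast the tissue flows at an
  instant (V~RMS~);
* **structure** — how elongated cells are. Vertex-model theory predicts a
  rigidity transition at a critical cell shape index
  `p0 ≈ 3.81`; `jamscope` uses the threshold value 3.813 with the tie
  going to "unjammed", both exposed as parameters.

Both signatures are computed by `jamscope` with the study-standard
acquisition geometry as defaults: frames every 5 min for 200 min,
calibration 0.75488 μm/px, two-pass PIV at 64→32 px with 50 % overlap.

## Velocimetry

`multipass_piv()` estimates displacement per frame pair by mean-subtracted
circular FFT cross-correlation in square interrogation windows, refined to
subpixel precision by a 3-point Gaussian fit per axis (falling back to a
parabolic fit when a log is undefined). The first pass (64 px) feeds the
second (32 px) as a bilinearly interpolated window-offset predictor, so
the second pass only resolves the residual. Vectors are validated with the
normalized median test (8-neighbourhood, noise floor `eps = 0.1` px,
threshold 2.0 — the literature-standard settings; outliers are replaced by
the neighbourhood median and flagged invalid). A field in which fewer than
80 % of vectors survive is marked low quality and the pipeline warns; the
pipeline's exit status (3) records it.

Two numerical choices deserve emphasis:

* **High-pass prefiltering** (`highpass_sigma = 2` px, configurable).
  Monolayer images carry intensity structure at the scale of whole cells
  — comparable to the interrogation window. Because the window crop is
  static while the scene moves, that envelope correlates at zero lag and
  drags fractional displacements toward integers (we measured a 0.5
  px/frame drift reported as ~0.29 px without the filter, and within
  0.035 px with it). Subtracting a Gaussian-blurred copy of each frame
  before correlation is the standard PIV remedy and is applied by
  default.
* **Coordinates.** x = column, y = row, origin at the top-left pixel
  centre; displacements are the motion of the second frame's content
  relative to the first; velocities are calibrated with
  `pixel_size / frame_interval`.

What windowed correlation measures is the *window-coherent* component of
motion. Motion that is incoherent below the window scale — neighbouring
cells moving in unrelated directions — partially cancels inside the
window. `ground_truth_fields()` constructs the field an ideal windowed
velocimeter would return from simulator ground truth; against it the PIV
chain is accurate to tens of percent on incoherent fixtures and to ~1 %
on coherent (uniform-flow) fixtures. On real monolayers, whose velocity
fields are correlated over many cells, PIV-derived dynamics are the
established readout; on the synthetic model below, which has no heading
coupling, PIV systematically reports less motion than individual cells
perform. The test suite therefore checks *exact* recovery on coherent
fixtures and *tracking of the coherent component* on incoherent ones.

## Trajectories and dynamics statistics

`integrate_trajectories()` seeds tracers on a regular grid (default: one
tracer per velocity grid spacing) and advances them by explicit Euler
steps through the bilinearly interpolated field sequence. Tracers that
leave the gridded region freeze and are excluded from statistics from
that moment (fields of view are bounded; wrap-around would be wrong).
Euler integration is first-order: on a rotation field the radius drifts
outward by `(ωΔt)²/2` per step, and the step-halving test pins exactly
that behaviour.

`compute_msd()` and `compute_overlap()` average over tracks and, by
default, over sliding time origins (better statistics on 40-frame
movies); a strict `origin_policy = "first"` mode uses only `t = 0`
origins. The overlap indicator `w^i` is 1 when the track moved less than
`d_c` over the lag — the standard self-overlap reading, the only one
consistent with `Q ∈ [0, 1]`. `d_c` defaults to one velocity-grid spacing
in μm (12.08 μm at the default calibration): displacements below one
velocity sample are "no rearrangement". `compute_vrms()` is the root mean
square of valid vector magnitudes per field, and equals the naive
per-vector accumulation identically.

## Morphometry

`shape_metrics()` reports, per label: area (pixel count × pixel area),
perimeter, shape index `q = perimeter/sqrt(area)`, aspect ratio (from the
eigenvalues of the second-moment matrix, with the 1/12 px² finite-pixel
correction), centroid and a border flag. Border-touching cells are
excluded by default (truncation biases q upward); labels under 9 px are
dropped with a warning.

The perimeter estimator matters more than anything else here, because q
is compared with a threshold only ~2 % away from the hexagonal ground
state. Naive boundary-pixel counting inflates perimeters by up to ~27 %
depending on orientation. The classical 4-direction Crofton estimator
(exported as `crofton_perimeter()`) is excellent on smooth shapes (disk:
within 0.1 % at r = 150 px) but orientation-biased by up to ~5 % on
straight axis-aligned edges. `jamscope` therefore measures perimeters as
the length of the 0.5-level marching-squares contour of the lightly
smoothed mask (`contour_perimeter()`, smoothing σ = 2 px): the
interpolated contour tracks the true edge with subpixel accuracy at any
orientation, giving squares, hexagons and disks within 1 % of their
closed forms and scale invariance within 0.5 % under 2× upsampling. Its
known cost is corner rounding ~σ, i.e. q is underestimated by ~0.5 % for
~30 px cells — identical for all conditions compared.

`segment_membranes()` converts a membrane/F-actin image into labels:
Gaussian smoothing, then either (with seeds) a seeded watershed
implemented as level-synchronous flooding — basins dilate through all
pixels at or below the rising water level, so competing labels meet on
membrane ridges — or (without seeds) EBImage's watershed on the inverted
image with h-minima suppression via its tolerance parameter. Unseeded
watershed over-segments on weak ridges; seeds (e.g. nuclei) are
recommended. Masks from any external segmenter are accepted as
first-class input (`label_mask()`, `read_mask_tiff()`).

`classify_jamming()` compares mean q against `p0` (default 3.813 — the
more precise of the two printed variants of the threshold, with 3.81 the
rounded one). Cells can be pooled (default) or aggregated as
mean-of-per-field-means via `by`; both are legitimate and reported
explicitly, since they differ when field sizes differ.

## The synthetic monolayer

`simulate_monolayer()` integrates `n_cells` active Brownian particles
(ABPs) with soft harmonic repulsion in a periodic square box
(Euler–Maruyama, stability guard `dt ≤ cell_radius/(10 v0)`): each cell
moves at `v0` along a heading that diffuses with rate `d_r`, and
overlapping disks repel with drift `repulsion_stiffness × overlap`.
Initial positions are a jittered hexagonal lattice; an equilibration run
(`equil_time = 30` min of the same dynamics, positions re-origined)
removes the lattice-relaxation transient from recorded statistics.

Defaults are chosen once to match the study geometry: ~300 cells per 40×
field at 0.75488 μm/px implies `n_cells = 300` cells of radius 11 μm
(≈ 380 μm² each) in a ≈ 356 μm box (packing ≈ 0.9), 41 frames at 5 min.
`repulsion_stiffness = 0.05` μm/min per μm overlap treats cells as
soft and deformable — centres can approach while shapes (the Voronoi
tessellation) absorb the strain; stiffer packings order the centre
pattern so strongly that even fast-moving monolayers retain hexagonal
Voronoi statistics, which is not what elongation-with-motility looks
like. `d_r = 0.1`/min gives a 10-min persistence time.

The renderer stamps a frozen per-cell speckle texture (blurred noise,
cosine-tapered to the cell radius) at each wrapped position using a
band-limited Fourier subpixel shift — bilinear placement would blur
fraction-dependently and alias into PIV displacement estimates — then
adds Gaussian sensor noise and quantizes to 8/16 bits. The rendered
window is an interior crop of the periodic box so velocimetry never sees
a wrap seam. `voronoi_masks()` rasterizes the periodic Voronoi
tessellation of the cell centres as space-filling labels (no background
boundary pixels; ties to the lower index).

What the generator emulates: caged versus flowing dynamics with a single
knob (`v0`), frame cadence and calibration, space-filling cell geometry
with motility-dependent disorder. What it does not emulate: spatially
correlated velocity fields (headings are independent), cell division and
extrusion, T1-resolved shape dynamics (centres move, shapes are Voronoi),
intensity drift/vignetting, and pseudostratified 3-D structure. Passing
tests therefore establish correctness of the measurement chain, not
biological realism of any particular parameter set.

## The jamming benchmark

`run_jamming_benchmark()` runs the full pipeline on two simulations
differing only in motility: `v0 = 0.1` μm/min ("arrested") versus
`v0 = 2.5` μm/min ("migratory"), with per-arm time steps chosen as the
largest frame-interval divisor satisfying the stability guard. The
expected contrast — high arm unjammed with larger terminal MSD and lower
terminal Q — is asserted. At these settings the low arm shows terminal
Q ≈ 1.0 and mean q ≈ 3.66 (jammed), the high arm terminal Q ≈ 0.03 and
mean q ≈ 3.85–3.90 (unjammed), stable across seeds; the rasterized
fully-random (Poisson-Voronoi) ceiling is q ≈ 3.90 at this resolution.

## Assays

`teer_value()` implements the 24-well Transwell reduction
`(raw − 100 Ω) × 0.33 cm²`; readings below the blank stay negative and
are flagged, never clipped, preserving the audit trail.
`fluorescence_per_cell()` and `positive_fraction()` are the standard
per-field normalizations. `modulus_from_storage()` applies rubber
elasticity `E = 2(1 + ν)G′`; at ν = 0.5 (incompressible hydrogel) this is
`E = 3G′`, making a G′ = 1 kPa gel the familiar "3 kPa" substrate.

## Problem sizes, determinism, limitations

The test suite and the acceptance script run simulations at reduced
scale (typically 135–500 cells, 9–41 frames, 256–384 px windows) — large
enough for every statistic to be in its asymptotic regime for the
property being tested, small enough to run on one CPU in minutes. All
randomness is funnelled through explicit integer seeds (simulation,
per-cell textures, per-frame noise are each derived deterministically
from the configured seed), so every pipeline output is bit-reproducible;
re-running a `pipeline_run` with the same configuration reproduces its
CSVs byte-identically, and the provenance record carries the config hash
and seed needed to do so.

Known limitations: PIV underestimates sub-window-incoherent motion (see
above), so MSD/Q from field integration describe collective dynamics
rather than single-cell motility; the contour perimeter rounds corners by
~σ; the unseeded watershed over-segments weak ridges; the ABP model has
no alignment interaction and so cannot reproduce swirl-scale velocity
correlations of real epithelia; and the shape statistics of the simulator
come from Voronoi geometry of centre points, not from deformable cell
outlines.
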