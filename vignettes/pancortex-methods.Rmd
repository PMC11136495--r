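---
title: "Methods: registration, dF/F extraction and neurobehavioral alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registration, dF/F extraction and neurobehavioral alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancortex)
```

`pancortex` covers the post-acquisition path of a mesoscale two-photon
(2p) imaging experiment: from widefield sensory maps and ROI-extraction
outputs to area-resolved, behavior-aligned single-neuron statistics.
This vignette documents the models, conventions, parameters and design
choices, and what the synthetic test bench does and does not establish
about real data.

## Coordinate conventions

All rasters are matrices with row = y increasing downward (posterior)
and column = x increasing rightward; continuous point coordinates are
0-based `(x, y)` and a point belongs to the pixel that contains it
(floor). Pixel centers sit at half-integer coordinates. Every module —
atlas lookup, registration, the synthetic generator — uses this single
convention, which is why registration accuracy can be scored exactly
against generator ground truth.

## Atlas projections

The cortical area map is a 2D integer label raster (0 = off-map) with an
accompanying area table (id, acronym, hemisphere). When a 3D label
volume is supplied, `project_map()` rotates it about the
anterior–posterior axis and takes the first nonzero voxel along each
top-down ray ("surface view"). Two presets matter in practice: 0° for
upright (dorsal) preparations and a 22.5° roll for side-mount
preparations that expose lateral cortex. Because labels are categorical,
rotation uses nearest-neighbor interpolation; the rotation center is the
centroid of the nonzero voxels. Neither choice is canonical — smooth
interpolators are meaningless for labels, and any fixed center differs
from the centroid only by a translation absorbed by the later landmark
registration — so these are this package's choices, made once and
verified against a brute-force voxel-loop oracle in the tests.

## Widefield multimodal mapping

Sensory response images are stimulus-triggered averages: per trial and
pixel, `(mean response − mean baseline) / F₀`, with windows of 1 s
before and after each onset and `F₀` the global 10th percentile of all
movie intensities. Windows are closed–open in frames,
`[onset − 1 s, onset)` and `[onset, onset + 1 s)`, with fractional
boundaries floored — a deterministic rule that makes hand-computed
fixtures exact. Trials whose windows straddle the movie edges are
dropped (with a warning), not padded. Because `F₀` scales with the
movie, the response image is invariant to global intensity scaling.

Response masks keep pixels at ≥ 50 % of the image maximum, reduced to
the largest 4-connected component. The mapping protocol only requires
the suprathreshold area to be contiguous; the 0.5 fraction is the
package default and is exposed as a parameter (`level_frac`). The MMM
bundle (`compose_mmm()`) is purely compositional — vasculature image,
per-modality masks/outlines, named skull landmarks — with no
resampling; anesthetized vs. awake acquisition is metadata only.

## Two-step registration

Both alignments (CCF→MMM and 2p→MMM) are fitted from user-curated
landmark pairs. With fewer than 6 pairs a least-squares affine is used;
with 6 or more, a piecewise-affine transform: Delaunay triangulation of
the source points with one exact affine per triangle, so the transform
is exact at every control point. Landmarks are curated by hand, so no
robust-fitting (RANSAC-style) machinery is used. Points outside the
source hull are mapped by the global affine fitted to all pairs and
flagged `out_of_hull`, rather than erroring — callers can drop them.
Inversion refits the swapped landmark roles, which is again exact at
control points.

Area assignment is the double reverse-transformation: each 2p centroid
goes 2p→MMM, then MMM→CCF through the *inverse* of the CCF→MMM fit,
then a nearest-pixel lookup on the label raster. Off-map or background
points come back unassigned (`NA`) — a value, not an error, since real
sessions always have a few ROIs beyond the mapped sheet.

All registration is 2D. Brain curvature produces depth offsets of
roughly 200 µm across 2.5 mm of a curved-window preparation; this
z-structure is not modeled, only documented.

## dF/F extraction

The trace pipeline is: screen ROIs at cell probability ≥ 0.5 → subtract
neuropil `F − γ·F_neu` with γ = 0.7 → rolling-percentile baseline →
`dF/F = (F − F₀)/F₀` → resample to 10 Hz.

The rolling baseline is the package's one compiled kernel (Rcpp, sliding
sorted window): for each sample, the linear-interpolation percentile
(R `quantile` type 7) over a centered window of `W·rate` samples
(default W = 30 s, percentile 10). Whether the original analyses used
centered or trailing windows is not documented; centered was chosen for
phase neutrality and the window shrinks at the trace edges (a window
longer than the trace gives the full-trace percentile everywhere).
Degenerate baselines (`F₀ ≤ 0`) are an error naming the offending
neurons, since dF/F is meaningless there.

Resampling follows acquisition practice: integer downsample ratios take
every k-th sample *without prior filtering* — deliberately, despite the
aliasing risk, because that matches how the source data streams are
conditioned; Fourier-method resampling is used for upsampling; and
non-integer downsampling falls back to linear interpolation with a
logged message. Session length is the shorter of the neural and
behavioral streams.

## Behavior

Primitives arrive on native clocks (wheel encoder 100 Hz, face cameras
30 Hz) and are harmonized onto one 10 Hz grid over their overlapping
span. Camera-trigger jitter on the order of 10 ms is ignored at 10 Hz
resolution. Motion energy is the ROI-summed absolute frame difference.
Bout detection takes maximal supra-threshold runs and discards those
shorter than 900 ms — the minimum-bout default borrowed from
behavioral-motif segmentation practice; the detection threshold itself
has no principled default and is a required argument.

## Sorting

`pc_sort()` z-scores each neuron over time (constant neurons become
zero vectors, hence loading 0), takes the SVD, and orders neurons by
descending loading on PC1 or PC2, ties broken by original index. The
component sign is fixed so the summed loading is nonnegative.

`cluster_sort()` is an explicitly simplified version of the published
Rastermap ordering: k-means on z-scored activity (seeded, 10 restarts,
best inertia), cluster chaining by the asymmetric similarity
`max over lags ℓ ∈ [0, max_lag] of corr(x[1:n−ℓ], y[1+ℓ:n])`
(Pearson on the overlapping segments, so the measure is scale-free;
zero-variance segments contribute 0; ties take the smallest lag), and
within-cluster ranking by correlation to the cluster mean. The
published algorithm's within-cluster upsampling in PCA space is a
non-goal and is not reproduced; group boundaries on a sorted raster
remain user inputs, as they are selected by eye in practice.
Superneuron rows average 50 adjacent sorted neurons (last block
smaller) and are z-scored per row for display.

## Neurobehavioral statistics

Per-neuron correlations are plain Pearson r. Zero-variance neurons get
r = 0 *with a flag* rather than `NA`, so per-area means stay defined;
flagged neurons are excluded from t-tests. Per-area statistics use
`t = r̄/(s/√n)` with df = n − 1 and include only areas with ≥ 20
neurons (the reporting rule used for per-area maps; smaller areas are
listed but not quantified). p-values are two-sided by default — the
conservative choice when the direction is not pre-registered — with a
one-sided option. No multiple-testing correction is applied across
areas; per-area p-values should be read descriptively. Reported
session-level "median t" constructions that mix session df with
per-area tests are not reproduced; this package computes per-area t
with the area's own df.

Group density maps report, per area with ≥ 20 neurons,
`100 × (group members in area) / (area total)`; for any partition of
neurons into groups these percentages sum to 100 per area, which the
tests assert as an identity. Correlation distributions are summarized
by their histogram mode (bin width 0.05 on [−1, 1]) and the adjusted
Fisher–Pearson skewness `G1 = g1·√(n(n−1))/(n−2)`, cross-checked
against `e1071::skewness(type = 2)`.

## The synthetic test bench

The generator produces complete sessions with known ground truth, and
its defaults *are* the study conditions: ~30 cortical areas, 3 Hz 2p
sampling (the typical large-FOV rate), GCaMP6s kernel rise 0.2 s and
decay 1.2 s, neuropil gain 0.7, behavior at 100/30/30 Hz, and
ON/OFF/uncoupled fractions 0.4/0.2/0.4 for coupling-recovery runs.
Coupling magnitudes are uniform in [0.5, 1.5] on z-scored regressors —
chosen (once) so per-neuron correlations fall in the −0.6..0.6 range
typical of such recordings; they are generator choices, not measured
facts. The rate link is a softplus rather than an exponential, keeping
rates bounded and transient amplitudes of order 0.1–1 dF/F.

Three constructions deserve explanation:

- **Area maps** are Euclidean Voronoi partitions of an elliptical
  sheet; pixelation can leave diagonal slivers of a cell 4-disconnected
  from its seed, so disconnected fragments are detached and regrown
  from the seed-connected components, guaranteeing one 4-connected
  region per area.
- **Ground-truth fluorescence** is defined as the neuropil-free
  component of the stored trace, `F − gain·F_neu`. This makes "neuropil
  subtraction at the generator gain recovers the truth" an exact,
  bit-level identity rather than a floating-point approximation, which
  is the property the pipeline tests assert.
- **Poisson spiking** means even uncoupled, noise-free neurons
  fluctuate; "constant" expectations apply to the rate, not to any
  single realization, and the tests are phrased accordingly.

What passing these tests shows: the geometry, algebra and bookkeeping
of the pipeline are correct — transforms invert, assignments match
ground truth away from boundaries (≥ 99 % at zero landmark jitter,
≥ 95 % at 1 px), coupling signs are recovered, sorting recovers planted
structure. What it does not show: robustness to real-data pathologies
the generator does not emulate — motion artifacts, hemodynamic
contamination, bleaching, non-affine tissue distortion, segmentation
errors, or behavioral covariates beyond three primitives.

## Problem sizes and determinism

Test and acceptance runs use 128×128-pixel maps, 500-neuron
registration sessions, a 2000-neuron × 20 min × 3 Hz coupling session,
and 100-instance oracle sweeps — sizes chosen so the full suite
exercises every path at interactive timescales while keeping the
statistical margins wide. Every stochastic step is seeded; a session is
a pure function of (seed, configuration), and the pipeline itself is
deterministic (identical inputs give bit-identical dF/F).

## Interfaces

File formats are deliberately plain: label rasters as 16-bit TIFF,
area tables / landmarks / neuron tables as CSV, transforms and ground
truth as JSON, session trace arrays as CSV (equivalent in content to
Suite2p's array outputs, which have no native R reader). A thin
command-line wrapper (`inst/cli/pancortex`) exposes the projection,
fitting, assignment, dF/F and simulation entry points for shell use;
all logic lives in the exported functions.
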