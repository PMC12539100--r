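---
title: "Methods: vascular network quantification from 3D image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vascular network quantification from 3D image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselnet)
```

## Scope and model

vesselnet quantifies the topology of stained vascular networks in
calibrated 3D fluorescence stacks. The underlying model is deliberately
minimal: vessels are bright, roughly tubular structures on a darker
background; the biologically meaningful object is not the voxel mask but
the network graph — centerlines, their branching points and free ends.
Everything in the pipeline serves the reduction

volume → binary vessel mask → one-voxel-thick skeleton → graph.

Assumptions worth stating explicitly:

* one channel, one stain; the signal is monotonically related to vessel
  presence (no inverted contrast);
* voxel calibration (dz, dy, dx in µm) is known — lengths and per-mm³
  densities are meaningless without it;
* intensity within vessels may vary strongly (it does, in cleared
  whole-mount preparations) and the background may fluoresce; both are
  imaging artifacts the preprocessing has to undo, not features.

Axis convention everywhere: arrays are indexed `[z, y, x]` with
`dim = c(nz, ny, nx)`, z being the TIFF page axis. Calibration follows
the same (dz, dy, dx) order.

## The stages and their parameters

### Preprocessing

Fixed order: downscale → brightness window → background subtraction →
Gaussian blur. The order is not configurable; making it configurable
would create silently incomparable runs of the same nominal parameter
set.

* `scale_xy` (factor in (0, 1], default 1): local-mean area resampling of
  x and y only. Large tiled acquisitions are commonly halved before
  processing; area resampling preserves mean intensity and physical
  extent (the voxel pitch is divided by the factor).
* `brightness_min`, `brightness_max` (intensity units, defaults 0 and the
  bit-depth maximum): a plain linear window with clipping, then rounding
  (round-half-to-even). An explicit window was chosen over any
  auto-contrast: reproducibility beats convenience, and the window is the
  natural knob for lifting weakly fluorescing vessels above the
  threshold (lower `brightness_max`) or sharpening definition (raise
  both). Degenerate input `low >= high` is an error, not a silent clamp.
* `background_radius` (pixels, default off): classic per-slice
  rolling-ball subtraction, implemented as grayscale opening with a
  non-flat hemispherical structuring function. It is optional and off by
  default because well-windowed images rarely need it; it earns its keep
  on stacks with strong diffuse background.
* `gaussian_sigma` (voxels, per axis, default 1.5 isotropic): separable
  convolution, half-sample reflective boundaries, kernel support 4σ. The
  blur is the main reconnection mechanism for vessels fragmented by
  intensity heterogeneity; σ per axis matters because z sampling is
  usually coarser than x/y. σ = 0 on an axis disables smoothing there.
  The default was fixed once against the phantom battery: small enough
  to keep a 3-voxel-radius tube's cross-section intact after
  thresholding, large enough to bridge few-voxel fragmentation gaps.

### Binarization

* Yen threshold: a 256-bin histogram over the observed min..max of the
  (already windowed) volume; the returned threshold is the bin boundary
  maximizing the maximum-correlation criterion, ties broken toward the
  lowest threshold so the result is deterministic. Foreground is
  *strictly above* the threshold. A constant image has no threshold and
  is a per-image error (batch runs log and skip it).
* `particle_min_size` (pixels, default 5): per-slice 2D 8-connected
  components below this area are deleted — the slice-wise semantics of
  the classic particle-analysis step on stacks, which is what users of
  that step expect. A `particles_3d` switch provides volumetric removal
  (26-connected, voxel count) for workflows that prefer it; default off.
* `closing_max_radius`, `closing_min_radius` (voxels per axis, default
  1): a 3D maximum filter then a 3D minimum filter with ellipsoidal
  neighbourhoods. Separate radii are exposed because the two filters are
  genuinely separate knobs (unequal radii give a net dilation or
  erosion); equal radii realize morphological closing, which bridges
  gaps up to twice the radius. At the volume border the maximum filter
  treats outside as background and the minimum filter as foreground, so
  closing never erodes structures that touch the border.
* Hole filling: 6-connected background components not touching the
  border become foreground. Foreground uses 26-connectivity, background
  6 — the standard complementary pair; mixing any other pair invites
  topological paradoxes. The practical reason for the step is downstream:
  an enclosed cavity survives thinning as a closed shell and contaminates
  the skeleton with loops (`graph_cycle_rank()` makes this visible; the
  acceptance tests check it).

### Skeletonization and graph

* Thinning: iterative deletion of *simple points* — voxels whose removal
  provably changes neither 26-connected components nor tunnels nor
  cavities (topological numbers T26 = 1 for foreground, T6 = 1 for
  background). Candidates are collected per border direction (six
  subiterations), then deleted sequentially with a re-check, in a fixed
  z, y, x scan order; the sequential re-check makes topology
  preservation unconditional and the scan order makes results
  deterministic. Voxels with at most one neighbour are protected so line
  ends are kept. The companion check `cycle_rank()` (components +
  cavities − Euler characteristic, all computed independently of the
  thinning code) is how the tests verify topology preservation rather
  than assuming it.
* Voxel classes by 26-neighbour count: ≤ 1 end, 2 slab, ≥ 3 junction.
  Adjacent junction voxels merge into one junction node, so a thick
  crossing counts once; the reported junction count is merged clusters,
  not raw junction voxels (the honest choice when comparing against
  manual counts — a single anatomical branch point should not count
  multiple times because the thinning left a 2-voxel cluster).
* Segments end in two junctions, two end points, or one of each. Two
  corner cases need conventions: a closed slab ring with no terminal
  voxel at all is one loop segment with zero endpoints; an isolated
  voxel is one zero-length segment. Segment lengths are summed
  calibrated Euclidean steps between voxel centres.
* `prune_length` (voxels, default 5): a single pass deletes terminal
  branches — segments with one end-point terminus and one junction
  terminus — whose non-junction voxel count is below the threshold,
  keeping the junction voxels; classes and graph are then recomputed
  once. Free-floating segments (two end points) are never pruned: they
  may be small genuine vessels, not artifacts of thinning. Whether such
  pruning should iterate (newly exposed short branches) is genuinely
  open; this package defines it as single-pass, with `prune_iterative`
  available, because a single application is predictable and the default
  threshold is small. `prune_calibrated` switches the threshold to µm
  for anisotropic stacks.

### Measurements

Per image: volume fraction (foreground / total voxels); network length
as skeleton voxel count, raw and per mm³ of imaged volume
(`(nz·dz)(ny·dy)(nx·dx)·10⁻⁹` mm³); skeleton, segment, junction and
end-point counts; all segment lengths in µm. Densities are normalized to
the full imaged bounding volume, not to a hull of the specimen — the
bounding volume is what "imaged volume" means, and hulls introduce their
own parameters. A calibrated total network length in µm (sum of segment
lengths) is emitted as a clearly labelled extra column; the voxel-based
length remains the primary unit.

### Validation and statistics

`skeleton_overlap()` scores the percentage of produced-skeleton voxels
inside a ground-truth mask; because both are thin, the ground truth is
usually dilated 1–2 rounds first (`dilate_ground_truth()`, 3×3×3 cube by
default, 6-neighbour cross available) and the growth percentage is
reported alongside. Overlap is monotone in dilation rounds by
construction.

`mann_whitney_bonferroni()` uses exact enumeration of all group
labellings when `min(n) ≤ 8` (and the enumeration is feasibly small),
which covers the group sizes typical for organoid experiments (n of
2–9); ties are handled exactly in that branch and by midranks with the
tie-corrected variance (plus continuity correction) in the normal
branch. The number of tests `m` in the Bonferroni correction is supplied
by the caller per analysis family — inferring family size silently is
exactly the kind of decision that should stay visible in analysis code.
`glass_delta()` uses the control-group standard deviation with the n−1
denominator (the conventional estimator; with control groups of 2–9
values the choice matters and is therefore stated), and the ≤ 0.2 /
≤ 0.5 / > 0.5 category cuts with inclusive boundaries.

## The phantom generator

`phantom_spec()` / `render_phantom()` draw tubes of given radius around
centerline polylines and corrupt them the way confocal vasculature data
is corrupted: a smooth seeded multiplicative intensity field inside
vessels (the cause of fragmented segmentations), constant background
fluorescence, additive Gaussian noise, optionally weak (low-contrast)
vessels and explicit fragmentation gaps that erase tube voxels along an
arc span while leaving the truth untouched.

The ground truth — tube mask, centerline skeleton, and the counts of
skeletons, segments, junctions and end points with segment lengths — is
derived from the centerline graph *by construction* (unique path
endpoints as graph nodes, degree-2 nodes contracted), never by running
the analyzer on the rendered image. Generator and analyzer are therefore
independent, and "pipeline counts equal truth" is a real test, not a
tautology.

`make_test_suite()` fixes seven phantoms at 96³ voxels, 1 µm isotropic,
tube radius 3: straight tube, Y-bifurcation, H-network, two disjoint
networks, closed loop, fragmented tube (two 3-voxel gaps), low-contrast
tube. The canvas size is a design choice: large enough that every
topology fits with comfortable margins, small enough that the full
battery renders and processes in seconds, which keeps the whole test
suite fast. The battery is noise-free by default because its job is
exact topology recovery; noise and heterogeneity can be switched on for
robustness experiments.

What the phantoms deliberately do **not** emulate: optical anisotropy
(PSF elongation in z), depth-dependent attenuation, vessel radius
variation along a branch, and curved-sheet structures. Passing the
battery therefore demonstrates correctness of the algorithms on clean
tubular topology — it does not certify segmentation quality on any
particular real dataset, which is why the overlap-versus-ground-truth
tooling exists and why parameter defaults should be re-examined per
dataset (brightness window and σ first; the diagnostics are fragmented
or artifact-laden skeletons).

## Numerical and I/O details

* Histograms for thresholding span observed min..max in 256 bins
  regardless of bit depth; after an 8-bit-style window this matches the
  behaviour users expect from 8-bit tools, while still working on 16-bit
  input.
* Convolution boundaries are half-sample reflective; closing treats
  out-of-volume as background for dilation and foreground for erosion
  (see above); component labelling never wraps.
* The thinning scan order, threshold tie-break, lexicographic batch
  ordering and CSV writers make every pipeline stage bit-reproducible;
  the acceptance script checks byte-identical batch reruns.
* TIFF reading accepts 8- and 16-bit single-channel multi-page files.
  Calibration precedence: explicit override > ImageJ-style metadata
  (`spacing=` plus resolution tags) > the JSON sidecar written by
  `write_volume()`; with none of the three, reading fails rather than
  guessing. The available TIFF writer cannot embed description tags, so
  the sidecar is how round-trips preserve calibration; binary masks are
  written as 0/255 8-bit.
* Batch processing isolates failures per image (logged, skipped) —
  unprocessable stacks occur in real experiments and must not poison a
  batch.

## Limitations

* No vessel radius, tortuosity or orientation measurements; the skeleton
  graph would support them, but they are out of scope here.
* Machine-learning segmentation is intentionally absent; the automatic
  threshold plus morphology is transparent, fast and parameter-light.
* The junction count of heavily thickened crossings depends on the
  thinning's cluster structure; merged clusters mitigate but do not
  define away the ambiguity of what "one junction" means anatomically.
* Exact Mann–Whitney enumeration is quadratic-combinatorial; above the
  small-sample regime the tie-corrected normal approximation is used,
  which is standard but approximate.
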