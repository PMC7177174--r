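---
title: "Simulating radiologist interaction with a semi-automated 3D segmentation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating radiologist interaction with a semi-automated 3D segmentation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why simulate a rater?

Semi-automated lesion segmentation tools are initialised and corrected by a
radiologist in real time: a drag across the lesion's longest extent on one
slice, perhaps a perpendicular short-axis drag, single clicks that "drop"
hard constraints on the contour, further drags on the reformatted coronal
and sagittal planes, and — when all else fails — manual editing. Validating
such a tool on a large labelled cohort is laborious precisely because a
human must interact with every case after every algorithm change.

`interseg` replaces the human with a deterministic simulated rater. Given a
ground-truth mask, it drives a pluggable segmentation engine through the
same workflow a radiologist would follow, placing drags and clicks *only
where the evolving result disagrees with the ground truth*, and measures how
3D accuracy (Dice similarity coefficient, `DSC = 2|A∩B|/(|A|+|B|)`) changes
with the level of interaction. The package bundles everything needed to run
that experiment end to end with no external data: lesion preparation,
axis-drawing strategies, a reference engine, the interaction loop,
evaluation, a phantom generator and an experiment runner.

## The simulated workflow

For each lesion (a connected component of the ground truth, 26-connected by
default; adjoining lesions are split beforehand by a zero-valued separator
mask, mirroring how a human would cut them apart):

1. **Slice choice.** Within the central third of the lesion's axial slice
   range, the slice with the largest ground-truth area is chosen — a proxy
   for a radiologist scrolling to where the tumour looks largest. For a
   range `[a, b]` with `n` slices the central third is
   `[a + floor(n/3), a + ceil(2n/3) - 1]`, which is exact, always nonempty,
   and degenerates to the single slice when `n < 3`. Area ties go to the
   lower slice index.
2. **Long axis.** One of four strategies (below) draws the initial drag on
   the ground-truth cross-section.
3. **2D segmentation**, then optionally the **short axis** (the longest
   chord perpendicular to the long axis) and the **dropped-point loop**: the
   ground-truth boundary point farthest from the current contour is clicked,
   the engine re-segments, and the loop repeats until no disagreement
   exceeds `disagreement_threshold_px` (default 2 px), a cap of `max_drops`
   (default 5) is reached, or no eligible point remains (new points must be
   at least `min_spacing_px = 5` px from earlier ones). The disagreement
   metric is one-directional — from ground-truth boundary points to the
   segmentation boundary — because the click must land on the *true*
   boundary; a symmetric Hausdorff distance would allow clicks on spurious
   segmentation excursions outside the lesion.
4. **MPR.** The long-axis midpoint centres the reformatted coronal and
   sagittal planes. At MPR levels the same strategy machinery draws axes
   (and short axes, and drops) on those planes' ground-truth cross-sections.
5. **Scout and 3D.** The engine segments the coronal/sagittal planes using
   an intensity model re-learned from the completed axial 2D result, then
   runs full 3D segmentation seeded by the three plane masks.
6. **Edit to perfection** (the strongest levels) replaces the in-scope plane
   masks with the exact ground-truth cross-sections before the 3D stage.
   This is plane-mask replacement, not voxel-wise 3D replacement: even a
   "perfect" set of planes leaves the 3D stage real work to do, which is
   why perfect-level 3D accuracy stays below 1.

Eight interaction levels cross the in-plane interaction (long only;
long + short; long + short + drops; edited to perfection) with the plane
scope (axial only vs all three MPR planes). Levels apply their actions
unconditionally, giving a clean factorial design; every action is recorded
in a trace that replays through the engine to the bit-identical mask.

## The four long-axis strategies

* **`true_longest`** — the boundary-pixel pair at maximum Euclidean
  distance (the RECIST-style longest diameter), found exactly.
* **`medial`** — an ellipse is fitted to the cross-section by PCA (centroid
  plus eigendecomposition of the pixel covariance; half-lengths
  `2·sqrt(eigenvalue)` recover an exact ellipse's semi-axes) and the longest
  chord parallel to its major axis is taken. This axis tends to cross the
  lesion centre, where intensity-driven engines can exploit symmetry.
* **`statistical`** — candidate boundary points are spread at multiples of
  `spacing_deg` (default 3°) of polar angle about the ellipse centre,
  centred on each medial endpoint, and every candidate pair `(i, j)` is
  scored:

  `Score = α·(1 − D_KL) + β·Length + γ·Centrality`

  with `Length` the candidate length relative to the true longest axis,
  `Centrality = 0.1 + 0.9·C/(2r)` where `C = |i − r| + |j − r|` (`r` is the
  centre index, and `C` is halved when `i` and `j` fall on the same side of
  `r`, favouring axes that cross the centre), and `D_KL(P‖Q) =
  Σ P log(P/Q)` the Kullback–Leibler divergence between the Parzen-window
  intensity densities of all lesion pixels (`P`) and of the pixels sampled
  under the axis (`Q`, bilinear samples at 0.25-px steps). A drag whose
  pixels "typify" the lesion has low divergence.
* **`swept`** — starting from the true longest axis, the second endpoint
  slides along the boundary (one boundary pixel per step, up to
  `sweep_arc_mm = 10` mm each way); each position triggers the engine's
  interactive 2D segmentation, scored by 2D Dice against ground truth, and
  the best position wins. Because the start position is in the candidate
  set and wins ties, the sweep can never score below its starting axis.
  Sweeping is scored on the immediate 2D result rather than the downstream
  3D mask: the sweep models *interactive* feedback, and a 3D evaluation per
  position would be neither real-time nor what a user watching the 2D
  contour responds to.

## The reference engine

The engine is pluggable (any object providing `segment_2d`,
`segment_scout`, `segment_3d` with the documented contracts can be
registered by name); the reference engine `"parzen_rg"` is a probabilistic
region grower:

1. A foreground Parzen density is estimated from intensities sampled under
   the user's drags. Two robustness choices matter here. First, a 1-px
   margin at each drag endpoint is excluded: endpoints sit on the visible
   boundary, where partial-volume mixing with background would broaden the
   model. Second, only the central 10–90% quantile band of the samples
   enters the density: boundary-mixture tails otherwise bleed the model
   across the lesion edge. Interior modes such as a dark necrotic core
   survive the trim (and anything fully enclosed that is lost to it is
   recovered by hole filling).
2. A background density comes from a 2-px ring just outside the region of
   interest — a disc centred at the long-axis midpoint with radius
   `roi_radius_factor` (default 1.5) times half the axis length, expanded
   if needed to cover dropped points.
3. Each ROI pixel receives a foreground posterior under equal priors;
   pixels above `posterior_threshold` (default 0.5) are kept.
4. The connected component containing the drawn axes is retained (the axis
   raster is forced into the mask, which also guarantees the containment
   contract), and holes are filled.
5. Dropped points are enforced: the tissue between the ROI centre and each
   drop is folded into the foreground model (the click asserts that the
   structure reaches that boundary point); if the contour still misses a
   drop, a one-pixel bridge is grown to it, and if the mask overshoots past
   a drop, an open notch is carved along the outward ray. The contract —
   every drop within `drop_tolerance_px = 1.5` px of the final boundary —
   is checked and reported.

The scout stage re-estimates the foreground model from the axial 2D mask
pixels, honouring any user axes and drops on the coronal/sagittal planes.
The 3D stage learns its model from all three plane masks, bounds its search
with an ellipsoid whose semi-axes are the per-plane mask half-extents times
`roi_radius_factor`, takes its background from the shell just outside that
ellipsoid, keeps the 26-connected component containing the plane-mask
seeds, and fills 3D holes (background components not reaching the
subvolume border). Because the three plane masks all contain the axis
midpoint, their union is connected, so the seed component is unique. Every
stage is deterministic; identical inputs give bit-identical masks.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha, beta, gamma` | 0.5 / 0.3 / 0.2 | score weights (divergence / length / centrality); the degenerate settings (one weight 1) force the documented behaviours |
| `N` | 8 | candidates per endpoint side; each side holds `N+1` points indexed `0..N`, centre `r = N/2` |
| `spacing_deg` | 3° | polar spacing of candidates ("a few degrees") |
| `sweep_arc_mm` | 10 mm | sweep half-arc each direction |
| `bandwidth` | 2% of plane range | Parzen kernel width |
| `kl_floor` | 1e-8 | smoothing added to `Q` before the log |
| `roi_radius_factor` | 1.5 | ROI radius / half axis length |
| `posterior_threshold` | 0.5 | foreground posterior cut |
| `drop_tolerance_px` | 1.5 px | drop-to-boundary contract |
| `min_spacing_px` | 5 px | minimum distance between drops |
| `disagreement_threshold_px` | 2 px | disagreement worth fixing |
| `max_drops` | 5 | drops per plane (matching the "five points" a user plausibly places on a complex lesion) |
| `cat1_dsc, cat2_dsc, delta` | 0.883 / 0.796 / 0.05 | category thresholds and the significant-change margin used in cohort comparisons |

The weights `α, β, γ` have no canonical published values; the defaults
weight statistical typicality slightly above length and centrality and are
fully configurable.

## Design decisions on genuinely open points

* **Centrality direction.** As printed, `0.1 + 0.9·C/(2r)` *increases* with
  distance from the medial endpoints, while the halving rule and the
  surrounding motivation favour centre-crossing axes. We implement the
  formula exactly as printed (with the halving applied to `C`, not to the
  final value — halving the final value would break the 0.1 floor) and
  expose `invert_centrality` to use `0.1 + 0.9·(1 − C/(2r))` for the
  apparent intent. The printed form is the default.
* **Candidate indexing.** "`N` points per side with centre index `N/2`"
  only admits the full index range `0..2r` of the centrality formula if
  each side holds `N+1` points; we use `N+1` per side, which also makes the
  construction symmetric about the endpoint.
* **Chord searches.** The medial and short axes are found by an exact
  search over boundary-pixel pairs whose perpendicular offsets differ by at
  most 0.5 px — the same resolution as offset stepping, but with a clean
  brute-force equivalence that the test suite verifies exactly.
  Consequently the short axis is perpendicular up to the lattice: the
  deviation angle is `atan(0.5/length)`, sub-degree for typical axes; an
  exact 1° guarantee is unattainable with endpoints constrained to pixel
  centres on short chords.
* **Divergence clamping.** `1 − D_KL` implies a bounded reward but KL is
  unbounded; `D_KL` is clamped to `[0, 1]` before use.
* **Degenerate inputs.** Empty-vs-empty masks score Dice 1 (an evaluation
  must not crash on failed lesions; empty-vs-nonempty scores 0); a mask
  with no chord at the ellipse orientation falls back to the true longest
  axis with a warning; a boundary too small for `N` candidates reduces `N`
  symmetrically with a warning; a ground-truth plane missed by a lesion is
  simply emptied at edit-to-perfection, and 3D proceeds from the remaining
  planes.
* **Numerical estimation.** The exported `parzen_pdf()` is the exact
  Gaussian-kernel estimator (what the axis score uses, and what the tests
  compare against a direct-summation oracle to 1e-12). The engine's
  per-pixel posteriors instead use a binned estimate — a 256-bin histogram
  convolved with the Gaussian kernel — which is equivalent at grid
  resolution (the kernel spans several bins) and an order of magnitude
  faster on full planes and volumes.
* **Ties.** Deterministic everywhere: lowest slice index for equal areas,
  first scan-order boundary pair for equal lengths, lowest `(i, j)` for
  equal scores, the start position for equal sweep Dice, descending voxel
  count then lexicographic bounding-box minimum for lesion ids.

## The phantom generator

Real post-contrast T1 brain-tumour data cannot ship with a package, so the
study conditions are emulated by a seeded generator producing image +
ground-truth pairs with the features the simulation actually exercises:

* **Shapes.** Spheres, randomly rotated ellipsoids, and lobulated shapes
  built as star-shaped radial perturbations
  `r(θ, φ) = r0·(1 + amp·P(θ, φ))` with low-order spherical-harmonic-like
  terms and seeded coefficients normalised so the surface stays
  star-shaped — concave enough to need dropped points, never
  pathological.
* **Intensity.** Region means (background 20, lesion 40–100, optional dark
  necrotic core at 45 — inside the target mask, as a non-enhancing core
  belongs to the gross tumour), per-region texture noise, a 0.8 mm
  partial-volume Gaussian blur, and acquisition noise (sd 4). The
  contrast-to-noise ratios exercised span 5–20.
* **Multiplicity and adjacency.** Suites mix solitary and two-lesion cases
  at roughly 80/20 (the multiplicity mix of typical glioma cohorts), and an
  adjacency mode places two touching spheres along a lattice axis together
  with the axis-aligned separator plane that splits them — the digital
  analogue of manually drawn separator lines.

Truth masks are the pre-blur analytic shapes, so geometric oracles (e.g.
the 4/3·π·abc ellipsoid volume) apply. What the phantoms do **not**
emulate: brain anatomy, bias fields, multi-spectral contrasts, skull,
registration error, or inter-rater ambiguity in the ground truth itself.
Passing the suite therefore demonstrates that the simulation machinery,
engine contracts and accuracy ordering behave as designed — not that the
reference engine would reach any particular absolute accuracy on clinical
MR data.

## Problem sizes in the shipped suites

The canonical evaluation suite (`default_suite_spec()`,
`default_difficulty_grid()`) uses 56-voxel cubes at 1 mm isotropic with
lesion radii 6–10 mm, a size at which a full 100-case × 8-level experiment
runs in a few minutes on one CPU while still exercising every code path
(lobulation, cores, low contrast, multiplicity). The engine-recovery suite
uses 64-voxel cubes with spherical lesions of radius 8–20 mm. These sizes
are the package's choices for routine verification; nothing in the
implementation assumes them, and `phantom_spec()` scales to arbitrary
volumes.

## Known limitations

* The reference engine is a deliberately simple contract-complete region
  grower; proprietary interactive engines (with learned shape priors or
  map-based constraints) will behave differently in detail. The evaluation
  pipeline runs unchanged against any engine registered through
  `register_engine()`.
* Freehand brush/ball editing is not simulated; its effect is represented
  by the edit-to-perfection level.
* Short axes are restricted to the perpendicular of the long axis;
  free-form additional drags are out of scope.
* Human wall-clock timing cannot be produced by a simulation; the runner
  logs computational stage timings for information only, and the category
  partition (axial-sufficient / MPR-drag / needs-edits at 0.883 / 0.796)
  is provided so that externally measured per-category times can be
  combined into a weighted average.
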