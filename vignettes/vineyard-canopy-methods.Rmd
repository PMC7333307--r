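---
title: "Canopy volume and missing-plant detection: models, parameters, validation"
author: "vinecanopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy volume and missing-plant detection: models, parameters, validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinecanopy)
```

## The problem

Row-trained vineyards are managed on two quantities that are tedious to
measure on the ground: the canopy volume of the vines (a proxy for
vegetative vigour and biomass) and the location of missing plants (dead or
removed vines whose slots should be replanted).  UAV photogrammetry
delivers two site-wide products from one flight — a digital elevation model
(DEM) with surface semantics (the raster sees canopy tops) and a dense 3D
point cloud — and both carry enough geometry to estimate the two quantities
unsupervised.  `vinecanopy` implements the two complementary estimation
pipelines on a uniform polygon grid that isolates three plants of one row
per cell, plus a synthetic-vineyard generator that provides ground truth
for end-to-end validation.

Throughout, the ground-measurement model of a vine is the cuboid

$$V = CH \times CT \times CL,$$

with `CH` the canopy height above the cordon, `CT` the mean canopy
thickness, and `CL` the canopy length along the row.

## The polygon grid

Cells are rectangles centered on a row axis: across the row they reach the
midpoint to each adjacent row (the full inter-row spacing), and along the
row they span `plantsPerCell` intra-row spacings $\ell_p$ (3 plants by
default; 2.5 m x 2.7 m cells at 2.5 m x 0.9 m spacing, 3 m x 3 m cells at
3.0 m x 1.0 m).  Cells tile each row from its start with half-open
intervals, so a point on a shared boundary belongs to exactly one cell.
Terminal leftovers shorter than a full cell are dropped by default
(`keepPartial = TRUE` keeps them with a prorated slot count).  Row axes
are taken from known site geometry — automatic row detection is out of
scope.

## The 2.5D surface method

1. **Terrain normalisation** (`mitigateSlope`).  The ground is estimated
   by grayscale morphological opening of the DEM with a flat disc and
   subtracted (a top-hat).  The disc only has to be wider than the canopy
   cross-section to roll under it; the default radius is 0.5 m (diameter
   1 m, against a typical 0.4 m canopy thickness).  A larger disc degrades
   slope tracking — the residual on bare terrain is bounded by
   slope x radius — which is why the radius is *not* tied to the inter-row
   spacing.
2. **Vine/soil binarisation** (`binarizeOtsu`).  The height grid is
   min-max rescaled to [0, 1] and thresholded globally by Otsu's
   criterion, evaluated exhaustively over 256 levels; pixels above the
   threshold are vine (0/black), others soil (1/white).  The mask is
   computed once for the whole site, as a global bimodal histogram is far
   better conditioned than per-cell ones.
3. **Thickness profile.**  Within a cell, the vine-pixel count of each
   image column, $\delta(x)$, scales to meters of canopy thickness
   perpendicular to the row as
   $\delta_p(x) = \delta(x)\, dp \cos\theta$, where $dp$ is the pixel
   size and $\theta$ the angle of the row against the horizontal image
   axis ($\theta$ comes from the known row azimuth by default, or from
   the principal axis of the cell's vine pixels).  Profile columns are
   those the row axis actually crosses inside the cell, so rotated cells
   do not pick up phantom gap columns at their corners.
4. **Gaps and missing plants** (`detectGaps`).  Columns with
   $\delta_p(x) < 0.1$ m are gap columns (runs shorter than 3 px are
   closed as speckle).  Their total along-row extension is
   $L_v = n_{gap}\, dp / \cos\theta$ and the missing-plant count is
   $N_{ext} = \mathrm{round}(L_v / \ell_p)$, clamped to the cell's slot
   count.  Note the division by $\cos\theta$: a horizontal span maps to a
   longer along-row distance on a rotated row; this keeps $N_{ext}$
   rotation invariant.
5. **Height and volumes** (`cellHeight`, `volumes25d`).  Per image row,
   the mean elevation of vine pixels forms $h^{(v)}(y)$ and of soil
   pixels $h^{(s)}(y)$; the canopy height is
   $dh = Q_{25}(h^{(v)}) - Q_{75}(h^{(s)}) - 0.8$ m, the cordon height
   being subtracted after the quartiles (linear-interpolation quartiles,
   the common type-7 rule).  Negative values clip to zero with a warning.
   The mean-plant volume is $V_p = dh \cdot \ell_p \cdot \delta_m$ with
   $\delta_m$ the mean of the supra-threshold $\delta_p$, and the cell
   volume is $V_{DEM} = dh \cdot dA$ with
   $dA = N_{px} (dp\cos\theta)^2$.

On a noise-free synthetic slab vineyard on flat ground the pipeline is
exact: $V_p$ recovers $CH \cdot CT \cdot \ell_p$ to pixelisation error
(under 3%), and planted missing slots are recovered exactly.

## The 3D alpha-shape method

1. **Ground segmentation** (`fitGroundPlane`).  An angle-constrained
   random sample consensus: 1000 iterations of 3-point planes, candidates
   rejected unless their normal is within 5 degrees of vertical, scored
   by the number of points within 0.5 m.  Among candidates scoring at
   least 80% of the best consensus the *lowest* plane at the site center
   is selected — on a continuous hedgerow the canopy mid-plane is a
   second admissible near-horizontal plane, and plain consensus
   maximisation can pick it.  The winner is refined by a least-squares
   plane through its inliers; if the refined plane violates the angular
   constraint (genuinely steep terrain) the fit errors out rather than
   returning a wrong ground.  The consensus loop is seeded and fully
   deterministic.  Note that terrain at exactly the 5-degree limit is a
   boundary case: noise can push the refined dip marginally past the
   constraint.
2. **Canopy extraction** (`splitGroundCanopy`, `clipCell`).  Inliers are
   ground; remaining points above the plane are canopy; stray points more
   than 0.5 m below it are discarded (counted and reported).  The canopy
   cloud is clipped to each grid cell with the same half-open rule as the
   raster side.
3. **Alpha-shape volume** (`alphashapeVolume`).  The cell's points are
   Delaunay-tetrahedralised and every tetrahedron with circumsphere
   radius at most $\alpha$ = 0.5 m is kept; the volume is the sum over
   kept tetrahedra.  $\alpha$ is a *length* (the radius convention; some
   libraries use $1/\alpha$), $\alpha = \infty$ recovers the convex hull,
   and degenerate inputs give volume 0 with a warning.
4. **Missing plants** (`averageVineVolume`, `missingPlants3D`).  The
   average vine volume $\bar v$ is the mean alpha-shape volume of the
   complete reference cells divided by the slot count; reference cells
   can be supplied, or are auto-selected by classifying the cells once
   under an initial guess (the upper-quartile cell volume over the slot
   count).  A cell's plants present are
   $\mathrm{round}(V_{cell}/\bar v)$, clamped to the slot count, and the
   missing count is the complement.  Nearest-integer rounding is the
   default: a ceiling rule flips to "no plant missing" the moment a
   one-missing cell's ratio crosses 2.0, so under any symmetric per-vine
   size variation it misses about half of those cells; rounding at the
   half-integers is robust to that noise while still flagging one
   missing plant whenever the cell volume is clearly below two average
   plants.  `rounding = "ceiling"` remains available.

## The synthetic vineyard generator

`generateSite` places plant slots at $\ell_p$ along parallel rows at the
inter-row spacing, empties each slot independently with probability
`missingFraction`, and draws per-vine `CH`/`CT`/`CL` around the spec means
with a common coefficient of variation.  `renderDem` rasterises the
highest surface per pixel (canopy top over present vines, terrain
elsewhere) plus Gaussian noise — exactly the surface-model semantics of a
photogrammetric DEM.  `renderCloud` samples the terrain and the canopy
*surfaces* (top, sides, ends; never the slab bottom, which a nadir survey
cannot see) at `pointDensity` points/m².  Defaults follow the study
conditions the package targets: 2.5 m x 0.9 m spacing, NE/SW rows
(azimuth 45 degrees), 0.8 m cordon, 1.2 m canopy height above it, 0.4 m
thickness, 0.005 m/pixel DEM, 1 cm surface noise, 5% terrain slope, 15%
missing plants, canopies occupying 90% of their slot.

Three deliberate idealisations matter when reading test results:

* canopies are slabs (or ellipsoids) with smooth faces — no shoots,
  leaves, or reconstruction artifacts such as doming and occlusion holes;
* the point density is uniform, whereas photogrammetric density varies
  with texture and view geometry;
* terrain is a noisy plane, not undulating ground.

Passing the synthetic benchmarks therefore demonstrates correctness of
the *geometry processing*, not field-grade accuracy on arbitrary real
surveys.

Two scenario switches exist because the field phenomena they emulate are
the interesting validation cases. `overhangFrac` makes the neighbors of
an empty slot overhang it near the canopy top by that fraction of the
slot (the palissage "hidden gap"): the DEM then sees canopy over most of
the slot and the 2.5D method under-counts, while the volume deficit
remains visible to the 3D method.  `canopyShape = "ellipsoid"` produces
canopies whose top-surface footprint overstates their mean cross-section;
on such canopies the 2.5D cuboid volume exceeds the 3D alpha-shape volume
in every cell of the benchmark — the volume bias between the methods.
Rectangular slabs cannot express that bias: a slab fills its own bounding
cuboid, so both methods estimate the same quantity there.

## Numerical choices

* **Delaunay/alpha-shape core** (C++): incremental insertion with a
  division-free determinant insphere predicate.  Coordinates are rescaled
  to the unit box and perturbed by a deterministic, index-hashed jitter of
  1e-10, which resolves cospherical degeneracies (regular grids) with
  consistent sign decisions; simplex volumes and circumradii are then
  evaluated on the *original* coordinates, so in general position the
  result is identical to the exact Delaunay sum (verified against a
  brute-force all-tetrahedra oracle to 1e-9) and on degenerate inputs the
  error is bounded by the jitter.  A sampled solid unit cube at the
  working $\alpha$ comes out at volume 1 to machine precision.
* **Otsu**: exhaustive 256-level search on the rescaled histogram; ties
  resolved toward the lower threshold by the scan order.
* **Quartiles**: type-7 (linear interpolation), R's default, stated
  because the height estimate depends on it.
* **Rounding of counts and percentages**: half away from zero
  (`round` in R is half-even, which field reports do not use).
* **Gap bridging**: sub-threshold runs shorter than 3 px are closed
  before measuring $L_v$; at 0.005–0.01 m/pixel that is 1.5–3 cm,
  well under any meaningful gap.
* **Decimation**: cells denser than `maxPoints` (default 2000) are
  thinned by an even deterministic stride before the alpha shape; at the
  densities involved the point spacing stays far below $\alpha$, where
  the alpha-shape volume is insensitive to sampling.

## A structural property worth knowing: gap bridging at $\ell_p \approx 2\alpha$

A tetrahedron spanning an empty slot between two canopy walls a gap $g$
apart has circumradius at least $g/2$.  With $\alpha$ = 0.5 m, slots
narrower than $2\alpha$ = 1.0 m between continuous, well-aligned canopy
walls are partially *bridged* by the alpha complex, refilling part of the
missing plant's volume deficit.  At 2.5 m x 0.9 m spacing with canopies
filling 90% of their slots the wall gap of an isolated missing plant is
~0.99 m — right at the threshold — and the 3D method shows a structural
undercount of roughly 10–17% on the pooled benchmark, while remaining
within the acceptance band.  At 3.0 m x 1.0 m spacing the slot equals
$2\alpha$ and carving is robust, which is why the hidden-gap scenario is
generated at that geometry.  On real canopies, ragged wall surfaces
weaken the bridging; on synthetic planar walls it is maximal, so the
benchmark is conservative in this respect.

## Problem sizes in the tests

The validation suite runs entirely on generated data, sized for a
single-CPU desk machine: benchmark sites of 5 rows x 21.6 m (~120 plant
slots) at 0.01 m/pixel and 120–150 points/m², pooled over 20 seeds for
the end-to-end missing-plant recovery (pooling removes the ~10% integer
granularity a single ~18-missing-plant site imposes on a percentage), 6
seeds for the hidden-gap comparison, and brute-force alpha-shape oracles
up to 40 points per set.  The defaults of the generator itself remain at
the full-resolution study conditions (0.005 m/pixel).

## Known limitations

* Rasters are ESRI ASCII grids (lossless text); GeoTIFF and LAS/LAZ need
  external conversion.  No CRS transformations: everything lives in one
  local metric frame.
* Per-vine (rather than per-cell) segmentation, RGB vegetation indices,
  and automatic row detection are out of scope.
* The 2.5D method inherits the failure modes of its thresholds: short
  non-vegetated stretches inflate $L_v$ (false positives on sparse
  canopies), and overhanging neighbor canopy hides gaps (false
  negatives) — both reproduced on synthetic scenarios.
* Terrain within 0.3 degrees of the 5-degree angular limit of the ground
  plane fit may be rejected depending on noise.
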