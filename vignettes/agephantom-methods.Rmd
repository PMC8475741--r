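---
title: "Age-scalable phantom geometry: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-scalable phantom geometry: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agephantom)
```

## The model

`agephantom` implements the geometry pipeline behind age-scalable
computational phantoms used for retrospective organ dose reconstruction in
late-effects epidemiology. The phantom is a deliberately simple body model:
six scalable body regions (upper head, lower head, neck, trunk, arms, legs)
represented as axis-aligned cuboids by their eight corner points, with
organs represented as grids of points inside those regions. Simplicity is
the point — the model exists to be scalable to *any* age at treatment, not
to be anatomically detailed.

The phantom frame puts the patient's left at $+x$, runs $+y$ from superior
to inferior (the head starts at $y = 1$ cm), and $+z$ from anterior to
posterior; lengths are centimetres.

### Scaling

Children grow non-uniformly: at birth the head is about a quarter of total
height, by adulthood about a seventh. Growth is therefore tabulated per body
region $r$ and per anatomical direction $d$ at the discrete ages
$a \in \{0.1, 1, 3, 5, 10, 15, 18\}$ years. The discrete scaling factor is
the ratio to the generic (age-18) size,

$$F_{dis}(d, r, a) = \frac{S(d, r, a)}{S(d, r, 18)},$$

and between tabulated ages the continuous factor interpolates linearly on
the intervals $[0.1,1), [1,3), [3,5), [5,10), [10,15), [15,18)$:

$$F_{cont}(d, r, a) = F_{dis}(d, r, a_-) +
  \frac{a - a_-}{a_+ - a_-}\,\bigl(F_{dis}(d, r, a_+) - F_{dis}(d, r, a_-)\bigr).$$

Ages are specified to the nearest tenth of a year; growth is assumed to stop
at 18, so larger ages clamp to the adult factors (exactly 1). Each organ
scales with the region that contains it.

### Transformation

Scaling factors alone would tear the body apart, so translations keep the
regions contiguous:

* $x_t = x \cdot F_{cont}(x, r, a)$ — valid because the phantom is symmetric
  about the mid-sagittal plane.
* $y_t$ is a telescoping sum: the full scaled lengths of all regions
  superior to the point's region, plus the point's scaled offset below its
  own region's superior boundary. This guarantees *exact* contiguity of
  adjacent regions at every age (the shared boundary is the same partial
  sum computed twice) and re-bases the phantom at $y_t = 0$; the generic
  1 cm origin offset vanishes. Heights are unaffected; geometric
  comparisons are made on extents and relative positions.
* $z_t = (z - z_{abr,r}) \cdot F_{cont}(z, r, a) + z_{shift,r}$ with
  $z_{shift,r} = \tfrac12\,(l_{head,z} F_{cont}(z, uh, a) - l_{r,z} F_{cont}(z, r, a))$,
  which centres every region's scaled z-extent on the head's scaled
  mid-plane.

Two open choices had to be pinned:

* **What "head" means in $z_{shift}$.** The reference length $l_{head,z}$
  could be the upper head alone or the whole head. We use the upper-head
  region's z-length, and expose the choice (`head_ref` argument): the two
  candidates differ only by a global z-translation of the whole phantom, so
  nothing metric depends on it.
* **Arms.** Arms are fixed parallel to the sagittal plane, flank the trunk
  with the trunk's y-span, scale with their own `ar` factors, and are
  re-anchored at the trunk's *scaled* superior boundary. Because arm and
  trunk factors differ, arms may slightly overlap or detach from the trunk;
  this is tolerated (arms sit outside the y-contiguity chain).

### DICOM reorientation

Treatment planning systems expect the DICOM LPS patient frame. For
head-first supine the pinned mapping is $(L, P, S) = (10x, 10z, -10y)$
(cm → mm): a proper rotation up to the unit change, exactly invertible,
with the head at maximal $S$ and the anterior surface at minimal $P$. All
arithmetic stays in double precision; rounding happens only at DICOM
serialization, where coordinates become decimal strings at 0.001 mm
resolution (hence the round-trip guarantee of ≤ 0.001 mm per vertex).

### Structures

Body regions become per-slice rectangular contours (the exact L–P
cross-section of the cuboid). Organs become 3-D convex hulls of their point
grids, sliced per plane; each cross-section of a convex body is convex, so
the polygon is recovered exactly from the hull-edge/plane intersections.
The slice grid is pinned at $S_{min} + (k + 0.5)\,\Delta$, half-open at the
top, making contour counts deterministic (a 100 mm box at 10 mm spacing
yields exactly 10 contours); default spacing is 2.5 mm, a typical pediatric
CT slice thickness. Organs with fewer than 4 non-coplanar points (the
one-point pituitary; historically also 15-point kidneys in coarser models)
cannot support a hull: they are exported as DICOM POINT ROIs with a
warning rather than dropped, preserving their use for point-dose lookup.
A slice tangent to the hull (zero-area intersection) emits no contour.

No R DICOM library exists in this toolchain, so the package carries a
minimal DICOM Part 10 codec (explicit VR little endian, defined-length
sequences) sufficient for RT Structure Set and CT Image objects. The
conformance checker re-parses written files byte-by-byte, independently of
the writer's in-memory state. The synthetic CT series exists only to host
structures in a TPS: the phantom is water-equivalent by construction, so
voxels are 0 HU inside any body-region cuboid and −1000 HU outside.

## Validation metrics

* **Percent difference** supports both sign conventions found in practice:
  reference-minus-candidate over reference (`"eq7"`, the definitional
  form) and candidate-minus-reference (`"signed-candidate"`, the form
  consistent with published dose-comparison tables); they are exact
  negatives. Display rounding is to integer percent; full precision is kept
  internally.
* **NMSD** between two representations of the same organ is implemented as
  the root-mean-square distance over index-paired points. The defining
  formula is sometimes printed without the square root (units mm²) while
  results are reported in mm; we take the rooted form to match the reported
  units. Index pairing is valid because both representations derive from
  one generic model; unordered point-set distances are out of scope.
* **Organ mass** is reference tissue density × voxelized convex-hull
  volume (voxel centres counted inside the hull, grid anchored at the hull
  bounding box). On convex bodies the estimate refines monotonically; at
  1 mm voxels it is within 2% of the analytic hull volume for the organ
  sizes used here.
* **Mass comparison** sums organ parts (e.g. wall + contents,
  medulla + pelvis + cortex) within each sex, then averages the sexes,
  before differencing phantom − reference.

Historically this class of phantom was validated by comparing two
independent software representations of the same model (a legacy in-house
implementation against its DICOM conversion). Neither representation is
publicly available, so the package's self-consistency analogue compares
its vectorized transform against `scale_phantom_pointwise()`, a second,
independently coded scalar implementation, and demands agreement at
NMSD < 1e−9 mm and volume differences < 1e−9 % across the ten standard
validation ages — an exact-arithmetic bound where two separately
maintained systems could only be expected to agree within a few percent.

## The synthetic fixture

The true generic-phantom coordinates and the growth measurements behind the
scaling tables were never published, so `generate_fixture_phantom()` ships a
stated world with their structural properties, chosen once:

* Adult height 176 cm split upper head 12.6, lower head 12.6, neck 5,
  trunk 60, legs 85.8 cm — an adult-sized, plausible segmentation.
* Newborn (age 0.1) height 55 cm with head (uh + lh) 13.75 cm: head
  fraction exactly 0.25 at age 0.1 and 25.2/176 ≈ 0.143 at 18, matching the
  quarter-to-seventh rule.
* Interior-age y-sizes chosen monotone with resulting total heights
  (75, 96, 109, 138, 167 cm at ages 1, 3, 5, 10, 15) within ~1% of
  50th-percentile population heights; transverse growth fractions are
  slower for the head (closest to adult size at birth) than for trunk and
  limbs, as in real growth data.
* All nine organ groups plus their sub-lobes, with the documented
  low-resolution organs: a 55-point heart, 15-point kidneys, a one-point
  pituitary.
* The seed jitters organ points about regular lattices (clamped inside
  each organ's box); regions and the growth table are deterministic.

What the fixture does *not* emulate: real anatomy (organ shapes are boxes
of points), sex differences, a skeleton, or measurement noise in growth
data. A green test therefore establishes the correctness of the scaling
and transformation *machinery* and the DICOM plumbing — not anatomical
fidelity, and not the numerical values of the original proprietary model.

## Numerical choices

* Boundary equalities (region contiguity, mid-plane alignment) are asserted
  to 1e−9 cm; they hold analytically, so the tolerance only absorbs
  floating-point noise.
* The hull uses a relative degeneracy tolerance of 1e−9 on the coordinate
  scale; sections deduplicate vertices at 1e−9.
* Ages are snapped to tenths with a warning (not rejected), keeping the
  command line forgiving; ages below 0.1 are refused because no growth data
  exists below one month, and the interpolation's lowest knot is 0.1 even
  though the first interval is nominally $[0, 1)$.
* Organ-to-region assignment is explicit in the definition file, not
  inferred by containment, since a grid straddling a boundary would be
  ambiguous.
* Phantom JSON is written at 17 significant digits, which round-trips
  doubles bit-exactly.

## Known limitations

* Cuboid regions and convex organs only; no concave anatomy can be
  represented, and convex hulls of coarse grids underestimate organ volume
  (the historical models' organ masses are known to be much smaller than
  reference-phantom masses for the same reason).
* One orientation (head-first supine); no couch or posture variants, and
  no arms-perpendicular posture.
* Dose calculation is out of scope: only the percent-difference arithmetic
  on externally supplied dose metrics is provided.
* The DICOM codec covers the subset of the standard the package writes;
  it is not a general-purpose DICOM reader.
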