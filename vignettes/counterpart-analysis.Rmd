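---
title: "Horizontal counterpart analysis on 2D and 3D landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Horizontal counterpart analysis on 2D and 3D landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(counterpart3d)
```

## The analysis

Enlow's counterpart analysis evaluates craniofacial balance not against
population norms but within the individual face: each *part* is compared
with the *counterpart* it must structurally match for the profile to be
balanced. The horizontal analysis uses three part/counterpart pairs —
middle cranial floor vs mandibular ramus, maxillary vs mandibular skeletal
arch, and maxillary vs mandibular dento-alveolar arch — scored by the
millimetre-difference method: a part minus counterpart difference between 0
and 2.5 mm (inclusive) is *harmonic*; anything larger is *non-harmonic*.
`counterpart3d` implements this analysis twice, on named landmark
coordinates in millimetres (landmark identification on the images is
upstream of this package):

* **2D** (`analyze2d()`), the classical simplified tracing on
  lateral-cephalogram landmarks. A frame of constructed lines is built
  first: the functional occlusal plane FOP through the posterior and
  anterior occlusal contacts; the reference line Ref parallel to FOP
  through articulare (Ar); the pterygomandibular line PM from the
  sphenoethmoidal junction (SE) to the pterygomaxillary fissure point
  (PTM); the posterior ramus alignment PRa from Ar through the point where
  FOP meets the posterior ramus border; and the anterior ramus alignment
  ARa, parallel to PRa through the lingual tuberosity (LT). All six
  lengths are separations *along Ref*, i.e. absolute differences of scalar
  projections onto Ref's direction, between a landmark (A, SPr, Ar, or the
  orthogonal projections of B and IPr onto Ref) and one of two on-Ref
  anchors: `pm_ref` (PM ∩ Ref, the "neutral PM" point) and `ara_ref`
  (ARa ∩ Ref).

* **3D** (`analyze3d()`), defined directly on CBCT landmarks. The
  landmark set is first oriented into a canonical anatomical frame (x left
  → right, y posterior → anterior, z inferior → superior); three
  measurement planes are then constructed from three rules — through three
  points; through two points and normal (perpendicular) to a reference
  plane; through one point parallel to a reference plane — and every
  length is an unsigned point-to-plane distance: A and SPr to the plane
  through the posterior nasal spine parallel to the coronal plane; B and
  IPr to the plane through the two lingual tuberosities normal to the
  axial plane; basion to the plane through the two anterior clinoid
  processes normal to the axial plane; and each condylion to the
  lingual-tuberosity plane (both rami are always computed; by convention
  the right one enters the MCF–ramus discrepancy).

`discrepancies()` forms the three signed part-minus-counterpart values and
their harmony labels, and `cohort_summary()` reproduces the validation
design: per-index means and SDs of the 2D and 3D discrepancies over a
paired cohort, Kolmogorov–Smirnov normality checks, and paired Student's
*t*-tests of the 2D-vs-3D difference.

## Geometric foundations and numerical choices

All geometry lives in `line_through()`, `line_parallel_through()`,
`intersect_lines()`, `project_point_onto_line()`,
`plane_from_three_points()`, `plane_from_two_points_normal()`,
`plane_parallel_through_point()` and `point_plane_distance()`.

* 2D lines are stored in anchor + unit-direction form, so vertical lines
  (common: the PM line is nearly vertical) need no special casing.
* Three-point plane normals follow the right-hand rule over
  `(p2 − p1) × (p3 − p1)`, so signed distances are reproducible; distances
  are unsigned by default (`signed = TRUE` is a debugging aid for
  anterior/posterior placement errors).
* The two-points-normal construction takes the plane normal as
  `ref_normal × (p2 − p1)`, which contains both points exactly and is
  perpendicular to the reference plane by construction; it is
  underdetermined (and rejected) when the segment is parallel to the
  reference normal.
* Degeneracy tolerances are global and configurable through
  `geometry_tolerance()`: 1e-9 mm for coincident points/containment and
  1e-6 rad for parallel directions. They are deliberately far below
  landmark-identification error (~0.5 mm), so they only catch genuinely
  degenerate constructions, which are reported with the offending landmark
  names.
* All coordinates are handled in mm internally; unit conversion (cm
  reports, image scale factors) is confined to I/O.

### Orientation frame

`build_orientation_frame()` consumes three picked point triplets, one per
CBCT view, on the most external slice of the scan. When the resulting
planes are not exactly mutually orthogonal, the axial normal is honoured
exactly — it anchors both "normal to the axial plane" constructions — the
coronal normal is orthogonalized against it, and the third axis completes
a right-handed basis; triplets whose axial and coronal normals are within
10° of parallel are rejected as a non-orthogonal setup. Triplet point
order fixes each normal's sign by the right-hand rule, making the
transform deterministic. The frame's origin is the common point of the
three (orthogonalized) planes. Because measurement depends on the
orientation only through the axial and coronal plane directions, all
measurements are invariant under rigid motions applied jointly to
landmarks and triplets (verified to 1e-9 mm in the test suite).

### Interpretation choices the tracing literature leaves open

Two readings in the 2D analysis are fixed by this package and documented
here. First, the "neutral PM" anchor of the middle cranial floor is taken
as PM ∩ Ref, since both MCF and ramus are measured along Ref and PM is
the only PM-named construct in the simplified tracing. Second,
mandibular lengths use the ARa ∩ Ref anchor (not the LT projection
directly), following the construction of the anterior ramus alignment.
The constructed gonion is computed and reported as a diagnostic aid but
takes part in no horizontal measurement. Because ramus and corpus
*outlines* are not available to a coordinate-based tool, the two tangent
points feeding gonion and the FOP/posterior-ramus intersection are
required input landmarks rather than derived quantities.

## The synthetic skull generator

`generate_skull()` is the package's test bed, standing in for patient
CBCTs: it emulates skeletal Class I craniofacial landmark configurations
with controllable part/counterpart differences, bilateral asymmetry and
landmark-placement noise. Its design goals, in order: (i) every planted 3D
length is realized *exactly* by the 3D plane constructions; (ii) the
projected 2D landmark set reproduces the same planted lengths exactly, so
2D and 3D discrepancies agree for symmetric noise-free skulls; (iii) the
layout respects typical Class I proportions.

The layout places the PNS plane at y = 0 and builds everything from the
planted lengths: A and SPr at y equal to the maxillary lengths; the
lingual tuberosities at y_LT with B and IPr the mandibular lengths
anterior of them; the clinoid pair at y = 8 with basion `mcf` posterior;
each condylion its ramus length posterior of y_LT. The single coupling
y_LT = ramus_right − mcf makes the 2D frame consistent: the PM line
projects vertically through the PNS plane and both ramus alignments
vertically through LT, so the six 2D along-Ref lengths equal the planted
ones identically. This is also anatomically faithful — in Enlow's scheme
the PM plane passes at the lingual tuberosity's level. Vertical offsets
default to realistic Class I proportions (cranial-base landmarks 2–4 cm
above the palatal plane, articulare ~35–40 mm above the occlusal plane,
symphysis lowest); they are configurable but enter no horizontal
measurement directly.

Remaining knobs, with defaults and rationale:

| knob | default | meaning |
|---|---|---|
| `lengths` | 52/57, 49/52, 34.5/33/33 mm | planted part lengths; default discrepancies (+1.5, −5, −3 mm) sit in the clinically reported range for Class I |
| `halfwidths` | LT 30, clinoid 12, condyle 50 mm | distance of bilateral landmarks from the midsagittal plane |
| `asymmetry` | 0 | x/z offsets of the left member of each bilateral pair; restricted to x/z so planted lengths stay exact |
| `noise_sd` | 0.5 mm | isotropic Gaussian landmark-placement error, applied independently to the 3D set and to the projected 2D set (two independent tracings, as when a cephalogram extracted from the CBCT is traced separately); no published operator-error magnitude exists for this analysis, so 0.5 mm is a documented assumption |
| `length_sd` | 2 mm | between-subject SD of planted lengths in `generate_cohort()` |
| `magnification` | 1 | uniform lateral-projection enlargement; orthographic projection, no perspective model |

The lateral projection drops the mediolateral axis ((x, y, z) → (y, z))
and collapses bilateral pairs to their midpoint — the "averaged shadow"
convention of lateral radiography. The generator verifies its own output
(noise-free layouts must reproduce planted lengths to 1e-6 mm) and raises
a diagnosis-carrying error for configurations that break a construction.

### What passing tests do and do not show

The generator plants landmarks that satisfy the measurement constructions
*exactly*, with Gaussian identification noise on top. Real CBCTs add
everything the template omits: curved anatomy around each landmark (so
"most posterior point" definitions interact with shape), voxel
anisotropy, orientation-picking variability on the external slices,
perspective and soft-tissue effects in real cephalograms rather than
orthographic projections, and systematically different 2D/3D anatomical
definitions (articulare-based vs basion/clinoid-based cranial floor).
Parameter-recovery and invariance results therefore validate the
*implementation* of the constructions, not the clinical equivalence of
the 2D and 3D analyses on patients.

### Statistical behaviour of the replicated cohort design

With the matched template and independent per-modality noise, the
2D-vs-3D difference of each discrepancy index has mean zero up to
second-order noise-propagation terms (≪ 0.1 mm against a
between-subject difference SD of ~1.5 mm), so each paired *t*-test is
essentially an exact-null 5%-level test. Jointly requiring all three
indices of a cohort to stay above α = 0.05 therefore succeeds with
probability ≈ 1 − 3α plus a dependence correction — around 85–90 % of
replicate cohorts, not more, even for a perfectly calibrated method.
Single-cohort conclusions of "no significant 2D/3D difference" replicate
accordingly often, and the package's replicate-cohort summaries should be
read against that analytic baseline rather than against 95 %.

## Cohort sizes and run times

Validation in the test suite and acceptance script uses the study-scale
design directly: cohorts of n = 18 subjects, 100 replicate cohorts for
the replication property, 100 random skulls/rigid motions for recovery
and invariance, and 1000 random instances for the geometry oracle. These
sizes were chosen to keep Monte-Carlo error well below the assertion
margins while the whole suite runs in seconds on one core.

## Known limitations

* Landmark identification is upstream: no DICOM/volume handling, no
  automatic landmark detection, no retromolar-triangle apex detection.
* Only the *horizontal* counterpart analysis is implemented; Enlow's
  vertical counterparts and neutral-track constructs are out of scope.
* The classical KS normality test against a fitted normal is
  anti-conservative because μ and σ are estimated from the sample; the
  Lilliefors correction is available (`ks_normality(..., lilliefors =
  TRUE)`) but off by default, mirroring common clinical-software output.
* No multiple-testing correction is applied across the three indices;
  the three tests are reported individually.
* Voxel-index coordinates must be converted to mm upstream; FCSV files
  are interpreted in their declared RAS/LPS frame, CSV/JSON files in the
  canonical anatomical frame.
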