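---
title: "Geometric methods for automated 2D knee templating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric methods for automated 2D knee templating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneetemplate)
```

## The planning problem

Before a total knee arthroplasty (TKA), the surgical team templates the case
on plain radiographs: they determine the mechanical axes of the femur and
tibia, decide where the bone cuts will run, and choose femoral and tibial
component sizes so that the implants cover the resected surfaces without
overhanging the cortex. `kneetemplate` implements this measurement chain as a
deterministic geometric pipeline operating on calibrated bone contours and
anatomical landmarks — the kind of annotations a segmentation and
landmark-detection front end produces from anteroposterior (AP) and lateral
knee radiographs. Detection itself (segmenting bone from pixels, finding
landmarks, recognising the calibration marker) is deliberately out of scope:
the package starts where those models stop, at geometry.

## Calibration

A radiograph magnifies anatomy by a patient- and setup-dependent factor, so
all measurements are taken in millimetres obtained from a calibration marker
of known physical size: `compute_scale()` turns the marker's two pixel
endpoints and its physical separation into a single isotropic `mm/pixel`
scale, and `calibrate_scene()` converts pixel contours and landmarks into a
millimetre frame with y pointing proximally (raster y grows downward, so the
conversion flips the axis). One scale per image is used; ruler-based
calibration gives no information about anisotropy, and screen distortion
correction is not attempted.

## Coronal (AP) templating

The coronal plan follows the mechanical-alignment school, aiming at a
neutral hip–knee–ankle (HKA) angle:

* the **femoral mechanical axis** (FMA) joins the femoral head centre and the
  trochlear groove, oriented distally;
* the **tibial mechanical axis** (TMA) joins the midpoint of the medial and
  lateral plateau edges to the talar dome centre;
* the **distal femoral resection** is the perpendicular to the FMA placed
  9 mm proximal to the most distal condylar contour point — the fixed
  resection thickness matching the implant in at least one compartment;
* the **tibial resection** is the perpendicular to the TMA placed 10 mm
  distal to the most proximal plateau contour point (medial proximal tibial
  angle, MPTA, of 90°);
* the **insert points** are the outermost intersections of each resection
  line with the bone contour; their distance is the mediolateral (ML) width
  that drives size selection.

Osteoarthritic knees wear asymmetrically — varus knees erode the medial
plateau — so a cut referenced to the intact side can leave the worn side
almost untouched. The pipeline therefore measures the resection depth on
each side as the distance, parallel to the TMA, from the plateau landmark to
the resection line. If the lesser (shallower) side receives less than 2 mm,
the cut is rotated about its intersection with the TMA until the MPTA
becomes 88°, tilting toward the deficient side, and the insert points and
width are recomputed.

Several details are conventions the package had to fix:

* *Rotation pivot.* The 2° rotation pivots on the intersection of the
  original cut with the TMA, keeping the overall resection level anchored to
  the axis.
* *Depth metric.* Resection depth is measured parallel to the mechanical
  axis, matching how resection thickness is checked intraoperatively.
* *Lesser side by comparison.* The deficient side is identified by comparing
  the two depths rather than assuming it is medial, so valgus wear is
  handled symmetrically (the reported MPTA is then 92°, since MPTA is by
  definition the medial angle).
* *Single application.* The realignment is applied once; if 88° still
  leaves less than 2 mm the residual depth is reported rather than iterated,
  so the plan never drifts far from the mechanical-alignment target.
* *More than two crossings.* Concave contours or osteophyte lobes can
  produce more than two intersections; the outermost pair is used because
  insert points represent the cortical borders.
* *Sign conventions.* HKA is reported signed with varus positive, the
  convention used when classifying alignment (varus > 3°, valgus < −3°).

The femoral cut receives no angular adjustment — wear adaptation is a tibial
manoeuvre here — and ties in the furthest-point search are broken by the
lowest vertex index of the (counter-clockwise normalised) contour so results
are deterministic.

## Sagittal (lateral) templating

On the lateral view the femoral component is aligned flush to the **anterior
cortical line** of the distal femur, which avoids notching the anterior
cortex, a known fracture risk. The cortical line is not a landmark; it is
extracted from the contour: points whose offset along the tibial anatomical
axis lies 20–80 mm proximal to the most distal femoral point are resampled,
the anterior-most point of each 2 mm scanline bin is kept (so the posterior
shaft cannot contaminate the fit), and a total-least-squares line is fitted.
The window is configurable; the default brackets the supracondylar shaft on
an adult femur while staying clear of the trochlear flare. The femoral
anteroposterior (AP) length is then the longest perpendicular distance from
that line to the distal femoral contour on its posterior side.

The tibial cut starts perpendicular to the tibial anatomical axis (through
the two shaft landmarks), 10 mm below the most proximal plateau point, and
is rotated about its intersection with the axis so that the posterior end
drops by the posterior tibial slope (PTS), 3° by default. The slope is a
configuration value: 3° reflects a posterior-stabilised design philosophy
and other systems may prefer different values. The AP width is the chord of
the sloped cut between the outermost tibial contour intersections, which on
a flat plateau of depth $d$ equals $d / \cos(\mathrm{PTS})$.

## Size selection and merging

A size chart lists ML and AP dimensions per catalogue size (strictly
increasing in both). `select_size()` picks the **largest size whose
dimension does not exceed the measured width** — a floor rule, because the
governing principle is overhang prevention and rounding up could overhang.
Widths outside the chart clamp to the extreme sizes with `undersized_bone` /
`oversized_bone` flags. The AP and lateral predictions are merged by taking
the **smaller of the two sizes**, again to prevent overhang; `template_knee()`
assembles the whole chain and returns a `tka_template` object with print,
summary and plot methods.

The package ships a synthetic eight-size chart (3 mm steps) that mirrors the
*structure* of a commercial catalogue without reproducing vendor dimensions;
real charts are supplied as CSV/JSON (`read_size_chart()`).

## The synthetic knee generator

Because real radiographs cannot ship with the package, the generator
(`synthetic_knee_truth()`, `generate_ap_scene()`, `generate_lat_scene()`,
`generate_cohort()`) produces paired AP/lateral scenes whose every
measurement station has a closed form, making it the test oracle for the
entire pipeline:

* AP femur: shaft plus two circular condylar arcs (radius 24 mm) with an
  exact vertex at the 9 mm station, so the ML width there is
  $2d + 2\sqrt{r^2 - (r-9)^2}$ by construction;
* AP tibia: plateau with straight metaphyseal walls of fixed flare
  (0.2 mm/mm), so the 10 mm-station width is linear in the parameters; the
  medial plateau corner is lowered by the attrition parameter;
* lateral femur: straight anterior cortex and circular posterior condyle, so
  the AP length is exactly the cortex-to-condyle distance;
* lateral tibia: flat plateau with vertical walls, so the sloped chord is
  $d / \cos(\mathrm{PTS})$ exactly.

Deformity is imposed by rotating the femur about the knee centre so the
femoral head deviates medially by the requested HKA for varus; left knees
are mirrored. Bone widths are derived from a chart entry plus a 1 mm in-bin
margin — inside the 3 mm size bin, so a noiseless measurement recovers the
intended size exactly, while realistic measurement error of a millimetre or
two can move the prediction at most about one size, mirroring how templating
accuracy is reported clinically. Contour noise is uniform along outward
vertex normals (redrawn, continuing the seeded stream, in the rare event a
draw self-intersects); landmark jitter is uniform per coordinate. Cohort
defaults mimic the statistical structure of an osteoarthritic TKA
population — 77.7% varus beyond 3°, 13.7% valgus, the rest neutral; medial
attrition growing with varus severity; mid-catalogue sizes dominating; a
small right-side majority; pixel scales of 0.12–0.18 mm/px — without
claiming anthropometric realism.

What the generator does **not** emulate: osteophytes and irregular cortical
margins, rotated or flexed projections, exposure artefacts, segmentation
failure modes, or correlated (rather than independent) contour errors.
Passing tests on synthetic cohorts therefore demonstrate that the geometry
is implemented correctly and degrades gracefully with annotation error; they
do not certify accuracy on clinical images.

## Evaluation tools

Predictions are compared to implanted sizes with the standard taxonomy:
*exact* (same size), *accurate* (within one size, inclusive of exact), and
otherwise *overestimate*/*underestimate* by sign. Chance-corrected agreement
uses Cohen's kappa with quadratic weights,
$\kappa = 1 - \sum w_{ij} O_{ij} / \sum w_{ij} E_{ij}$ with
$w_{ij} = (i-j)^2/(k-1)^2$, reported together with the conventional
interpretation band (slight/fair/moderate/substantial/almost perfect).

Postoperative verification maps implant points marked on follow-up
radiographs into the preoperative frame with a similarity transform fitted
the way such comparisons are done in practice: scale and translation from
manually marked corresponding points (scale from the rotation-free ratio of
RMS point spreads), rotation by aligning the segmentation masks. The mask
alignment runs a 1° coarse overlap grid over ±20° and then refines with the
difference of the masks' principal-axis orientations (second moments average
over every bone pixel, giving sub-degree precision); near-isotropic masks,
for which the principal axis is ill-defined, fall back to golden-section
refinement of the overlap. Position error compares insertion-point midpoints
(AP femoral/tibial, lateral tibial) and the most-posterior implant point's
offset from the anterior cortical line (lateral femoral); alignment error is
the angle between planned and marked implant baselines.

## Numerical choices

* Intersections deduplicate vertex-grazing crossings within 1e-6 mm; vertex
  side classification uses a 1e-12 cross-product tolerance.
* Polygons are normalised counter-clockwise on construction and checked for
  self-intersection; extremes of linear functionals are searched over
  vertices only (where they must occur), ties to the lowest index.
* Degenerate inputs fail loudly with named errors: coincident axis
  landmarks, zero-area or self-intersecting contours, resection lines that
  miss the bone, empty masks, missing landmarks, charts with non-monotone
  dimensions.
* Mask ingestion takes the largest region's marching-squares boundary at
  level 0.5 (warning when several regions are present) and simplifies it
  with a 0.5 px Douglas–Peucker tolerance.

## Problem sizes

The test-suite and acceptance-script cohort sizes — 200 noiseless knees for
exact recovery, 500 knees at 0.5 mm contour noise and 1 mm landmark jitter
for within-one-size accuracy, an 81-knee cohort for agreement statistics,
1000 random polygons for the geometric oracles, 100 random transforms for
registration recovery — were chosen to estimate rates with a resolution of a
percentage point or better while keeping a full run around a minute on one
core.

## Limitations

The pipeline is strictly two-dimensional and component-size oriented: no
axial rotation profile, no flexion/extension or soft-tissue gap balancing,
no patellar templating, no insert-thickness choice, and no vendor-specific
femorotibial size-compatibility constraints. The lesser-side rule is applied
once rather than iterated, and the anterior-cortex window assumes an adult
femur imaged with the shaft visible at least 80 mm above the joint line.
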