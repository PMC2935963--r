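---
title: "Methods: shape-sensitive cortical bone analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape-sensitive cortical bone analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqctshape)
```

## The measurement problem

A pQCT slice of a long-bone shaft shows a dense cortical ring around a
low-attenuation medullary cavity. Vendor geometry output reduces this ring
to a circular tube of equal area, which is exact only when the bone really
is circular; a tibia — roughly triangular at mid-shaft — is not.
`pqctshape` measures the ring as it is: segment, trace both boundaries,
and quantify diameters, circumferences, directional thicknesses and the
deviation of the section from an ideal circle and ellipse.

The pipeline is deterministic: the same image, configuration and seed
always give the same row of numbers.

## Coordinate conventions

* Pixel (row *r*, col *c*), 1-based, has its center at
  ((*c* − ½)·*v*, (*r* − ½)·*v*) mm, with *v* the voxel size. x grows
  rightward with columns, y grows **downward** with rows.
* Contours are closed polygons over boundary **pixel centers** (no
  subpixel interpolation), oriented counter-clockwise on screen. Pixel
  centers keep the chain-code perimeter definition unambiguous — every
  step is *v* or *v*·√2.
* The maximum-diameter angle is measured from the image vertical in
  [0°, 180°); the fitted-ellipse orientation from the +x axis in
  [0°, 180°). Image-top is taken as anterior, reflecting conventional
  patient positioning; both conventions are configurable in spirit (the
  relevant outputs carry enough information to re-derive either).
* Raw files are headerless row-major unsigned 16-bit; byte order defaults
  to little-endian (the scanner's PC platform) and is configurable
  because exports in the wild differ. The stated scan geometry of
  "2.02 pixels per mm" alongside a 0.5 mm voxel is treated as a rounding
  artifact of the export dialog: the voxel size alone defines physical
  scale, and a true 0.495 mm voxel is representable by setting it.

## Segmentation model

A pixel is bone when its value is at or above the threshold; "similar
intensity" in the flooding step is exactly this single-threshold
criterion, which matches the original tool's one threshold slider.
Threshold default 450 scanner units, range 200–1000 (outside values need
an explicit override): 450 is the published operating point that
deliberately includes the dense endosteal trabeculization visible in a
third of scans.

Foreground uses 8-connectivity and background (hole) 4-connectivity — the
standard digital-topology pairing that prevents the ring and its cavity
from leaking into each other through diagonal gaps. Cleanup is
morphological opening with a 3 × 3 cross, one pass by default; the
original description says only "erosion and dilation", so equal counts
(a true opening) and the smallest isotropic-ish element are assumed and
configurable. Opening is idempotent, which gives the pipeline its
re-analysis stability.

The interactive crosshair is replaced by explicit `(row, col)` seeds or,
for batch work, an automatic seed at the brightest pixel of the largest
above-threshold component: reproducibility over interactivity. A flooded
component that touches the image border, or that encloses no cavity,
raises an error naming the stage — the original program "usually failed"
silently on movement artifacts; this implementation fails loudly on the
same inputs (the phantom generator's streak reproduces exactly this
failure). When several enclosed holes each exceed 5% of the total hole
area a warning is raised and the largest is used.

## Shape metrics

* **Centroid**: unweighted mean of cortical pixel centers. The original
  description says "center of mass" without specifying density weighting;
  the binary centroid is chosen as the default because exported raw units
  are uncalibrated, and a weighted variant is available through
  `mask_centroid(weights = ...)`.
* **Maximum diameter**: exact maximum pairwise distance, computed on the
  convex hull (where the maximum always lies; verified against the
  all-pairs scan in the tests). Ties — common on symmetric digitized
  shapes — break toward the endpoint pair least in (y, x) order, making
  results deterministic.
* **Minimum diameter**: width of the orthogonal projection perpendicular
  to the maximum axis, not a chord: a chord through the centroid can exit
  and re-enter a concave tibial section, while the projection width is
  robust. The chord variant exists behind
  `analysis_config(min_diameter_chord = TRUE)`.
* **Thickness profile**: for each periosteal vertex, the shortest
  distance to the endosteal polygon (point-to-segment). The direction is
  periosteal → endosteal, fixed by the method's phrasing; no symmetric
  Hausdorff variant is used.
* **Directional thickness**: the maximum-diameter line is cast through
  the centroid; on each side the thickness is the gap between the
  outermost periosteal and endosteal crossings. Anterior is the
  smaller-y (image-top) side; left the smaller-x side. Whether the
  original plugin used the centroid line or the diameter endpoints is
  unknowable from its description; the centroid line is chosen because it
  is defined for every ring, and the choice is isolated in one function.
  Left/right values are computed but ordered last, mirroring the
  convention of reporting anterior, posterior, minimum and mean only.
* **Areas**: `contour_area()` is the raw shoelace area. The reported
  `tot_csa` / `cort_csa` use the digitally corrected area
  shoelace + (B/2 + 1)·v² (B = boundary vertex count), which by Pick's
  theorem equals the exact pixel count of the enclosed digital region.
  The correction matters: the center polygon alone cuts off the
  half-pixel rim, a systematic −3% at tibial sizes, while pixel counting
  is what the reference method for total CSA does.

### Digital perimeter bias

Chain-code perimeters of smooth shapes carry a positive bias of a few
percent (the traced polygon zig-zags along the digitization), and the
bias does **not** vanish with voxel size — it is a property of the
estimator, documented here rather than hidden: on the standard circular
phantom the periosteal circumference reads ≈ +3.4% over 2πR at
v = 0.5 mm. Diameters, areas and thicknesses converge to truth as v
shrinks; the tests assert monotone convergence of their aggregate error
over v ∈ {1, 0.5, 0.25} mm.

## Conic fits and the two error metrics

The circle fit minimises the algebraic residual Σ(x² + y² + Dx + Ey + F)²
— linear, exact for circular data. The ellipse fit is the direct
least-squares method with the ellipse-specificity constraint
4ac − b² = 1, solved via the scatter-matrix partitioning that avoids the
classical formulation's singular 6 × 6 eigenproblem; points are centered
on their mean first and the conic un-shifted afterwards, keeping the
design matrix conditioned for contours far from the origin. Exact
recovery on noiseless conics (to 1e−6) and rotation/translation
equivariance are asserted in the tests.

Two deviation metrics are reported per conic. The circle error is
geometric: mean squared radial deviation, in mm². The ellipse error is
the mean squared algebraic residual of the normalised conic. Published
magnitudes for the two quantities (circle ≈ 0.05 mm², ellipse ≈ 10–12 on
tibiae) cannot arise from one common metric — an ellipse fits any section
at least as well as a circle — so the self-consistent reading is exactly
this two-metric one, and both algebraic and geometric (Sampson) variants
of each are emitted so either convention can be reproduced downstream.

## Ring model

From filled area A and cortical area C: R = √(A/π), r = √((A−C)/π),
reported as 2πR, 2πr and R − r. No vendor formula is printed anywhere
public; these equal-area equations are the standard reconstruction and
are labelled as such. Two properties anchor them: they agree with the
shape pipeline on circular phantoms (tested at 5% discretization
tolerance), and they strictly underestimate the true periosteal
circumference on any non-circular section (the circle minimises perimeter
at fixed area) — the direction of the 23–27% discrepancy reported when
the two approaches were compared on real tibiae.

## Cohort statistics

Outcomes are transformed to natural logarithms; the group difference is
100 × the group coefficient of an OLS fit of ln(y) on group (+ optional
age/height/weight), the *sympercent*: symmetric, multiplicative, and
exactly 100·ln(c) for an exact ratio c. Stars at 0.05/0.01/0.001 with no
multiple-testing correction, matching the analysis style the package
mirrors; descriptive blocks use medians and IQRs with the
lower-interpolation convention (`quantile(type = 1)`). Agreement between
methods is plain Pearson r plus y-on-x OLS with standard errors. Standard
OLS conventions are assumed throughout (the historical analyses ran in a
desktop statistics package whose exact SE conventions are undocumented).

`simulate_cohort()` generates log-normal outcomes with specified true
sympercent effects over 38 + 38 subjects (the mirrored study size),
uniform age 24–36 y and normal height/weight sized like the study
populations; recovery within 3 simulation SEs is a test, not an
assumption.

## The phantom generator

Phantoms emulate what the analysis needs from a scan — a dense ring
(800 units, well above threshold) on a low background (50), optional
endosteal speckle ("trabeculization", a seeded random fraction of a band
inside the cavity), Gaussian noise, and a full-width bright streak
standing in for movement artifacts (3 px tall so a single opening pass
cannot erase it). Ground truth is closed-form for circles, Ramanujan's
second approximation for elliptical perimeters (exact to far below
discretization error at these axis ratios), and dense 4096-point
numerical evaluation of the generating curves for the tibia-like shape —
a rounded-triangle cosine perturbation ρ(θ) = R(1 + 0.12·cos 3θ +
0.05·cos 2θ) sized to a young-adult mid-shaft tibia (max diameter
26–28 mm, mean thickness 4–5 mm).

For an eccentric cavity the directional-thickness truth is subtle: the
left/right line runs through the *ring* centroid, which sits opposite the
displaced hole by off·r²/(R² − r²), so those truths are evaluated on the
dense generating curves rather than by the naive R − r ± offset formula
(which stays valid for the anterior/posterior line through both centers).

What phantoms do **not** emulate: beam hardening, reconstruction kernels,
partial-volume gradients at the cortical edge, or genuinely trabecular
texture. Passing the phantom suite therefore demonstrates the geometry
engine is correct on known shapes; it does not by itself validate
biological accuracy on scanner data, which is what the overlay rendering
(`render_overlay()`, `autoplot()`) is for — per-scan visual QC.

## Problem sizes and runtime

Tests and examples run phantoms at 128 × 128 × 0.5 mm (64 mm field, the
standard shapes fit with wide margin), with the convergence study at
64/128/256 pixels for v = 1/0.5/0.25 mm. These sizes keep the full suite
under a minute while leaving every ratio (ring thickness in voxels,
boundary length) in the regime of real 283 × 283 scans; analysing a full
283 × 283 export takes well under a second.

## Known limitations

* Chain-code circumferences carry the documented +few-percent bias;
  compare like with like (the ring-model columns are bias-free but
  model-bound).
* Single-threshold flooding cannot separate cortex from dense
  trabecularised bone — by design, matching the published operating
  point; lowering the threshold grows the "cortex" accordingly.
* The anterior/left labels assume standard positioning; a rotated limb
  rotates the labels with it (the axis angle column records the
  rotation).
* No densitometry: raw exported units are uncalibrated, so BMC/BMD/SSI
  are out of scope.
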