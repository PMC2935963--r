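# pqctshape

Shape-sensitive analysis of cortical bone cross-sections from peripheral
quantitative computed tomography (pQCT).

Standard pQCT vendor software summarises the geometry of a long-bone shaft
with a *circular ring model*: it converts the total and cortical
cross-sectional areas into area-equivalent radii and reports the resulting
circumferences and mean thickness, as if the bone were a circular tube. Real
tibiae are nowhere near circular, and the interesting biology — where the
cortex is thick, how far the section departs from a circle or an ellipse —
is invisible to that model. `pqctshape` is for researchers analysing raw
pQCT cross-section exports who want the actual shape: it segments the
cortical ring from the raw 16-bit image, traces the periosteal and
endosteal boundaries, and quantifies the section's geometry and its
deviation from ideal conics, alongside the ring-model numbers for
comparison and the log-scale (sympercent) statistics used to compare
cohorts.

## What it computes

Given a raw scan (by default 283 × 283 pixels of unsigned 16-bit
attenuation, 0.5 mm voxel):

1. **Segmentation** — threshold at *T* (default 450, adjustable 200–1000),
   seeded flood fill (8-connected) from a crosshair-style seed or an
   automatic seed, morphological opening (3 × 3 cross) to strip noise, then
   Moore-neighbour boundary tracing of the outer component and of the
   enclosed medullary cavity. Scans whose cortex does not close into a
   ring — the classic movement-artifact signature — are rejected loudly.
2. **Shape metrics** — centroid; maximum diameter
   `max_{p,q ∈ ∂P} ‖p − q‖` and its angle from the image vertical; minimum
   diameter (projection width at right angles to the maximum axis);
   periosteal and endosteal circumferences (chain-code perimeter);
   anterior/posterior/left/right cortical thickness along the
   maximum-diameter axis through the centroid; the min/max/mean of the
   point-to-boundary thickness profile; total and cortical cross-sectional
   area (digitally corrected polygon area, equal to the pixel count by
   Pick's theorem).
3. **Conic deviation** — an algebraic least-squares circle fit and the
   direct least-squares ellipse fit under the constraint `4ac − b² = 1`
   (Fitzgibbon's method in its numerically stabilised scatter-partitioned
   form). `Av E Circ` is the mean squared radial deviation from the fitted
   circle (mm²); `Av E Ellip` is the mean squared normalised algebraic
   residual of the fitted conic. A perfectly circular (elliptical) section
   scores exactly 0.
4. **Ring model** — `R = √(A/π)`, `r = √((A−C)/π)` from the filled and
   cortical areas, reported as `2πR`, `2πr`, `R − r`; exact for circular
   rings, an underestimate of the true circumference otherwise
   (isoperimetric inequality).
5. **Cohort statistics** — sympercent group differences
   (`100 ×` the group coefficient of an OLS fit of `ln(outcome)` on group +
   covariates), agreement regressions between methods, and a
   median/IQR comparison table with significance stars.
6. **Phantoms** — circular, eccentric, elliptical and tibia-like annular
   phantoms with analytic ground truth for every metric, used throughout
   the test-suite and available for your own validation.

## Worked example

Build a noisy circular-annulus phantom (outer radius 13 mm, inner 9 mm,
0.5 mm voxel) and analyse it:

```r
library(pqctshape)

ph  <- build_phantom(phantom_spec(outer = 13, inner = 9, noise_sd = 30, seed = 2),
                     image_geometry(128, 128, 0.5))
res <- analyze_scan(ph$image, analysis_config(width = 128, height = 128))
```

Selected columns of the one-row result (a tibble):

```
  max_diam_mm min_diam_mm peri_circ_mm endo_circ_mm thk_mean_mm tot_csa_mm2
1      25.933      25.933       84.426       58.284       3.935         532
  cort_csa_mm2 err_circle_mm2 err_ellipse_alg peri_circ_ring_mm endo_circ_ring_mm
1          277          0.013           2.101            81.764            56.608
```

Reading: the true diameter is 26 mm and the pipeline reports 25.93; total
and cortical areas (truth 530.9 and 276.5 mm²) come back within 0.3%; the
digital (chain-code) circumferences carry their documented upward bias of
a few percent over 2π·13 = 81.68 and 2π·9 = 56.55 mm, while the ring-model
columns — exact for this circular phantom — sit on the analytic values.
`err_circle_mm2` is small because the section *is* a circle up to
pixelation; on a tibia-like phantom it rises a hundred-fold. An overlay
PNG for visual quality control comes from
`render_overlay(ph$image, res, "overlay.png")`, and `autoplot(res)` gives
the same picture as a ggplot.

Cohort comparison on a simulated two-group table (38 subjects per group):

```r
d <- simulate_cohort(n_per_group = 38,
                     effects  = c(endo_circ = 9.9, thk_mean = -26.5),
                     baseline = c(endo_circ = 49.5, thk_mean = 5.36),
                     sigma = 0.08, seed = 1)
compare_cohorts(d, c("endo_circ", "thk_mean"))
```

```
    outcome median_1 median_0 pct_diff pct_diff_stars pct_diff_adj
1 endo_circ    55.25    48.85     10.0            ***         9.78
2  thk_mean     4.14     5.34    -26.1            ***       -25.93
```

The true simulated effects (+9.9% and −26.5% on the sympercent scale) are
recovered within simulation error, with and without age/height/weight
adjustment.

## Command line

A thin driver ships in `inst/cli/pqctshape`:

```sh
pqctshape analyze scan.raw --threshold 450 --voxel 0.5 --auto-seed --out r.csv
pqctshape phantom --out-raw ph.raw --out-truth truth.json
pqctshape batch manifest.csv --out results.csv
pqctshape compare cohort.csv --outcomes peri_circ,endo_circ
```

Exit codes: 0 success, 1 analysis failure (stage-named message), 2 bad
arguments.

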