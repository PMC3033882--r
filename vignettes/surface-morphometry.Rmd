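---
title: "Single-subject lesion detection with surface-based morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject lesion detection with surface-based morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(surfmorph)
```

## The detection problem

Focal cortical malformations — focal cortical dysplasia above all — are a
leading cause of medically intractable epilepsy, yet a large fraction escape
visual MRI reading. Two of their imaging signatures are quantifiable on a
reconstructed cortical surface: focal thickening of the cortical ribbon and
blurring of the gray–white junction, the latter visible as a gray/white
intensity contrast that drifts toward zero. surfmorph implements an
automated, single-subject detection framework built on these signatures:

1. every subject's per-vertex measures live on a shared template mesh with
   vertex correspondence (established upstream by spherical registration,
   which is out of scope here);
2. measures are smoothed on the surface with a kernel of known FWHM;
3. a normative model (per-vertex mean and SD over a healthy control cohort)
   turns a single patient's overlay into a z-map,
   $z_v = (x_v - \mu_v)/\sigma_v$;
4. supra-threshold vertices are grouped into edge-connected clusters and
   small clusters are discarded (extent correction);
5. a patient counts as detected when a cluster touches the traced lesion;
   a control scored by leave-one-out counts as a false positive when it
   shows any cluster at all.

Everything downstream of these maps — sensitivity/specificity,
threshold-by-smoothing sweeps, ROC/AUC, area-based coverage, electrode
classification — is in the `evaluation` functions.

## Morphometric measures

**Thickness.** At each vertex, the average of the shortest distance from
the white-surface vertex to the pial surface and the shortest distance from
the corresponding pial vertex back to the white surface. These are true
point-to-triangle distances: `compute_thickness()` finds candidate
triangles around the nearest target vertices and minimizes the exact
point-triangle distance, so the value does not depend on the target mesh's
vertex sampling. On concentric spheres 2 mm apart the estimate is within
2% of the closed form.

**Gray/white contrast (GWC).** $(I_g - I_w)/(I_g + I_w)$, with $I_g$ and
$I_w$ sampled by trilinear interpolation 0.5 mm above and below the
gray/white interface along the vertex normal
(`sample_volume_at_offset()`). With white matter brighter than gray on
T1-like contrast, values lie in $(-1, 0)$; values nearer zero mean a more
blurred junction, so *positive* z deviations indicate blurring. The ratio
is invariant under global intensity rescaling, which is why no intensity
normalization is attempted.

**Mean curvature.** The cotangent-Laplacian mean-curvature normal with
mixed Voronoi vertex areas, signed so convex-outward is positive. The
Voronoi mass (rather than the barycentric one used for `vertex_areas()`)
is what makes the sphere limit $1/R$ hold to a fraction of a percent even
at the twelve irregular valence-5 vertices of an icosphere; with
barycentric masses the error there exceeds 10%.

Local gyrification, sulcal depth and jacobian distance are consumed as
precomputed overlays only; they depend on surface inflation and spherical
registration, which this package deliberately does not reimplement.

## Smoothing and its calibration

The literature specifies surface smoothing only by its FWHM (5, 9 or
12 mm are the conventional levels), not by an algorithm. surfmorph makes
FWHM the contract: smoothing is iterated explicit diffusion
$x \leftarrow x + \Delta t\, A^{-1} (W - D)\, x$ on the edge graph, with
barycentric vertex areas $A$ as the mass matrix, unit edge weights, and
$\Delta t = 0.9 \min_i(A_i/\mathrm{deg}_i)$. Two properties are exact by
construction: the symmetric stiffness $(W - D)$ conserves the
area-weighted mean, and the $\Delta t$ bound makes every step a convex
combination of one-ring values (maximum principle). The iteration count
for a requested FWHM is found by placing a unit impulse at the vertex
nearest the mesh centroid, iterating, and measuring the full width at half
maximum of the binned radial profile (linear interpolation of the
half-maximum crossing); the smallest count reaching the target is cached
per mesh. On a 1 mm planar grid the achieved FWHM is within a few percent
of request at all three conventional levels; the contract tested is 15%.
A kernel narrower than the local mesh resolution cannot be represented, so
any positive FWHM applies at least one diffusion step.

## Normative modelling and clusters

`fit_normative()` uses the unbiased ($n-1$) SD and floors it at
$10^{-6}\times$ the cohort's median positive SD — vertices where a finite
cohort happens to be constant would otherwise produce infinite z. Controls
are scored by strict leave-one-out (`loo_zscores()`), so no subject's data
ever enters its own reference model.

`extract_clusters()` defaults to two-sided detection with the sign of each
cluster recorded: the clinical spectrum includes both thickening (dysplasia)
and thinning (encephalomalacia), and blurring pushes GWC *up* toward zero.
Positive and negative excursions are clustered separately and never merge
across an adjacent sign change. Extent correction defaults to a fixed
30 mm² minimum cluster area; where a data-driven criterion is preferred,
`mc_cluster_extent_null()` estimates the 95th percentile of the maximum
cluster area under smoothed Gaussian noise on the same mesh.

## Geodesic distances

Geodesics (lesion radii, electrode footprints, adjacency bands) are
shortest paths by Dijkstra on the edge graph augmented with the
straight-line "flip diagonal" chord across every interior edge. Pure
edge-graph Dijkstra overestimates distances by up to ~15% in directions
between edge orientations, which would bias geodesic disc areas low by
nearly 10%; the chord augmentation brings disc areas on an icosphere to
within a few percent of the spherical-cap closed form while staying
deterministic and dependency-light. Exact polyhedral geodesics are a
non-goal.

## The synthetic cohort

`simulate_cohort()` emulates the statistical structure the detector
assumes: per subject and measure, overlay = mean + SD × a unit-variance
spatially correlated Gaussian field, obtained by smoothing white noise to
a 10 mm correlation FWHM and re-standardizing each vertex by the exact
per-vertex SD of the smoothed operator (its row norms). Defaults are a
41-hemisphere control cohort on a subdivision-4 icosphere of 50 mm radius
(2562 vertices, ~3.3 mm edge length — enough to resolve a 10 mm lesion
while keeping a full 40-replicate recovery study in a few minutes on one
CPU); thickness-like overlays of 2.5 ± 0.3 mm; GWC-like overlays of
−0.25 ± 0.03. Lesions are geodesic discs of 10 mm radius with the effect
expressed in SD units (default 6 SD) and a cosine taper over the outer 20%
of the radius so cluster boundaries are not artificially crisp; a
`delta = 0` patient is a "null patient" whose true label is still recorded.
Lesion centers are seeded draws excluding vertices within two radii of a
previous lesion.

What the generator does *not* emulate: folded cortical geometry, regional
mean/SD structure, registration error, age effects, or T1 volumes (GWC
overlays are simulated directly; volume sampling is validated separately
on analytic volumes). Passing recovery tests therefore demonstrate the
statistical machinery, not performance on real MRI.

Because a null patient is statistically a control, the honest null
comparison is its *any-cluster* rate against the leave-one-out control
false-positive rate; overlap with its (empty-effect) label would compare
two different events.

## Numerical and design choices

- **Vertex areas**: barycentric one-third rule; robust on obtuse triangles
  and an exact partition of the total area.
- **Nearest-vertex ties** (voxel projection) break to the lowest index;
  cluster sorting ties break to the lowest member vertex.
- **Morphological closing** of projected labels defaults to one ring,
  matching the sub-voxel pinholes it is meant to fill; the radius is a
  parameter because no canonical value exists.
- **ROC curves** are built from the threshold sweep (one operating point
  per threshold), anchored at (0,0) and (1,1), ties in false-positive rate
  resolved by the maximum sensitivity, AUC by trapezoid.
- **Percentages** are reported to one decimal, rounding half away from
  zero.
- **Missing values** (`NA`) propagate: excluded from smoothing averages and
  re-flagged, flagged in z-maps, never counted in clusters.
- **Determinism**: every stochastic routine takes its randomness from the
  R RNG; pipelines funnel a single named seed, and identical config + seed
  reproduce outputs byte-for-byte.

## Worked example

```{r, eval = FALSE}
cfg <- cohort_config(seed = 7)        # 41 controls, 1 patient, 6 SD lesion
co <- simulate_cohort(cfg)
ctl <- vapply(seq_len(ncol(co$controls$thickness)), function(i)
  as.numeric(smooth_overlay(co$mesh, co$controls$thickness[, i], 5)),
  numeric(n_vertices(co$mesh)))
attr(ctl, "measure") <- "thickness"
model <- fit_normative(ctl, fwhm = 5)
pat <- smooth_overlay(co$mesh, co$patients$thickness[, 1], 5)
zmap <- zscore_subject(model, pat, "patient_001")
clusters <- extract_clusters(co$mesh, zmap, threshold = 4)
categorical_detection(clusters, co$labels[[1]])
lesion_coverage_metrics(co$mesh, clusters, co$labels[[1]])
```

The same flow, plus the sweep and reporting, is available as a one-call
pipeline (`run_pipeline()`) driven by a YAML config, and as the thin
`surfmorph` command-line script under `inst/cli/`.

## Known limitations

- Vertex correspondence across subjects is assumed, never computed.
- Dijkstra-with-chords geodesics are approximate (a few percent).
- The extent correction is an area criterion (fixed or Monte-Carlo), not a
  random-field-theory p-value.
- No covariate adjustment (age, sex); the normative model is a plain
  per-vertex Gaussian.
- Synthetic validation speaks to the statistics, not to segmentation or
  registration quality on real data.
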