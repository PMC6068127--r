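---
title: "QCT-based finite element analysis of the proximal tibia: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QCT-based finite element analysis of the proximal tibia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tibiamech builds subject-specific linear-elastic finite element (FE) models
of the knee from calibrated quantitative CT (QCT) density volumes and
derives regional mechanical metrics of the proximal tibia: minimum principal
(most compressive) and von Mises stress and strain in seventeen anatomical
regions, and the structural stiffness of the medial and lateral compartments.
On top of the per-knee pipeline it implements a short-term precision study
(repeat scans, CV%RMS) and an OA-vs-normal group comparison with a
skewness/kurtosis normality gate, exact Mann-Whitney tests, Hodges-Lehmann
confidence intervals and Cohen's *d* effect sizes.

This vignette documents the model, its assumptions, the tunable parameters,
and the design decisions made where the procedure was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The synthetic knee phantom

No patient CT volumes ship with the package; every stage is exercised
against a parametric knee phantom (`generate_knee_phantom()`) with
voxel-exact ground truth. The phantom emulates the acquisition conditions of
an in-vivo knee QCT precision protocol:

* proximal tibia, distal femur and fibula built from stacked superellipse
  cross-sections, with an intercondylar spine ridge on the tibial plateau
  and two femoral condylar lobes merging into a shaft;
* a dense cortical shell (default 3 mm, `cortical_shell_mm`; must span at
  least two voxels or the spec is rejected) around a smoothly varying
  trabecular interior whose density decays with depth below the joint
  surface (subchondral trabecular ~300 mg/cm^3 falling to ~150 mg/cm^3 in
  the metaphysis, cortical ~950 mg/cm^3, all +-8% smooth spatial noise);
* a soft-tissue limb, an air background, and three calibration rods
  (0/200/400 mg/cm^3 K2HPO4-equivalent) in a slab below the limb, mirroring
  a solid in-scan calibration phantom;
* the generative HU-density line is density = 0.8 HU - 4; the image is
  blurred (sigma 0.7 voxel) and carries 4 HU white noise, so the
  half-maximum-height rule sees realistic partial-volume edges;
* group conditions: OA knees default to body mass 101 kg (drawn 101 +- 16 kg
  in cohorts), 175 degree varus alignment and a 1.15 medial density
  multiplier; normal knees to 72 kg (72 +- 13 kg), 179 degrees and no
  density elevation. The medial density multiplier is a free parameter of
  the phantom: the motivating in-vivo data showed only a non-significant
  BMD trend, so 1.15 was chosen once as a plausibly detectable elevation
  and not revisited.
* with both axis unit vectors pointing superiorly, a varus angle `v` is
  realised as an inter-axis angle of `180 - v` degrees placed symmetrically
  about the vertical.

Repeat scans (`generate_repeat_scans()`) apply an independent 6-DOF rigid
repositioning (Gaussian translations/rotations, defaults 1 mm / 1 degree
SD) plus additive Gaussian intensity noise (default 5 HU), with per-repeat
RNG streams derived from the master seed by counter. What the phantom does
*not* emulate: CT physics (beam hardening, scatter, kernel-dependent PSF),
cartilage and menisci, osteophytes and cysts, and anatomical shape
variability beyond its parametric family. Passing tests therefore
demonstrate the correctness and stability of the *pipeline*, not clinical
performance on real scans.

## Image processing

**Calibration.** Rod voxel sets (known geometry, transformed by the recorded
repeat-scan rigid transform, eroded radially by 40% to avoid partial-volume
rims) give mean HU per rod; ordinary least squares of nominal density on
mean HU maps the volume to mg/cm^3. A non-positive slope, coincident rod
intensities, or calibrating an already calibrated volume are errors.

**Half-maximum-height (HMH) threshold.** The bone threshold is the midpoint
between the cortical peak level and the adjacent background level, each a
median over a probe region. `auto_probe_regions()` automates the operator
step: cortical probe = top 0.2% intensities, background probe = soft-tissue
band (above air, below 30% of the cortical level); manual probes can be
passed directly. The rule is equivariant under affine intensity maps.

**Segmentation.** Voxels at or above the threshold are labelled by
26-connected components (Rcpp); components are assigned to bones by seed
points (a seed in sub-threshold trabecular interior is resolved by an
expanding search up to 24 mm), and enclosed sub-threshold cavities — the
trabecular interior — are filled by border flood-fill on the complement.

**Axes and re-alignment.** The tibial axis is a best-fit line (first
principal direction) through cross-section centroids at the distal end of
the imaged extent, midshaft, 66% and a proximal level; the femoral axis
uses 32 cross-sections starting at 65% of the imaged femoral extent and
spanning 20 mm. Slices through the oblique distal cut face, the tilted
plateau surface, or the condylar lobes are avoided: horizontal slices
through those features have laterally biased centroids (on a short imaged
segment this bias can reach several degrees). The re-alignment rotation
maps the normalised average of the two axes onto the vertical, so both axes
make equal angles with the vertical — half the supplement of the inter-axis
angle (175 degrees -> 2.5 degrees each). The in-plane twist, which the
averaged-axis rule leaves free, is fixed by aligning the mediolateral
direction with +x, making medial/lateral splits deterministic. Density is
resampled trilinearly, labels by nearest neighbour. Left knees are mirrored
at load time so +x is always medial.

## Meshing and materials

The default mesh mode is `hex_voxel`: a structured grid of 8-node hexahedra
(default 2 mm) anchored at the mask bounding box; a cell becomes an element
when a strict majority of a 3x3x3 sub-cell lattice falls in bone (odd count:
no ties, unbiased volume). A soft-tissue cylinder (radius 1.1x the
mediolateral half-extent, spanning 5 mm below to 27 mm above the plateau)
fills non-bone cells on the same grid, so bone/soft-tissue interfaces share
nodes (bonded). Isolated femur cells that touch tibia cells only at
stair-step corners across the joint gap are demoted to soft tissue; a
substantial shared-node count means the gap truly closed and is an error.
`tet_quadratic` subdivides each hexahedron into six 10-node tetrahedra
(conforming Freudenthal split, shared midside nodes) for the quadratic
element formulation and Abaqus INP interchange; in this mode the soft
tissue shares the bone grid rather than being meshed coarser.

Before meshing, the model is cropped to 50 mm below / 28 mm above the
plateau (`crop_to_joint()`, `model_distal_mm` / `model_proximal_mm`). The
regional analysis reaches only 35 mm below the plateau and the femur acts
as a rigid load introducer, so more distal shaft adds degrees of freedom
without affecting the regional fields; the crop planes become the
constraint surfaces.

Per-element density is the mean of the calibrated volume at the element's
integration points; elastic modulus follows the power law
`E = max(floor, coeff_a * (rho/1000)^2.1)` with `E` in MPa and `rho` in
mg/cm^3. The 2.1 exponent is the published density-modulus relation for
proximal-tibial bone; `coeff_a` (default 12000 MPa at 1 g/cm^3) is a
documented configuration value chosen to keep peak cortical moduli in the
tens-of-GPa range — substitute the coefficient of whichever calibration
matches your density measure (`density_pretransform` provides an optional
linear density map, default identity). Bone has nu = 0.3; soft tissue is
overridden to E = 10 MPa, nu = 0.495 (incompressible-like); the distal
femur to a stiff elastic rigid surrogate E = 500 GPa. A single
density-modulus law serves both cortical and trabecular bone.

## Solver

Standard isoparametric elements: 8-node hexahedra with 2x2x2 Gauss
quadrature and mean-dilatation B-bar treatment of the volumetric strain
(without it the nu = 0.495 soft tissue locks volumetrically), and 10-node
tetrahedra with the 4-point rule. Boundary conditions reproduce single-leg
stance: the femoral top surface is fixed transversally and driven 1 mm
axially downward; the most distal tibia and fibula node sets are fully
fixed. The sparse symmetric system is solved by supernodal Cholesky
factorisation (CHOLMOD via Matrix; the supernodal, BLAS-backed variant is
selected explicitly — it is an order of magnitude faster than the
simplicial default on these 3D patterns). Element stress/strain tensors are
evaluated at centroids; minimum principal values come from a closed-form
symmetric 3x3 eigensolver, the von Mises stress from the usual deviatoric
invariant, and the equivalent strain uses the (2/3)-normalised convention,
which reduces to `(2/3)(1+nu)|eps_axial|` under uniaxial stress and to the
axial strain for an incompressible material (the source procedure never
defines its strain equivalent; this choice is recorded here). Because the
model is linear, fields are rescaled post hoc so the femoral vertical
reaction equals one body weight (`body_mass * 9.81`). Reported quantities
are element/nodal field values; equilibrium (top vs distal reactions) is
verified to 1e-6 relative and the linear-solve residual to 1e-8.

## Regions and regional metrics

Two depth measures drive the seventeen-region partition: the 3D Euclidean
distance transform from the tibial outer surface, and the vertical depth
below the local plateau top surface. Plateau/spine columns are banded by
vertical depth — 0-2.5 mm subchondral cortical, 2.5-5 subchondral
trabecular, 5-15 epiphyseal, 15-35 metaphyseal — with half-open bands
[lo, hi), the deepest closed at 35 mm, so counts are deterministic. The
outer cortical wall (EDT depth < 5 mm and clearly nearer the side surface
than the plateau) is peripheral cortical in the top 5 mm axial zone and
epiphyseal/metaphyseal cortical (surface depth < 2.5 mm) in the 5-15 /
15-35 mm axial extents. Sectors come from the sagittal split plane through
the plateau footprint median and a central slab of 20% of the mediolateral
extent (configurable); the central sector maps to subchondral spine
(0-5 mm, the two subchondral bands merged), epiphyseal central and
metaphyseal central.

Regional values are reported through fixed voxel probes
(`voxel_region_map()` + `probe_regional_metrics()`): regions are assigned
once on the image grid, element fields are projected to nodes by
volume-weighted averaging over tibia elements (standard FE nodal recovery)
and interpolated trilinearly at the probe voxels. Because the probe set is
mesh-independent, values from meshes of different element size are directly
comparable. The element-level `assign_regions()` /
`aggregate_regional_metrics()` path (volume-weighted element means) is also
provided and is the natural companion of the VTK/region-code exports.

**Compartmental stiffness.** Two extra displacement-driven solves per knee:
the femoral compartment opposite the side of interest is softened to
10 MPa so load passes through one compartment; stiffness = vertical
reaction force / mean vertical displacement of that side's subchondral
surface nodes (N/mm). Stiffness is a geometry/material property computed
from the unscaled solves — body weight cancels out of it by construction.

## Statistics

* **CV%RMS** — `100 * sqrt(mean_i((SD_i/|mean_i|)^2))` over subjects, SD
  with the n-1 denominator, absolute means for signed metrics; zero iff all
  repeats are identical.
* **Normality gate** — adjusted Fisher-Pearson skewness and excess kurtosis
  divided by their small-sample standard errors; |Z| > 1.96 on either flags
  the sample non-normal (constant samples are non-normal by convention).
  The decision is affine-invariant.
* **Comparison** — both groups normal: pooled-variance unpaired t-test with
  a t-based 95% CI; otherwise exact Mann-Whitney (exact for group sizes
  <= 12, normal approximation with tie correction above) with the
  Hodges-Lehmann estimate (median of pairwise differences) and its
  distribution-based CI. Percent differences are relative to the normal
  group's central value.
* **Cohen's d** — |difference| / SD. The default denominator is the
  all-scans SD (across every subject-repeat value): with that convention
  the reference medial-stiffness row reproduces its printed d of 0.54,
  which a pooled-SD denominator does not; the pooled SD remains available
  (`effect_size()` takes any SD). No multiple-testing correction is applied
  across the seventeen regions, matching the source protocol; report
  readers should interpret per-region p-values accordingly.
* Report rounding: stress 2 decimals (MPa), microstrain and stiffness
  integers, percents 1 decimal.

## Problem sizes and numerical choices

The package's own analysis scale (chosen once as its study conditions, and
the sizes all shipped tests and the acceptance script use): phantoms at
1.25 mm voxels for FE analyses (2 mm bone elements, 25-35k elements,
~100k DOF) and at 2 mm voxels with a 4 mm shell and 3 mm elements for the
fast pipeline tests; cohort runs use 4 + 4 subjects. The `PhantomSpec`
default voxel size remains 0.625 mm, the scanner resolution the phantom
emulates. Degenerate inputs are rejected rather than patched: voxels too
coarse for the shell, probe levels out of order, a closed joint gap,
under-constrained systems, zero subject means in CV%RMS.

## Known limitations

* **Mesh-convergence magnitude.** On voxel-grid hexahedral remeshing at
  this scale, the maximum relative change of the 17 x 4 regional means
  between a 2 mm and a 1.8 mm mesh is of order 5-30%, dominated by thin
  surface bands where strains are small (relative changes blow up) and the
  stair-stepped boundary shifts phase between element sizes. The
  mesh-independent probe aggregation reduces this substantially (from ~40%
  to ~10-20% in our measurements) but does not reach the ~1% achievable
  with half-million-element smoothed-surface quadratic-tet models in
  commercial solvers. `mesh_refinement_study()` reports the honest value.
* The quadratic-tet path is provided for formulation parity and INP export;
  full-knee tet models are an order of magnitude more expensive and are not
  used by the shipped studies.
* Regional strain magnitudes of the phantom are ~2-3x smaller than
  published in-vivo values — the phantom's trabecular densities and its
  cartilage-free load path are not calibrated to reproduce them, only their
  order of magnitude and medial/lateral contrasts.
* Automatic rod detection is not implemented: rod geometry comes from the
  phantom ground truth (or, for repeat scans, from the recorded rigid
  transform). Real-scanner use would require supplying rod regions.
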