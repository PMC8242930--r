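---
title: "Estimating body segment parameters from convex hulls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating body segment parameters from convex hulls: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullbsp)
```

## The problem

Multibody dynamic analysis (MDA) of animal locomotion needs, for every
rigid body segment, ten body segment parameters (BSPs): the mass, the three
centre-of-mass coordinates CM(x), CM(y), CM(z), the moments of inertia
Ixx, Iyy, Izz and the products of inertia Ixy, Ixz, Iyz. For extinct taxa —
and for extant ones where whole-body imaging is impractical — soft tissue
is unavailable and BSPs must be reconstructed from the skeleton. Convex
hulling is the quickest largely objective reconstruction: each skeletal
segment is "shrink-wrapped" by its convex hull, the hull is treated as a
uniform-density solid, and the resulting *naive hull BSPs* are converted to
soft-tissue predictions with per-segment, per-parameter linear calibration
equations fitted on extant species for which both skeleton and skin
surfaces exist.

`hullbsp` implements that pipeline end to end: exact mass properties of
watertight triangle meshes, convex hulls, slicing of elongate segments,
the bundled mammalian calibration table, and the regression machinery (OLS
and phylogenetic GLS) needed to fit new calibration tables.

The anatomical frame is fixed throughout: x craniocaudal, y mediolateral,
z vertical; units are SI (m, kg, kg m²). No unit inference is ever done on
input files — silently guessing units is a classic error source in
morphometry.

## Exact polyhedral mass properties

For a watertight, outward-oriented triangle mesh the ten volume integrals
∫dV, ∫x, ∫y, ∫z, ∫x², ∫y², ∫z², ∫xy, ∫yz, ∫zx are evaluated exactly by
signed-tetrahedron decomposition: each surface triangle (A, B, C) is joined
to the origin and closed-form monomial integrals over the tetrahedron are
summed with the sign of the tetrahedron's orientation. This is the
divergence-theorem sibling of the classical face-projection algorithm for
rigid-body mass properties; both are exact for polyhedra, and the
tetrahedron route is simpler to vectorize in R. Accumulation uses R's
`sum()`, which accumulates in extended precision where the platform
supports it.

From the integrals, `mass_properties()` derives mass = ρV, the centre of
mass, and the six inertial components about axes through the centre of mass
(parallel-axis corrected). Two conventions are fixed and tested:

* **Products of inertia** are stored with the *positive-integral*
  convention, Ixy = ρ∫xy dV. The assembled inertia tensor negates them off
  the diagonal, and the JSON/CSV output schema carries an explicit
  `products_sign_convention = "positive_integral"` field. The calibration
  equations for products are applied on this convention; the original
  calibration software's convention is not stated in its documentation, so
  this is asserted rather than cross-checked — a documented, untestable
  assumption.
* **Density** is uniform within a segment, defaulting to 1000 kg m⁻³
  (water). BSPs are linear in density: `rescale_density()` multiplies mass
  and all six inertial components by the ratio and leaves the centre of
  mass untouched. Predictions from the calibration table assume hull BSPs
  computed at 1000 kg m⁻³; a different target density should be applied to
  the *prediction*, which is why `predict_segment()` warns when it receives
  hull BSPs at any other density.

Validation is report-only (`validate_mesh()`): watertightness (every edge
in exactly two faces), consistent orientation (each shared edge traversed
in both directions), positive signed volume, and absence of zero-area
faces. The only repair ever applied is a global face flip for meshes that
are consistently oriented but globally inverted, and only at the file-read
boundary; mixed orientation is an error, because silently repairing it
hides corrupt scans.

## Convex hulls and segment slicing

No convex-hull library is available in the target environment, so the hull
is computed natively by an incremental beneath–beyond algorithm (the
Quickhull family): an extreme initial tetrahedron, then for each remaining
point the visible faces are removed and the point is joined to the horizon
edges. Points within 1e-10 (relative to the coordinate scale) of a
supporting plane are treated as on-hull and discarded. Degenerate inputs —
fewer than four distinct points, collinear or coplanar clouds — raise an
error instead of returning a zero-volume pseudo-hull, because downstream
log10 transforms require positive mass. The test suite checks the
implementation against an independent brute-force oracle that enumerates
all supporting planes.

Elongate segments (tails) are cut by `split_along_axis()` into n pieces of
equal *extent* (not equal volume) along a chosen axis — the reproducible
analogue of dividing a curved tail into roughly equal anatomical quarters;
per-vertebra boundaries are not recoverable from a surface mesh. Each cut
cross-section is closed by fanning cap triangles from the loop centroid, so
every piece is again a watertight solid; piece volumes sum to the input
volume to floating-point accuracy. With `axis = "auto"` the slicing axis is
the principal axis of the vertex cloud, its sign chosen toward the extreme
vertex with the larger absolute coordinate, and pieces are returned in
decreasing-coordinate order (proximal → distal).

## The bundled calibration table

The packaged resource (`load_bundled_table()`) holds 130 linear conversion
equations — 13 segments (six left limb segments: arm, forearm, hand, thigh,
shank, foot; and seven axial: head, neck, torso, four tail quarters) × 10
parameters — calibrated on paired skeleton/skin CT reconstructions of 32
extant mammal species spanning roughly 0.02–400 kg. Coefficients are stored
exactly as printed in the source tables (3-significant-figure intercepts,
2-decimal slopes) together with the printed 95% confidence intervals;
re-derivation is impossible because the underlying scan data are not
deposited. Per-cell n, R² and RMSE live in supplementary tables that are
not part of the bundled resource and are stored as missing.

Mass and the moments of inertia are modelled on the log10 scale
(soft = 10^(a + b·log10 hull)); centre-of-mass coordinates and products of
inertia on the linear, signed scale. Right-sided limb segments reuse the
left-side equations via `mirror_model()`: for the laterally antisymmetric
parameters CM(y), Ixy and Iyz the intercept's sign is flipped (the slope
acts on sign-flipped inputs and is unchanged). Axial segments are laterally
symmetric in principle, so `predict_segment(zero_axial = TRUE)` forces
CM(y), Ixy and Iyz to exactly zero *after* prediction; the models for those
cells are retained and applied by default because the calibration reports
them, and zeroing is an explicit modelling decision, not a silent default.

Two deliberately surfaced caveats: a handful of cells (torso CM(y), neck
Ixy/Iyz, some tail products) have slopes far from 1 with very wide printed
CIs — the package applies them verbatim and exposes the CI width rather
than judging validity; and predictions outside the calibrated ~0.02–400 kg
range raise an extrapolation warning but are never refused, since
reconstruction of very large extinct taxa inevitably extrapolates. The
warning keys on the hull mass because per-cell fitting ranges were not
published.

## Fitting new calibration tables

`build_calibration()` fits every (segment, parameter) cell with at least 3
species: the transformed soft value is regressed on the transformed hull
value by OLS and — when a phylogeny is supplied — by generalized least
squares whose residual covariance is the Brownian-motion matrix (entry i,j
= shared root-to-tip path length; Pagel's λ fixed at 1, OLS being λ = 0).
λ is *not* estimated by maximum likelihood: with 15–31 species per cell the
likelihood surface for λ is too flat for that to be reliable. Right-sided
rows are folded onto the left side by sign reversal before fitting, so both
limbs share one equation by construction.

Numerical and inferential choices:

* Both fits are full maximum likelihood (not REML) with k = 3 parameters
  (intercept, slope, σ²), so AIC = 6 − 2·loglik is directly comparable
  between them and any AIC difference reflects only the covariance
  structure. AIC ties (|ΔAIC| < 1e-9) go to OLS, the simpler model.
* 95% CIs use the t distribution with n − 2 degrees of freedom, on GLS
  standard errors for PGLS. The source publication does not state its CI
  construction; this is the standard choice and is documented as an
  assumption.
* The GLS solve whitens through the Cholesky factor of V, and the tree is
  pruned per cell to the species actually present — with 15–31 species per
  segment, pruning is the only way those cells can be fitted at all.
* The tree need not be ultrametric; only path lengths enter V.
* R² and leave-one-out cross-validated RMSE (hat-matrix identity
  e_i/(1 − h_ii), exactly equal to explicit refits) are reported for OLS
  only — R² has no agreed definition under GLS.
* Products of inertia are fitted on signed raw values, consistent with
  negative printed intercepts in the bundled table.

## The synthetic world, and what a green test establishes

The generator module builds everything the tests need, deterministically
under a seed:

* `simulate_tree()`: pure-birth trees (exponential waiting times, via
  `ape::rphylo`), tips `sp1…spN`.
* `simulate_bm()`: Brownian tip values through the Cholesky factor of the
  BM covariance.
* `generate_paired_dataset()`: hull values spread log-uniformly over a
  body-mass range defaulting to 0.02–400 kg (the calibration's span), true
  coefficients defaulting to the bundled table's, residual sd 0.05 on the
  transform scale (about the scatter implied by R² ≈ 0.95 at these signal
  variances — chosen once as a realistic level, not tuned), iid or
  Brownian residuals.
* `generate_specimen()`: 13 primitive segments (boxes, an icosphere head,
  hexagonal-prism neck and tail quarters) proportioned like a generic
  quadruped, scaled by `body_scale`; the "skeleton" is the skin shrunk
  isotropically toward its centroid by a factor drawn from `shrink_range`
  (default 0.3–0.7). Isotropic shrinkage guarantees the skeleton lies
  strictly inside the convex skin, and makes hull mass exactly
  shrink³ × skin mass — a closed-form structural relation with log-slope 1.
* `mc_mass_properties()`: a brute-force Monte-Carlo oracle — rejection
  sampling in the bounding box with ray-crossing inside tests (fixed
  oblique ray direction; grazing hits are retried from a deterministically
  perturbed origin). It shares no code with the exact integral path.

One statistical subtlety is worth stating because it mirrors a limitation
of the real calibration design. In the specimen world the shrink factor
perturbs the *hull* (x) side of the hull/soft regression. Errors in x
attenuate fitted slopes (regression dilution): at the default 0.3–0.7
spread the pooled mass slope comes out near 0.91, not 1. The end-to-end
acceptance check therefore runs at a narrow shrink spread (0.48–0.52),
which is the small-noise regime in which slope recovery is a meaningful
claim. The same mechanism operates in any real skeleton-based calibration
where the hull side is the noisier measurement — a reason not to
over-interpret calibration slopes slightly below 1.

What the synthetic world does *not* emulate: real anatomy (concave
segments, articulated joints), CT noise and segmentation error, posture
effects, or non-uniform tissue density. A green end-to-end test
establishes that the geometry, the transforms and the fitting machinery
compose correctly — not that the bundled equations are accurate for any
particular real taxon; their accuracy rests on the original calibration
dataset.

## Known limitations

* The bundled coefficients are printed values (3 significant figures /
  2 decimals); predictions inherit that rounding.
* The product-of-inertia sign convention of the original calibration
  software is unverifiable (see above).
* Whether calibrated CoM equations were expressed in a segment-local or
  scanner frame is not stated in the source; the package defines all
  coordinates in the input mesh's frame and assumes hull and soft CoM
  share it.
* Cap triangulation of cut cross-sections fans from the loop centroid,
  which is exact for the convex and near-convex cross-sections arising
  here but can self-intersect for strongly non-convex loops (volumes
  remain exact; rendering may look odd).
* Hull computation tolerates coincident and coplanar points but is not a
  robust-arithmetic implementation; inputs at extreme coordinate scales
  (≫ 1e6 m) will lose precision in the supporting-plane tests.
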