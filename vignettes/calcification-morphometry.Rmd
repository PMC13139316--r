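---
title: "Quantifying calcification cluster geometry and density: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcification cluster geometry and density: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(calcmorph)
```

# Scope

`calcmorph` quantifies the three-dimensional organization of arterial
calcification from CT attenuation volumes: how big, how elongated, how
irregular and how dense the individual calcific clusters are, and how those
properties covary across a cohort. This vignette is the package's own
account of its models and the choices behind them — what each stage
computes, which parameters matter, what the synthetic cohort generator does
and does not emulate, and where the design was genuinely open.

# Segmentation model

A calcification cluster is a maximal connected set of voxels at or above a
calcium attenuation threshold. The stage is deliberately minimal:

* **Windowing** (`normalize_intensity`) clips to a HU window. The default
  (−1024, 3071) spans the physical CT range and is therefore the identity:
  any rescaling would corrupt the density descriptors μ and σ, which are
  only meaningful on the native HU scale.
* **Thresholding** (`threshold_calcium`) is inclusive at 130 HU, the
  conventional calcium cutoff on contrast CT. Anatomical constraints (e.g.
  excluding adjacent bone) enter as a user-supplied binary ROI mask — the
  machine-readable stand-in for what is a human/clinical step; the package
  makes no attempt at automated bone discrimination.
* **Cleaning** (`morphological_clean`) is a binary opening with a discrete
  ball (default radius 1 voxel) followed by removal of components below a
  physical volume floor (default 1 mm³). The defaults suppress the speckle
  that threshold-crossing image noise produces without deleting plausible
  microcalcifications; both are configurable and echoed to the run
  manifest. The opening is not free: it shaves surface regions whose local
  curvature radius is below one voxel, which for thin, elongated clusters
  near the size floor can remove more than 10% of the voxels. That bias is
  a property of the operator, not an accident; analyses that need unbiased
  volumes of marginal clusters should set `opening_radius_voxels = 0` and
  rely on the size floor, which alone removes speckle at the default noise
  level (isolated super-threshold noise voxels form components far below
  1 mm³).
* **Labeling** (`label_components`) uses 26-connectivity by default, so
  corner-touching fragments count as one cluster — consistent with treating
  a cluster as a single discrete calcification; 6 and 18 are available and
  oracle-tested. Labels are assigned by decreasing component volume with
  ties broken by the smallest linear voxel index, making label maps
  reproducible across platforms.

# Shape and density descriptors

For each cluster the package reports volume, oriented-bounding-box (OBB)
dimensions, aspect ratio, eccentricity, compactness, μ, σ and the world-mm
centroid.

**Volume** is exactly `n_voxels × voxel volume` — conservation
(Σ cluster volumes = total foreground volume) is tested as an identity.

**OBB dimensions and aspect ratio.** The minimal oriented box is searched
over a deterministic, rotation-equivariant candidate set: the principal-
component frame of the voxel centres, plus, for each principal axis taken
as box axis, the in-plane rotation minimizing the 2D footprint area
(rotating calipers over the convex hull of the projected points). This is
near-minimal rather than provably minimal — the classical exact algorithm
enumerates 3D convex-hull facet orientations, and no 3D hull routine is
among the package's dependencies — but it is exact for ellipsoids and
boxes, and rotating a point set rigidly changes the returned dimensions by
less than 10⁻⁶ mm in the test suite. Every extent is padded by one mean
voxel spacing so that single-voxel and planar clusters keep positive
dimensions and a defined aspect ratio.

**Eccentricity** is `sqrt(λ1/λ3) − 1` from the eigenvalues of the central
second-moment tensor of the voxel centres, regularized by the voxel
self-moment (spacing²/12 per axis). The definition is a reconstruction:
reported per-cluster values in this field reach ≈2.6, outside the [0, 1)
range of classical ellipse eccentricity, so an elongation index on the
moment tensor is used instead. Because it is moment-based (all voxels, not
just the box), it responds to lobes and local surface asymmetry that leave
the aspect ratio unchanged — a two-lobe phantom is strictly more eccentric
than the single ellipsoid with the same bounding box. For an `r:1:1`
ellipsoid it equals `r − 1` in the continuum.

**Compactness** is `A^{3/2} / (6 sqrt(pi) V)`: 1 for a continuum sphere,
√(6/π) ≈ 1.382 for a cube, increasing with surface irregularity (again a
reconstruction, chosen over a classical 0–1 sphericity because reported
medians in this field exceed 1). The surface area comes from a
marching-tetrahedra isosurface at the 0.5 level of the cluster's indicator
field after Gaussian pre-smoothing with σ = 0.8 voxels. The smoothing is a
numerical necessity, not cosmetics: meshing the raw binary field
overestimates a sphere's area by ~28% (staircase artifact), while the
smoothed mesh is within 1% for a radius-16-voxel ball and within 7% of the
closed form for a 32-voxel cube. Components thinner than two voxels along
any axis cannot be meshed reliably and fall back to the voxel-face area
with a warning.

**Attenuation.** μ is the arithmetic in-cluster mean; σ the sample
standard deviation (n − 1), zero for single voxels by convention.

# Statistical analysis

All association analyses are rank-based, reflecting the heavily skewed
marginals of calcification features.

* `spearman` computes ρ as Pearson on average-tie ranks with the
  t-approximation p-value on n − 2 degrees of freedom.
* `coupling_matrix` treats the 15 unordered feature pairs of one matrix as
  the multiplicity family and adjusts with Benjamini–Hochberg; confidence
  intervals are bootstrap percentile intervals over complete-row resamples
  (default 1000).
* `partial_spearman` residualizes the ranks of both variables against the
  covariate ranks plus intercept and correlates the residuals; this equals
  the scaled negative off-diagonal of the inverse rank-correlation matrix
  (asserted to 10⁻¹⁰ in the tests). The p-value uses n − k − 2 degrees of
  freedom. Bootstrap resamples in which the covariate ranks become exactly
  collinear are redrawn; if more than half of the draws fail the data are
  declared degenerate rather than silently reported.
* `fit_rcs_model` places the three knots at the 0.10/0.50/0.90 empirical
  quantiles of the exposure (the conventional 3-knot default), fits OLS on
  the Harrell-normalized restricted cubic basis plus covariates, and tests
  nonlinearity by the Wald χ² of the single nonlinear coefficient (1 df).
  Under a linear truth the rejection rate at 0.05 is 0.047 (1000
  simulations, n = 150, unscreened); under a quadratic alternative with
  unit-SD noise its power exceeds 0.99. The calibration is assessed on the
  unscreened estimator to isolate the test statistic; influence screening
  (below) makes it mildly anticonservative (0.069 measured), which the
  documentation flags rather than hides.
* `influence_filter` computes Cook's distance, hat leverage and
  standardized DFBETAS from one fit via the closed-form leave-one-out
  identities and flags the union of the conventional cutoffs (4/n, 2p/n,
  2/√n). Screened spline fits exclude flagged rows and refit exactly once
  (no iteration). Numerically perfect fits (residual variance at machine
  noise) report zero residual-based diagnostics instead of 0/0 artifacts.
* `mann_whitney_u` counts pairs with half-credit for ties; p-values are
  exact by full enumeration when the smaller group has ≤ 8 observations
  and the assignment count is ≤ 2×10⁵, otherwise the tie-corrected normal
  approximation (the enumeration bound keeps stratified comparisons with
  one small and one large group out of infeasible C(n, k) territory).
* `compare_fragmentation` runs the primary single- versus multi-cluster
  dichotomy (Mann–Whitney per feature, BH across the feature family) and
  the count-stratified sensitivity analysis (Kruskal–Wallis, pairwise
  Mann–Whitney with BH only for features passing KW p < 0.05). The
  dichotomy refuses when either side has fewer than two plaques;
  undersized count strata are dropped with a warning naming them, since a
  cohort with a 2% four-cluster rate routinely produces singletons.

# The synthetic cohort generator

No public cohort of labeled carotid calcification volumes exists, so the
generator is a first-class, tested component that defines the study
conditions.

**What it emulates.** 107 plaques; cluster counts 1–4 with probabilities
(0.81, 0.12, 0.05, 0.02) — single-cluster predominant at 81%, the remaining
mass split plausibly and fully configurable; lognormal cluster volumes
(meanlog log 172, sdlog 1.4, truncated to 15–800 mm³ so every cluster is
comfortably segmentable and fits the 88³ × 0.5 mm grid); elongation
(major/minor axis ratio) lognormal with median 2.23 truncated to
[1.05, 4.5]; clusters rendered as randomly oriented prolate ellipsoids,
optionally with offset 0.6-scale lobes modeling surface asymmetry (the
default cohort is single-lobe, keeping the planted couplings clean; lobes
are exercised separately in the tests). Attenuation follows a
core–periphery ramp — edge 200 HU rising to a per-cluster core drawn
lognormally (median 1000 HU, sdlog 0.3, truncated 400–2400) — in
soft-tissue background (60 HU) with 25 HU Gaussian noise, a realistic CTA
noise level that keeps the background 2.8 SD below the 130 HU threshold.
With the mean ramp fraction of 1/4 this yields cluster means around
400 HU. Couplings among volume, elongation and core attenuation are
planted through a Gaussian copula with the exact Spearman-to-Pearson
conversion r = 2 sin(πρ/6); the defaults plant volume–elongation 0.8,
volume–core 0.5 and elongation–core 0.4, which propagate through feature
extraction to the volume–eccentricity, volume–μ and μ–compactness
couplings the analysis stage recovers.

**The attenuation ramp.** Inside a cluster the ramp fraction is computed
analytically as `1 − ρ(x)`, where ρ is the normalized radius of the
covering ellipsoid lobe; its mean is exactly 1/4 for any ellipsoid at any
scale. An earlier draft normalized a discrete distance transform by the
per-cluster maximum depth, but the discretization makes that mean strongly
size-dependent (small clusters have only a few depth shells), injecting a
spurious volume→μ coupling of either sign depending on a sub-voxel offset
convention — an instructive failure mode that the analytic form removes by
construction. The mask-level operation `fill_attenuation` (for arbitrary,
possibly non-ellipsoidal masks) retains the distance-transform definition
with a half-voxel surface offset, since no analytic geometry exists there.

**Fragmentation condition and coupling calibration.** Clusters in
multi-cluster plaques draw volumes scaled by 1/4 (floored at the truncation
minimum), reproducing the fragmentation phenotype in which multi-cluster
plaques carry smaller individual deposits. Mixing two volume scales in one
cohort necessarily attenuates pooled rank correlations involving volume
(the comonotone upper bound for the pooled volume–elongation Spearman under
this scaling is 0.822). The generator therefore treats the configured
couplings as properties of the *generated cohort*: it calibrates the
pre-scaling copula targets by a deterministic damped fixed point on a large
parameter-level draw (30,000 rows, fixed internal seed, six iterations, no
voxel rendering), projecting back into the positive-definite region when
necessary. With the default configuration the cohort-level couplings come
out at 0.795/0.488/0.396 (mean over 200 seeds; SDs 0.03–0.07 at ~140
clusters).

**What it does not emulate.** No CT physics — no beam hardening, no
partial-volume blur beyond grid discretization, no scanner-specific noise
spectra; no vessel-wall or lumen geometry (plaques are abstract ROIs); no
within-patient correlation between plaques. One consequence deserves
emphasis: the phantom's six features are nearly deterministic functions of
three latent parameters (eccentricity, aspect ratio and compactness are
all monotone in elongation; μ and σ in core attenuation), so *partial*
Spearman correlations on phantom cohorts are degenerate — adjusting
eccentricity for its collinear siblings flips the volume–eccentricity
partial negative. The end-to-end recovery checks therefore assess the
unadjusted correlation matrix; on clinical data, where the latent structure
is far richer, the partial analysis is the scientifically interesting one.
Passing tests on phantoms demonstrate that the pipeline measures what the
generator planted, not that real plaques behave like ellipsoids.

# Numerical choices and degenerate inputs

* Voxel world coordinates: centre of voxel [1,1,1] at the origin,
  `origin + (index − 1) × spacing`, no axis flips; NIfTI-1 round trips
  preserve anisotropic spacing exactly.
* The anisotropic Euclidean distance transform uses the exact two-parabola
  lower-envelope algorithm per axis (validated against brute force to
  10⁻¹⁵).
* Connected components are found by breadth-first search in compiled code;
  the independent test oracle is a frontier-vectorized flood fill in R.
* Cluster masks within a plaque are placed with a guaranteed two-voxel gap
  (support-function prefilter plus a dilation-overlap check), so the
  labeler always resolves the planted count; placement failures raise a
  geometry error suggesting a larger grid after bounded retries.
* Ties take average ranks everywhere; quantiles use the linear
  interpolation convention (R type 7).
* Bootstrap seeds, cohort seeds and every derived stream stay below 2³¹;
  the same seed reproduces every artifact byte for byte.

# Problem sizes in the test suite

The suite regenerates all fixtures in code: 200 random 16³ masks for the
labeling oracle, radius-16 balls and 32-voxel cubes for the closed forms,
cohorts of 3–14 plaques on 64³ grids for pipeline tests, and one
study-scale cohort (107 plaques, 88³ voxels, ~140 clusters) for the
end-to-end recovery of the planted couplings and the fragmentation effect.
Simulation-based calibration uses 1000 replications for the spline type-I
rate, 200 for its power and for partial-correlation recovery, and 200
bootstrap-coverage replications — sizes chosen to bound Monte-Carlo error
well inside the asserted bands.

# Known limitations

* The eccentricity and compactness formulas are principled reconstructions
  consistent with the value ranges reported in this field, but cannot be
  verified against any cohort's exact definitions.
* The OBB search is near-minimal; a pathological point cloud could in
  principle admit a slightly smaller box outside the candidate set.
* The opening's surface bias on thin clusters (above) means default-setting
  volumes of clusters near the size floor are conservative.
* Statistical rows are treated as independent clusters; plaques from the
  same patient are not modeled hierarchically.
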