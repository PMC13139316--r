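# calcmorph

Morphometry and coupling analysis of calcification clusters in 3D CT
attenuation volumes.

Carotid plaque calcification is not one thing: it ranges from a single
large, elongated deposit to a scatter of small fragments, and the size,
shape and density of the individual deposits appear to be tightly coupled.
`calcmorph` implements a reproducible pipeline for quantifying that
organization from CT angiography-style data: it segments calcific clusters
from Hounsfield-unit volumes, measures per-cluster geometric and density
descriptors, and analyses their statistical couplings with rank-based
methods. Because clinical CTA cohorts are rarely shareable, the package
ships a synthetic phantom generator that produces whole cohorts with known
ground truth and tunable couplings, so every stage of the pipeline is
testable end to end without any external data. It is aimed at researchers
developing or validating calcification morphometry methods.

## The pipeline

1. **Segmentation** — intensity windowing (HU-preserving), inclusive
   thresholding at ≥130 HU with an optional anatomical ROI mask,
   morphological cleaning (binary opening with a discrete ball, removal of
   components below a physical volume floor), and 3D connected-component
   labeling under 6/18/26-adjacency with deterministic size-ordered labels.
2. **Morphometry** — per cluster: volume *V* = *n*·voxel volume; maximum and
   minimum dimensions from a near-minimal oriented bounding box (PCA axes ×
   rotating-calipers footprint search), aspect ratio = max/min; eccentricity
   √(λ₁/λ₃) − 1 from the inertia-tensor eigenvalues λ₁ ≥ λ₂ ≥ λ₃ of the
   voxel centres (0 for a sphere); compactness *A*^(3/2)/(6√π·*V*) with the
   surface area *A* from a marching-tetrahedra isosurface of the smoothed
   indicator field (1 for a sphere, √(6/π) ≈ 1.38 for a cube); mean
   attenuation μ and attenuation heterogeneity σ (sample SD); world-mm
   centroid.
3. **Statistics** — Spearman correlation matrices with
   bootstrap-percentile CIs (1000 resamples) and Benjamini–Hochberg
   q-values; partial Spearman correlations (rank residualization);
   restricted cubic spline regression (3 knots, Harrell basis) with Wald χ²
   nonlinearity tests and influence screening (Cook's D > 4/n, leverage >
   2p/n, |DFBETAS| > 2/√n, union rule); Mann–Whitney U (exact for small
   samples, tie-corrected normal approximation otherwise) and
   Kruskal–Wallis comparisons of the single- versus multi-cluster
   fragmentation phenotype.
4. **Phantoms** — cohorts of plaque volumes containing 1–4 randomly
   oriented, optionally lobed ellipsoidal clusters (81% single-cluster by
   default), lognormal volumes, a dense-core/less-dense-rim radial
   attenuation ramp plus Gaussian noise, and a Gaussian copula
   (r = 2·sin(πρ/6)) planting target Spearman couplings among volume,
   elongation and core attenuation.

## Worked example

```r
library(calcmorph)

cfg <- cohort_config(n_plaques = 10, grid_shape = c(64, 64, 64),
                     volume_range_mm3 = c(15, 150), seed = 42)
cohort <- generate_cohort(cfg)

vol <- cohort$volumes[["P001"]]
vol
#> <attenuation_volume> 64 x 64 x 64 voxels, spacing 0.5 x 0.5 x 0.5 mm,
#>   HU range [-53.6, 1133.5]

labels <- segment_volume(vol)            # threshold 130 HU, clean, label
labels
#> <cluster_label_map> 64 x 64 x 64 voxels, 1 clusters, connectivity 26

compute_cluster_features(labels, vol, plaque_id = "P001")
#>   volume_mm3 aspect_ratio eccentricity compactness mu_hu sigma_hu
#> 1      87.25         2.37         1.48        1.12 460.7   198.19
```

One plaque held a single 87 mm³ cluster, elongated (aspect ratio 2.4,
eccentricity 1.5), mildly irregular (compactness 1.12), averaging 461 HU
with 198 HU of internal heterogeneity — the dense core against the fainter
rim. Across the ten plaques the planted size–shape coupling is already
visible:

```r
feats <- do.call(rbind, lapply(names(cohort$volumes), function(nm)
  compute_cluster_features(segment_volume(cohort$volumes[[nm]]),
                           cohort$volumes[[nm]], plaque_id = nm)))
spearman(feats$volume_mm3, feats$eccentricity)
#> volume-eccentricity Spearman rho = 0.71 (p = 0.0022, n = 16)
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers for the full study-
scale run (107 plaques), each a thin script over the package functions:

| script | writes |
|---|---|
| `01_simulate_cohort.R` | NIfTI volumes + `ground_truth.csv` |
| `02_segment_label.R` | label maps |
| `03_extract_features.R` | `features.csv`, `plaques.csv` |
| `04_coupling_analysis.R` | `correlations.csv`, `partial_correlations.csv`, `rcs_fits.csv`, `spline_predictions.csv` |
| `05_fragmentation.R` | narrates `group_comparisons*.csv` |

All artifacts land under `results/cohort/` together with a JSON manifest
recording every parameter and seed; rerunning with the same configuration
reproduces the CSVs byte for byte.

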