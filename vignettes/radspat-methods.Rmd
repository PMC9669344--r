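---
title: "Joint radiomics and spatial-distribution modelling of FLAIR lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint radiomics and spatial-distribution modelling of FLAIR lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Autoimmune encephalitis (AE) and WHO grade II diffuse astrocytoma (AS) can
look alike on FLAIR MRI: both present as non-enhancing hyperintense lesions,
and misclassification sends patients toward the wrong treatment entirely
(immunotherapy versus neurosurgery). Two kinds of quantitative information
help separate them. *Local* information — the texture, histogram and shape
of each lesion — differs because tumour tissue and inflammatory oedema have
different microstructure. *Global* information — how many lesions there
are, how large, and where they sit in the brain — differs because AE is
typically multifocal and medial-temporal while a low-grade astrocytoma is
typically a single unilateral mass, often frontal.

`radspat` implements a pipeline that scores both channels and fuses them:

1. **Per-lesion radiomics.** 351 features per lesion in four families
   (29 morphology, 20 intensity statistics, 30 histogram, 272 higher-order
   texture), following IBSI-style definitions.
2. **Radiomics Index for Lesion (RIL).** Features are reduced by Spearman
   correlation clustering, then an L1-penalized (LASSO) logistic model
   selects features and weights; RIL is the weighted sum of the selected,
   standardized features (plus the fitted intercept).
3. **Radiomics Index for Subject (RIS).** A Youden-optimal threshold $T$ on
   the training lesions splits lesions into a positive court
   ($\mathrm{RIL} \ge T$) and a negative court ($\mathrm{RIL} < T$). With
   $p$ and $n$ lesions in the two courts,
   $$\mathrm{RIS} = \begin{cases}
     \frac1p \sum_i \mathrm{RIL}_i^{+}, &
       \sum_i |\mathrm{RIL}_i^{+} - T| \ge \sum_j |\mathrm{RIL}_j^{-} - T| \\[4pt]
     \frac1n \sum_j \mathrm{RIL}_j^{-}, & \text{otherwise.}
   \end{cases}$$
   The court with the larger summed distance to $T$ "wins" and its mean RIL
   becomes the subject score; a single-lesion subject keeps its RIL.
4. **Spatial Distribution Index (SDI).** 27 per-scan features — lesion
   voxel counts in 16 atlas regions (12 supratentorial, 4 infratentorial),
   lesion count, mean/max/summed lesion sizes, and counts in seven size
   bins — pass through the same LASSO machinery.
5. **Joint model.** A logistic regression of the class on (RIS, SDI), with
   AUC / accuracy / sensitivity / specificity at training-frozen Youden
   cutoffs, DeLong AUC comparisons, Cohen's kappa and Fisher's exact test
   as the evaluation toolkit.

Everything runs end-to-end on synthetic 3D phantoms, so the whole pipeline
is testable without any imaging data.

## Conventions that needed a decision

**Positive class.** AS is the positive class throughout: sensitivity is the
fraction of astrocytomas detected. With the opposite convention the
sensitivity and specificity rows simply transpose.

**Court membership and ties.** Lesions with RIL exactly $T$ join the
positive court, and a tie in summed distances ($D^+ = D^-$, including the
degenerate all-lesions-at-$T$ case) resolves to the positive court. These
two rules together guarantee the winning court is never empty.

**RIL includes the intercept.** A constant shifts every RIL and the
threshold $T$ equally, so court membership — and hence RIS — is unchanged
under either reading; we keep the intercept so that `score_ril()` is the
full linear predictor.

**Youden candidates.** Cutoffs are scanned at midpoints between adjacent
sorted unique scores, plus the two trivial cutoffs (everything positive /
everything negative), so the maximized $J$ is never negative and is exactly
the exhaustive-search optimum. Ties prefer higher sensitivity, then the
lower cutoff.

**LASSO penalty.** The penalty minimizes the mean 10-fold cross-validated
binomial deviance (CV-min), with fold assignment derived from the run seed
and recorded in the model JSON. CV-min is the least-regularized standard
reading of "optimal parameters along the path". A known consequence is
overselection on null data: with 50 pure-noise candidates, runs may admit
several noise features (we measure a long tail up to ~15 at $n$ = 200–300).
The correlation-reduction step (default intra-cluster $|\rho| \ge 0.9$,
average linkage on $1 - |\rho|$, highest-variance representative) is the
main guard against redundant selections on real feature tables.

**Standardization is frozen on the training split.** Feature means and SDs
come from training data only and are stored inside each scorer, so
test/validation subjects are scored on the training scale and cannot leak
into selection, thresholds, or the joint fit (a directed test corrupts all
non-training rows and asserts every fitted object is bit-identical).

**Separation guard.** Perfectly separable synthetic cohorts are routine, so
the joint logistic fit falls back to a tiny ridge penalty ($10^{-4}$) when
the ML fit diverges or a coefficient is not finite; Wald p-values are only
reported for converged ML fits.

## Radiomics feature catalog

The four family counts (29/20/30/272) fix the catalog only up to an
interpretation; this package's interpretation is IBSI-style and shipped as
a machine-readable manifest (`write_catalog_manifest()`):

* **Morphology (29).** Voxel-counting and mesh volume, surface area,
  surface/volume ratio, compactness 1 and 2, spherical disproportion,
  sphericity, asphericity, centre-of-mass shift, maximum 3D diameter,
  PCA axis lengths with elongation and flatness, volume and area densities
  against the axis-aligned bounding box, a PCA-oriented bounding box, the
  PCA-eigenvalue ellipsoid, the minimum-volume enclosing ellipsoid and the
  convex hull, integrated intensity, and Moran's I / Geary's C.
* **Statistics (20).** The 18 intensity-based statistics plus the local and
  global intensity peak (mean over a 1 cm³ sphere).
* **Histogram (30).** 23 grey-level-histogram statistics (including the
  histogram-gradient quartet) plus 7 intensity–volume-histogram features.
* **Texture (272).** GLCM (25) and GLRLM (16) under four aggregations
  (2D per-slice per-direction averaged, 2D per-slice direction-merged,
  3D per-direction averaged, 3D merged); GLSZM, GLDZM (16 each), NGTDM (5)
  and NGLDM (17) under 2D-averaged and 3D aggregations. Distance-1
  neighbourhoods: 13 unique directions in 3D, 4 in-plane; grey levels from
  fixed-bin-number discretization with 64 bins by default (scale-invariant
  across arbitrary intensity units; the paper-silent choice most common in
  radiomics).

### Numerical choices

* **Mesh volume** comes from marching tetrahedra on the binary mask (Kuhn
  6-tetrahedron decomposition, isolevel 0.5). Because all cells are
  congruent, each (tetrahedron, occupancy-pattern) pair contributes a
  closed-form constant, making the computation exact and fast.
* **Surface area** uses a coarea estimator: the integral of the gradient
  magnitude of the Gaussian-smoothed ($\sigma$ = 0.5 voxel) mask indicator.
  Facet counting on the binary staircase overestimates a sphere's area by
  tens of percent; the coarea estimator is within ~2% for a radius-20
  digital ball, giving sphericity ≈ 0.97 where facet meshes give ≈ 0.79.
  The estimate is floored at the isoperimetric minimum for the measured
  mesh volume, so sphericity never exceeds 1 on tiny sharp masks.
* **Convex hull** is an incremental 3D hull (compiled) with a deterministic
  $10^{-3}$-relative jitter to break the massive coplanarity of
  voxel-corner clouds, and farthest-first insertion for robustness; clouds
  above 1500 points are decimated deterministically (hull volume error well
  below a percent). The oriented bounding box is PCA-aligned (a standard
  approximation to the optimal box) and the minimum-volume ellipsoid uses
  Khachiyan's algorithm on the hull vertices.
* **Moran's I / Geary's C** use inverse-distance weights over all voxel
  pairs, deterministically thinned above 2000 voxels to bound the quadratic
  cost.
* **Degenerate inputs** never produce non-finite values: constant regions
  give zero moment ratios, single-level histograms give entropy 0 and
  uniformity 1, directions with no voxel pairs fall back to a single
  self-pair at the modal grey level, and a mirrored or translated lesion
  reproduces the vector (exactly, outside the jittered hull features and
  the orientation-dependent tetrahedral mesh).

## The spatial-distribution features

Lesion instances are 26-connected components; components below 8 mm³ are
discarded, which aligns the smallest size bin `[8, 80)` with the
segmentation rule that ignores tiny lesions and makes the seven bin counts
total the lesion count exactly. Bins are half-open, the top bin
`[2560, ∞)`. Probabilistic (spatially normalized) masks binarize at
threshold 0.5, boundary included. Lesion voxels on atlas background are
counted in the size statistics but not the region counts (warned).

## The phantom generator

`phantom_config()` defines the synthetic study conditions: a 72×72×60 grid
at 2 mm isotropic spacing holding an ellipsoidal brain, parcellated
geometrically into 12 supratentorial angular sectors and 4 infratentorial
sectors below a ventral cut — deterministic, no template download.

The two classes contrast on every axis the analysis uses:

| parameter | AE-like | AS-like | rationale |
|---|---|---|---|
| lesion count | 1 + Poisson(1.5) | 1 + Poisson(0.07) | multifocal vs. ~7% multiple |
| radius (mm) | lognormal(log 7, 0.30) | lognormal(log 14, 0.20) | smaller, varied vs. single large |
| placement | bilateral medial-temporal-weighted sectors | unilateral frontal-weighted sectors | typical disease topography |
| intensity offset | +25 | +30 | hyperintense lesions |
| texture correlation | 2 mm | 6 mm | fine vs. coarse texture |
| texture skew | 0 | 0.8 | histogram-shape contrast |

Lesions are thresholded smoothed random blobs (a radial field plus
correlated bumps at 35% of the radius), not spheres, so morphology features
vary non-trivially; each blob is clipped to the brain, reduced to the
component containing its seed voxel, and guaranteed to reach the 8 mm³
floor. Scanner id is metadata only by default (an optional additive bias
exists for harmonization experiments), so the scanner-stratified split and
Fisher plumbing can be exercised without confounding.

These parameter values are free choices documented here: the clinical
source material describes the two cohorts' patterns qualitatively
(multifocal/medial-temporal vs. single/unilateral/frontal) but does not
publish lesion-size or count distributions. What passing tests on phantoms
show is that the *pipeline machinery* is correct and that separation is
controllable — with identical class parameters downstream AUCs concentrate
near 0.5, with the default contrasts they approach 1. Phantoms do not
emulate MRI physics (bias fields, partial volume, motion), inter-scanner
intensity shifts, or anatomically realistic parcels, so performance on
phantoms says nothing quantitative about clinical accuracy.

## Evaluation

AUC is the Mann–Whitney statistic (ties count ½). DeLong's test uses
placement-value covariances; identical scores give $p = 1$ by convention.
Cohen's kappa is $(p_o - p_e)/(1 - p_e)$ with kappa 1 for two identical
constant raters. Fisher's exact p is the two-sided probability-ordering
convention (via `stats::fisher.test`). Accuracy, sensitivity and
specificity are always reported at cutoffs frozen on the training split.

## Problem sizes

The bundled test-suite and the acceptance script run at reduced,
documented sizes chosen to keep a full run on one CPU comfortable: the
acceptance pipeline simulates 64 development + 24 validation subjects on
the default 72×72×60 grid with the full 351-feature extraction (≈170
lesions), and the property suites use table-level cohorts (50 seeded runs
of $n$ = 200–300 for selection properties, 20 seeded cohorts for the
model-ordering property). Texture oracles run on ≥100 random grids of up
to 5³ voxels, where brute-force enumeration is exact.

## Known limitations

* The feature catalog is an interpretation of the four family counts; no
  bit-compatibility with any specific extractor is claimed.
* CV-min LASSO overselects on null data (see above); if sparser signatures
  matter more than raw fit, pass stronger correlation-reduction thresholds.
* The hull-derived morphology features carry a deterministic ~0.1% jitter;
  they are stable per lesion but not exactly translation-invariant.
* 2D texture aggregations assume the third array axis is the acquisition
  (slice) axis; set `slice_axis` otherwise.
* The atlas is generic geometry: mapping the 16 labels onto a real
  parcellation (and spatial normalization itself) is the user's
  responsibility upstream of this package.
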