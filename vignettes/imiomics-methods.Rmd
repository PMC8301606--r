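---
title: "Voxel-wise body-composition mapping: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise body-composition mapping: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(imiomics)
```

This vignette documents the models implemented in `imiomics`, the
calibration of its synthetic-data generator, and the numerical and design
decisions that were genuinely open. It states no empirical result beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## The analysis in one paragraph

Whole-body water–fat MRI volumes are deformably registered to a reference
body, giving every reference voxel a corresponding point in every subject.
Two per-voxel channels result: *local tissue volume* (the Jacobian
determinant of the deformation, the local volume of subject tissue per unit
reference volume) and *fat content* (the subject's fat fraction pulled into
reference space). Each channel is then correlated voxel-by-voxel — Spearman
rank correlations, or parametric partial correlations when adjusting for a
composite cardiovascular risk score — against scalar traits measured by
carotid ultrasound: far-wall intima-media thickness (IMT, mm) and the
normalized echogenicity of the intima-media complex (IM-GSM, a grey-scale
median on a 0–256 scale anchored at blood = 0 and adventitia = 256).
Alongside the maps, the package reproduces the tabular workflow: atlas-based
VAT/SAT quantification with 50% fat-fraction retention, median fat content
in eroded organ VOIs, and sex-stratified SD-standardized ordinary least
squares association tables.

Because the underlying cohort's raw data are not public, the package ships
a first-class synthetic-data module: a calibrated tabular cohort generator
and a linked body-phantom generator with analytic ground-truth deformation
fields. All validation in the test suite runs against that ground truth.

## Cohort generator and its calibration

The generator draws each sex stratum from a Gaussian copula over 25 latent
variables (the cohort variables on a transformed scale). Right-skewed
variables — liver fat, pancreas fat, VAT, SAT — are modelled log-normally:
the latent variable is their natural logarithm, with `(mu, sigma)` chosen so
that the *arithmetic* mean and SD match the published per-sex values (so
sample means are directly comparable with the printed table). Smoking and
diabetes are latent-Gaussian variables thresholded at the calibrated
prevalence (smoking 4.4% women / 14.6% men; diabetes is not printed and
defaults to 3%, a plausible value for 50-year-olds in a Nordic population).
BMI and waist/hip ratio are deterministic functions of their parents and
are never drawn.

The correlation matrix is assembled from three ingredients:

* the published sex-stratified unadjusted standardized coefficients of the
  two association tables, read as correlations of each outcome (IMT,
  IM-GSM) with each body-composition variable (on the ln scale where
  applicable) — e.g. female IM-GSM vs ln VAT −0.41, IM-GSM vs total lean
  mass −0.75, male IMT vs total lean mass +0.32;
* plausible outcome–risk-factor correlations (e.g. IMT with systolic
  pressure ≈ 0.25 and LDL ≈ 0.2, in line with reported significances for
  this kind of cohort);
* an invented but physiologically sensible predictor block (fat
  compartments mutually 0.7–0.95, lean compartments 0.85–0.95,
  anthropometry–adiposity 0.7–0.9, HDL negatively tied to visceral fat,
  and so on).

Such a patchwork is almost never positive semi-definite. It is repaired by
Higham's alternating-projection nearest-correlation-matrix algorithm in a
*diagonally weighted* Frobenius norm (`nearest_psd_correlation`): the two
outcome rows carry weight 100, everything else weight 1, so the repair
lands almost entirely on the invented predictor block and preserves the
published outcome associations to better than ±0.01. With unit weights the
routine reproduces `Matrix::nearPD` (cross-checked in the tests).

Liver and pancreas fat are set missing for the first 16.4% of women and
22.4% of men in each stratum, matching the per-sex counts of the
characteristics table (138 of 165 women and 121 of 156 men have liver
values at the study's stratum sizes); this emulates the cohort subset
scanned before the dedicated liver protocol existed.

What the generator deliberately does *not* emulate: measurement error
distinct from biological variation, age structure (all subjects are 50),
non-Gaussian dependence beyond the copula, missingness mechanisms other
than the scan-order rule, and any within-subject longitudinal structure.
Passing calibration tests therefore demonstrate that the pipeline recovers
the encoded joint distribution, not that it would behave identically on
real cohort data.

## Body phantoms and ground-truth deformations

The reference body is assembled from ellipsoidal and cylindrical
primitives: torso, two tapering legs, two arms, head and neck; bone
(skull shell, spine, pelvis, limb bones), liver, pancreas, a heart blood
pool, an intra-abdominal VAT compartment, and subcutaneous fat shells split
at the hip into upper- and lower-body depots, with a residual lean class.
The geometry is parameterized by the physical grid extents, so coarser test
grids cover the same anatomy. The default grid is 128 × 96 × 250 voxels at
4 × 4 × 8 mm (left-right × anterior-posterior × foot-head, voxel-centre
convention, 0-based indices); in-plane spacing is deliberately coarser than
a clinical whole-body protocol (≈2 × 2 × 8 mm) to keep desk-scale
runtimes, and is configurable.

Per-subject deformations are sums of compactly supported radial scaling
kernels: for a region with scale factor $s$ and kernel centre $c$,
$u(x) = (s-1)\,w(q)\,(x-c)$ with $q$ an ellipsoidal distance and $w$ a bump
that is exactly 1 on a central plateau ($q \le 0.55$) and decays to 0 at
$q = 1$ with Wendland-C2 smoothness. Two consequences drive the design:

* inside the plateau the map is an exact local scaling, so the ground-truth
  Jacobian is $s^3$ throughout the region core (an isotropic 1.1 scaling
  gives 1.331);
* a compact kernel conserves total volume over its support — expansion in
  the core is repaid by compression in the decay annulus. Kernel supports
  are therefore sized so the labelled region sits inside the plateau while
  the annulus falls outside the body or in unanalysed lean tissue;
  perimeter bumps are used for the thin subcutaneous shells so that depot
  cores respond only to their own region's scale.

Scale factors are admissible in [0.5, 2]; the cohort linking maps each
subject's value to the cube root of its ratio to the sex-stratum median
(regional volume proportional to the cohort variable, median subject at
scale 1). VAT follows cohort VAT, upper SAT follows trunk+arm fat mass,
lower SAT follows leg fat mass, leg/arm muscle follow the leg/arm lean
masses, the heart blood pool follows total lean mass, and liver/pancreas
*fat-fraction levels* equal the cohort fat percentages (their sizes stay
fixed).

Subject images are produced by carrying the reference-geometry fat and
water fields through the numerically inverted ground-truth map with
trilinear interpolation. This partial-volume (anti-aliased) synthesis is
essential: nearest-neighbour label transport quantizes tissue boundaries to
the voxel grid, which makes the sub-voxel boundary shifts produced by
realistic scale factors literally unobservable, and no registration could
then be validated against them. Adipose-labelled voxels are clamped to fat
fraction ≥ 0.5 after interpolation so the depot-threshold construction
invariant holds exactly; Gaussian noise (SD 0.02 in fraction units) is
added inside the body and clipped to [0, 1]. The anatomy starts one slice
above the foot-end grid border so that warps never have to sample body
tissue outside the volume.

Ground-truth invertibility (finite-difference Jacobian > 0 on the body) is
asserted in the tests for linked cohort populations.

## Tissue-sequential registration

Registration proceeds in the three-stage order bone → water → fat, each
stage constrained by its predecessors:

1. **Articulated piece-wise affine bone registration.** The bone mask is
   partitioned into skull, spine, pelvis, left/right arm and left/right leg
   by bands at fixed fractions of the grid extent (identical for reference
   and subject). Each segment gets an axis-aligned affine from moment
   matching (centroids and per-axis second moments), optionally refined by
   Nelder-Mead on the SSD of smoothed, downsampled masks. Segments with too
   few voxels for stable second moments fall back to translation only, and
   scales are capped at [2/3, 1.5]. The affines are blended into one smooth
   field with normalized Gaussian weights centred on the segment masks; a
   constant identity-anchor weight (0.02) makes displacements decay to zero
   away from bone instead of propagating at full amplitude.
2. **Semi-elastic water registration**, a constrained multi-resolution
   demons scheme on the water channel initialized at the bone field, with
   bone voxels frozen to it.
3. **Elastic fat registration** on the fat-fraction channel initialized at
   the composed field, with bone and lean tissue frozen.

The demons core uses sum-of-squared-difference (Thirion) forces on the
smoothed image channels — the synthetic data are mono-modal, so SSD is the
natural metric — with per-voxel force normalization, a step cap of 1 voxel
per iteration, Gaussian smoothing of the update field (fluid-like;
sigma 2 voxels for the water stage, 1 for the fat stage — the
"semi-elastic" vs "elastic" distinction) and a light smoothing of the
accumulated field (sigma 0.5 voxels, diffusion-like) that propagates
boundary displacements into homogeneous region interiors. Three resolution
levels (×4, ×2, ×1) run with per-level iteration caps (coarse levels do the
bulk of the displacement cheaply) and an early stop when the mean update
over body voxels falls below 0.01 voxels. Both channels are pre-smoothed by
1 voxel per level so gradients extend beyond tissue edges. A level whose
result drives the Jacobian non-positive inside the body is rejected with a
warning. Degenerate voxels (vanishing gradient *and* vanishing difference)
get zero force — without this guard the normalized force is numerically
unstable in flat regions. After the final level, frozen voxels are set to
the constraint bit-exactly.

All fields are stored reference→subject (pull convention) on the reference
grid, so the Jacobian measures subject volume per reference volume and
larger tissue gives values above 1. Whether the original three-stage method
derives its volume maps from forward or inverse fields is not something the
package can resolve; the pull convention is used consistently and
documented. Out-of-bounds sampling uses a half-voxel clamp band at the grid
border (positions farther out take the fill value), which avoids spurious
boundary forces.

## Voxel-wise statistics

`spearman_map` rank-transforms (average ranks for ties) and
Pearson-correlates per voxel, with two-sided p-values from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom — the
standard large-sample approximation; the method used by the original
MATLAB analysis is not stated. Subjects missing at a voxel are dropped
voxel-wise and the n used is recorded; constant series give NaN/NaN.
`partial_corr_map` computes the parametric partial correlation
$r_{xy\cdot z}$ with a single confounder (the composite risk score), with
$t$ on $n-3$ degrees of freedom, and is verified against a
residual-on-residual oracle at 1e-12.

P-values are deliberately uncorrected, matching the convention of visual
map reading with an informal many-voxel rule; `cluster_filter`
operationalizes that rule by suppressing 26-connected suprathreshold
components smaller than a configurable minimum (default 50 voxels — the
original analysis is visual, so any numeric minimum is a proxy, which is
why it is a parameter). Rendering follows the published convention: one
coronal and six axial slices, grey water underlay where p ≥ 0.05, reversed
jet over a fixed [−1, 1] range elsewhere, red at strong positive.

## Depot quantification and DXA-like summaries

`segment_depots` transports the reference-space VAT/SAT atlas masks to
subject space by nearest-neighbour lookup through the numerically inverted
field (so the subject-space region is solid rather than a scatter of
pushed-forward points), then removes voxels with fat content below 50%.
The exclusion rule ("fat content below 50%") is implemented with an
inclusive boundary: fat fraction exactly 0.5 is retained, 0.49 is
excluded; no further threshold heuristics are layered on top. Volumes are retained-voxel counts times
voxel volume, in litres.

`voi_fat_content` erodes the VOI by one voxel (border avoidance, limiting
partial-volume effects) and reports the median fat fraction as a
percentage, with the average-of-two-middle-values convention for even
counts. `region_summaries` emulates planar absorptiometry from the phantom
labels directly: fat mass = Σ FF × voxel volume × 0.92 kg/L and lean mass
= Σ (1−FF) × voxel volume × 1.06 kg/L over soft tissue, with the standard
literature densities for adipose and lean tissue.

## Carotid frames and wall measurement

`synth_bmode` builds a horizontal-vessel frame (near-wall tissue, lumen at
the blood level, far-wall intima-media band, adventitia) at 0.1 mm/pixel
by default. The band intensity is the exact inverse of the grey-scale
normalization, `blood + (adventitia − blood) · GSM / 256`; band edges are
anti-aliased by area sampling so sub-pixel wall positions are defined;
speckle is emulated as additive Gaussian noise (default SD 6 grey levels)
before 8-bit quantization. A full speckle physics model is out of scope,
so the detector's repeat-measurement variability under this noise model is
comparable with scanner repeatability figures only qualitatively.

`detect_far_wall` measures each column of a 10 mm segment (≈100 columns at
0.1 mm/pixel): the lumen–intima interface is the first sufficiently large
positive gradient below the lumen centre and the media–adventitia
interface the maximal gradient below it within a plausible thickness
window (2.5 mm cap), each refined to sub-pixel depth by linear
interpolation of the 50% intensity crossing between median-estimated
plateaus. Columns are averaged with their immediate neighbours to suppress
speckle while keeping one measurement per column; detection fails loudly
if more than 20% of columns yield no edge. IMT is the column mean per
side, then the mean of the two sides.

The GSM normalization anchors the *median* of the blood reference region
to 0 and the *median* of the adventitia region to 256 (medians are robust
to speckle),
clamps to [0, 256] and takes the median over the ROI. The printed upper
anchor of 256 is honoured literally even though storage is 8-bit — the
normalized scale is continuous, and some protocols that rescale adventitia
to sub-maximum values (190/195) are deliberately not followed. GSM is
invariant under affine intensity transforms of the whole frame.

## SD-standardized association tables

`prepare_variables` ln-transforms exactly {liver fat, pancreas fat, VAT,
SAT} (after a `max(x, 0.01)` guard against near-zero draws) and z-scores
all 17 roster predictors *and both outcomes* within sex stratum. The
source text mentions standardizing the predictors only, but the printed
coefficient magnitudes (e.g. −0.41 for an outcome with SD ≈ 15 grey
units) are only dimensionally consistent with a standardized outcome, so
both sides are standardized; with both sides z-scored the unadjusted OLS
coefficient equals the Pearson correlation, which is what the calibration
encodes. Adjusted models add systolic blood pressure, LDL- and
HDL-cholesterol, diabetes and smoking as covariates on their natural
scales — that list is read as the adjustment set itself, not as a
substitution by the composite score; the score substitution is reserved
for the adjusted voxel maps, where a single covariate keeps the
computationally heavy voxel analyses tractable. Confidence intervals use the t
critical value on the residual degrees of freedom; missing liver/pancreas
values are dropped listwise with n recorded per cell.

`framingham` implements the 2008 general-cardiovascular-disease Cox
formulation (sex-specific log-scale coefficients, baseline survival and
population mean linear predictor) with a fully configurable coefficient
table, because the exact variant used by any given study is rarely stated;
all subjects of this cohort design are aged 50 and untreated for blood
pressure unless stated otherwise.

## Numerical choices and test problem sizes

* Correlation-matrix repair: eigenvalue floor 1e-8, alternating-projection
  tolerance 1e-9, residual negative eigenvalues lifted to 1e-10.
* Cohort sampling uses the Cholesky factor of the repaired matrix with a
  1e-8 ridge; fixed seeds give bit-identical cohorts (the Mersenne-Twister
  / inversion RNG is pinned, and the caller's RNG state is restored).
* Field inversion: 8–10 fixed-point iterations (the fields are smooth with
  Lipschitz constant well below 1, so convergence is geometric).
* Ties: average ranks everywhere; even-count medians average the two
  middle values.
* Degenerate inputs: constant voxel series → NaN/NaN; empty bone masks,
  empty VOIs after erosion, equal reference medians and singular designs
  raise errors rather than returning numbers.
* The test suite exercises the full anatomy on reduced grids covering the
  same physical body — 48 × 36 × 94 (≈10.7 × 10.7 × 21 mm) for
  registration validation and 32 × 24 × 64 for population-level runs —
  with per-level demons iteration caps of 60/40/20 (coarse to fine); these sizes are the
  package's choice of desk-scale validation problems, and every geometry
  parameter scales with the grid so the default 128 × 96 × 250 grid runs
  identically, only slower. Registration validation draws region scales
  from their full plausible ranges (e.g. VAT 0.75–1.45) rather than the
  narrower cohort-linked spread, probing the estimator across its intended
  operating range; voxels whose ground-truth Jacobian barely varies across
  phantoms (SD ≤ 0.02) are excluded from correlation summaries, since a
  near-constant ground truth carries no rank signal to recover.

## Known limitations

* The registration validates against phantoms whose deformations live in
  the same smooth low-dimensional family the generator produces; real
  inter-subject variability is far richer (posture, organ shape,
  station-stitching artifacts), so recovery figures here are an upper
  bound on real-data performance.
* Thin structures (subcutaneous shells, arm muscle) at the coarse test
  grids are only one to a few voxels thick; their Jacobian recovery is
  intrinsically resolution-limited.
* Voxel-wise inference is uncorrected by design; the cluster filter is an
  operational proxy for visual analysis, not a calibrated multiple-testing
  procedure.
* The DXA emulation shares the phantom's fat-fraction field with the MRI
  channel, so MRI-vs-DXA agreement in the synthetic world is optimistic.
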