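---
title: "Methods: leukoaraiosis volumetry and driving-safety path analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leukoaraiosis volumetry and driving-safety path analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladrive)
```

# What this package computes

Leukoaraiosis (LA) — ischaemic white-matter lesions that appear
hyperintense on FLAIR MRI — is common in healthy older adults and has been
linked to declines in driving safety. `ladrive` implements an analysis
pipeline for studying that link end to end:

1. **WMH volumetry**: threshold-based segmentation of hyperintense lesions
   on a FLAIR-like volume, with intensity standardization against a
   middle-cerebellar-peduncle (MCP) reference region, polynomial bias-field
   correction, and parcellation into four lobar compartments plus a
   periventricular compartment.
2. **Morphometry**: a brain-atrophy ratio `BA = CFV / ICV = 1 - TBV / ICV`
   from a simple three-class tissue segmentation.
3. **Behavioral scoring**: the moving-body recognition (DMD) ratio of a
   two-task dynamic visual cognition (DVC) test, and instructor-rated
   driving-safety-performance (DSP) scores at six closed-course locations.
4. **Inference**: Pearson correlation matrices, standardized multiple
   regression computed directly from a correlation matrix, and
   maximum-likelihood path analysis with chi-squared, GFI, AGFI, RMSEA and
   AIC fit indices.
5. **Synthetic data**: digital phantoms with known lesion ground truth and
   cohort tables drawn from a prescribed correlation structure, so every
   stage is testable without access to clinical data.

The package ships the published summary tables (per-variable means and SDs,
and the full 17-variable correlation matrix at n = 101) as plain-text
fixtures; the raw participant data are not publicly deposited, so all
subject-level inputs here are synthetic.

# Lesion volumetry

## Intensity model and standardization

The MCP is taken as lesion-free white matter. Its mean `mu_ref` and sample
SD `sigma_ref` (n − 1 denominator; an SD estimated from an ROI sample)
define the affine standardization

```
v' = 1000 + 100 * (v - mu_ref) / sigma_ref
```

after which the reference region has mean 1000 and SD 100 exactly. Lesions
are voxels with `v' > 1000 + 3.5 * 100 = 1350`, i.e. more than 3.5
reference SDs above normal white matter. The inequality is strict: tie
voxels are excluded, a measure-zero event under continuous noise made
explicit for integer-valued phantoms. The cut-off (3.5), target moments
(1000/100) and a minimum-connected-component filter (default off) are all
configurable.

The search region is the union of the four lobar white-matter labels and
the four periventricular bands; the MCP and everything infratentorial are
excluded, since LA is by definition a cerebral white-matter lesion.
Per-region volume is voxel count × (in-plane spacing² × slice thickness),
reported in ml. The four periventricular bands are pooled into one
periventricular figure (their printed volumes dwarf the lobar ones —
periventricular mean 14.6 ml versus parietal 0.14 ml — so they are reported
separately, never double-counted as lobar).

## Bias-field correction

Scanner inhomogeneity is modelled as a smooth multiplicative field. The
estimator fits a low-order 3-D polynomial (default order 2) to the
log-intensities over a tissue mask by least squares and divides it out.
By default the fitted log-field is centred to zero mean over the mask, so
correction changes shading but not the overall intensity scale (and an
order-0 fit is the identity); with `preserve_mean = FALSE` the raw fit is
returned, whose order-0 field is the geometric-mean normalizer. Because the
downstream standardization is affine-invariant, the two conventions lead to
identical segmentations; the centred default was chosen so corrected
volumes remain comparable to their inputs.

# The synthetic generator, and what it does not emulate

Phantoms are built on a deterministic layered atlas: an elliptical head
with a CSF rim, a grey-matter shell, white matter split into four angular
lobar sectors, a central ventricle box ringed by four quadrant
periventricular bands, and an inferior MCP block disjoint from all
cerebral labels. Default geometry is 64 × 64 × 27 voxels at
0.9375 × 0.9375 mm in-plane and 5 mm slices — the slice count and
thickness of the acquisition protocol; the in-plane spacing is not printed
for FLAIR and is borrowed from the printed T1 matrix specification
(configurable).

Intensities are class-constant (CSF 100, grey matter 300, white matter,
periventricular bands and MCP a common 500), with lesions elevated by
`contrast × wm_sd` (`wm_sd` = 50, the normal-white-matter SD unit in which
contrast is expressed), then a multiplicative quadratic bias field with a
stated maximum fractional amplitude, then additive Gaussian noise. The
rasterized sphere — voxel centres within the radius, in physical
coordinates — is the ground truth; its volume is the voxel count times the
voxel volume, not 4/3·pi·r³.

Phantoms are generated directly in a common template space, so the
anatomical-normalization step of a clinical pipeline has no counterpart
here — a deliberate simplification. Likewise out of scope: realistic
anatomy, Rician noise physics, multi-sequence simulation, and partial
voluming. Consequently, passing recovery tests demonstrates that the
thresholding, standardization and accounting are correct under the stated
noise model; they say nothing about tissue-contrast realism or
registration error on real scans.

A degenerate corner worth knowing: in a noise-free phantom the MCP is
exactly constant, so the estimated `sigma_ref` is 0 and standardization
refuses it. Exact-recovery demonstrations therefore standardize with the
generator's nominal moments (500, 50); the estimated route is exercised
whenever noise is present.

Cohort tables are drawn from a multivariate normal with the published
means/SDs and correlation matrix by default. The printed 2-dp correlations
make the 17 × 17 matrix slightly indefinite (smallest eigenvalue
−0.017); it is projected to the nearest positive-semidefinite correlation
matrix (eigenvalue floor 1e-6) and the repair is flagged on the output.
DSP columns can be integerized by rounding half away from zero and
clipping to their legal ranges (P1 3–9; P2, P6 4–12; P3–P5 2–6; total
17–51), which preserves means while respecting the three-point category
scale.

# Behavioral scores

The DMD ratio is implemented exactly as printed:

```
DMD = (presses on signal + presses on noise) / (total signal + noise trials)
```

Counting noise presses (false alarms) in the numerator is surprising for a
recognition rate, so a corrected convention — hits plus correct rejections
over total trials — is also provided. The verbatim convention is the
default to stay faithful to the published definition, the package does not
guess the authors' intent, and every output records which convention
produced it. Scores are reported ×100 when written into cohort tables,
matching the published scale.

DSP scoring sums three-point category ratings per location; the category
sets per location (e.g. P2, turning right at an intersection: searching,
speeding, signalling, positioning) are fixed, and validation names the
offending cell on any violation.

# Inference

## Standardized regression from a correlation matrix

With predictor correlation submatrix `Rxx` and predictor–outcome vector
`rxy`, the standardized coefficients are `beta = Rxx^-1 rxy`, with
`R² = rxy' beta`, `adj R² = 1 − (1 − R²)(n − 1)/(n − k − 1)` and
`F = (R²/k)/((1 − R²)/(n − k − 1))` on (k, n − k − 1) df. This is
algebraically identical to least squares on z-scored raw data, which the
tests verify to 1e-8 by constructing data whose sample correlation matrix
equals the target exactly (QR-orthonormalized columns recombined through
the Cholesky factor). Coefficient standard errors use
`SE_j² = (1 − R²)/(n − k − 1) · [Rxx^-1]_jj`. A singular predictor block is
refused, reporting the offending eigenvector.

## Path analysis

A path model is a recursive system of regressions among observed
variables: exogenous variables covary freely, residuals are uncorrelated —
the conventions under which the default five-variable model (age, brain
atrophy, occipital LA → sudden-motion DVC → P2) has
15 − 12 = 3 degrees of freedom. The fit minimizes

```
F_ML = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p
```

with an analytic gradient, starting from the per-equation least-squares
solution. For recursive models with uncorrelated residuals that start is
the exact ML optimum, which provides a sharp independent oracle: the tests
require ML estimates to match per-equation least squares to 1e-6, and the
optimizer is still run (and its gradient checked below 1e-8) so that the
equivalence is verified rather than assumed.

Two numerical choices matter. First, the fit runs internally on the
correlation-scaled covariance `D^-1 S D^-1`: the published SDs span four
orders of magnitude (occipital LA 0.004 versus periventricular LA 14.5),
and quasi-Newton steps on the raw scale produce singular trial
covariances. Because every variance is a free parameter, `F_ML`, chi²,
GFI, AGFI and RMSEA are invariant to this diagonal rescaling; estimates
are mapped back afterwards. Second, `chi² = (n − 1) F_ML` by default (the
Wishart convention, consistent with the `n − 1` in the RMSEA denominator);
the original software's convention is not stated, so `n · F_ML` is exposed
as an option — at n = 101 the two differ by 1%.

Fit indices:

```
GFI   = 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]
AGFI  = 1 - [p(p+1) / (2 df)] (1 - GFI)        (absent when df = 0)
RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))
AIC   = -2 logL + 2 q,  logL = -(n/2)[p log 2pi + log|Sigma| + tr(S Sigma^-1)]
```

AIC's additive constant depends on software conventions (raw-data
likelihoods include a mean structure that a covariance-only fit cannot
reconstruct), so AIC values are comparable within this package but not
across packages.

## Reproducing the published statistics

`run_paper_analyses()` with no cohort assembles the covariance matrix from
the packaged printed correlations and SDs at n = 101 and reproduces, within
the propagation of 2-dp rounding: the path-model fit (chi² ≈ 1.80 against
the printed 1.9, GFI 0.993, AGFI 0.965, RMSEA 0), the nine-predictor P2
regression (β for the sudden-motion DVC score 0.408 against printed 0.41;
β for parietal LA −0.44 against −0.46; R² 0.183 against 0.18) and the
seven-predictor sudden-motion regression (β occipital LA −0.23, β brain
atrophy −0.27, R² 0.159 against 0.16). These are computed fresh at run
time by the acceptance script and the test suite; the residual gaps are
exactly what feeding 2-dp correlations instead of raw data produces.

# Problem sizes and test design

The test suite and acceptance checks run at desk scale by design: phantoms
of 64 × 64 × 27 voxels (and 32 × 32 × 12 for unit tests), 20-phantom
recovery sweeps with contrast ≥ 5 SD, noise at most half the WM SD and
bias amplitude at most 0.2, five pooled lesion-free phantoms for the
false-positive-rate check against the Gaussian tail P(Z > 3.5) ≈ 2.3e-4,
and cohort recovery at n = 1e5 within ±0.01 per correlation. Volume
recovery is judged against one boundary-voxel shell of the true lesion
(surface voxel count × voxel volume), the resolution limit of a
voxel-counting volumetry.

Statistical test bounds are simultaneous where a maximum over many entries
is asserted (a Bonferroni Fisher-z bound across the 136 correlation pairs
at n = 101); single-quantity bounds use the standard-error or binomial
forms stated alongside each test.

# Known limitations

* The atlas is a geometric phantom, not anatomy; lobar sectors are angular
  quadrants and the "ventricles" are boxes. Volumetric realism of regional
  LA loads is out of scope.
* Tissue segmentation is intensity-only (k-means or fixed thresholds) and
  intended for phantoms; probabilistic segmentation of real scans is not
  provided.
* The path-model structure reproducing the published df = 3 is the unique
  natural five-variable structure, but the original figure is not
  enumerated variable-by-variable in text; the model is fully configurable
  through `path_model_spec()` should a different structure be intended.
* Printed 2-dp correlations limit agreement with the published statistics
  to the tolerances listed above; exact agreement would require the raw
  data, which are available only on request from the original authors.
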