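---
title: "Peritumoral iodine quantification with dectpeel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral iodine quantification with dectpeel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microvascular invasion (MVI) of hepatocellular carcinoma — tumor cells
inside small vessels, visible only under the microscope — predicts early
recurrence after resection, but it cannot be observed directly on
preoperative imaging. The working hypothesis behind this pipeline is that
MVI leaves a hemodynamic footprint just outside the tumor: occluded portal
venules trigger compensatory arterial hyperperfusion in a thin peritumoral
shell, which raises the local iodine uptake in the arterial phase of a
contrast-enhanced scan. Dual-energy CT (DECT) can quantify that uptake:
because iodine attenuates much more strongly at 80 kV than at tin-filtered
150 kV, a paired acquisition supports voxelwise material decomposition into
an iodine concentration map (mg/mL) and a virtual non-contrast (VNC) image.

`dectpeel` implements the full quantitative chain: two-material
decomposition, semiautomatic volumetric tumor segmentation, mm-scale
"peeling" of peritumoral and intratumoral layers, normalized iodine
concentration (NIC) per region, and the cohort statistics that turn
per-patient features into diagnostic-performance estimates. A synthetic
phantom and cohort generator supplies ground truth for every stage, so the
whole pipeline is testable without clinical data.

## Forward model and decomposition

Each voxel is modeled as soft tissue plus iodine:

$$\mathrm{HU}_{low} = v + s_{low}\,c, \qquad
  \mathrm{HU}_{high} = v + s_{high}\,c,$$

with $v$ the shared VNC value (HU), $c$ the iodine concentration (mg/mL),
and $s_{low} > s_{high} > 0$ the iodine sensitivities (HU per mg/mL).
`decompose_iodine()` inverts this 2×2 system exactly:
$c = (\mathrm{HU}_{low} - \mathrm{HU}_{high})/(s_{low} - s_{high})$.
Defaults are $s_{low} = 48$, $s_{high} = 15$; vendor decomposition
algorithms are unpublished, and on synthetic data the same matrix is used
forward and inverse, so all results are calibration-independent. Negative
concentrations (noise) are clipped to zero by default because downstream
"vital" thresholds assume a physical, non-negative map. The mixed-energy
reading image is the convex blend $0.6\,\mathrm{HU}_{low} +
0.4\,\mathrm{HU}_{high}$.

NIC is the regional *vital* iodine concentration — the mean over voxels
whose concentration exceeds a threshold (default 0.5 mg/mL) — divided by
the mean aortic concentration. Normalizing to the aortic blood pool removes
inter-patient variation in contrast timing and dose. Where an enhancement
criterion is not defined by the source analysis, the mean (not median) is
used throughout, and the aortic denominator is the all-voxel mean (the
blood pool is uniformly enhancing, so the distinction is immaterial there).

## Segmentation

`segment_tumor()` reproduces a semiautomatic workflow: the reader draws a
line across the maximal tumor dimension; the algorithm samples intensity
statistics in a 3-mm sphere at the line midpoint, grows a 6-connected
region within mean ± 2.5 SD (with a 5 HU floor on the half-width so
noiseless images still grow), confines growth to a bounding sphere of 1.5×
the line length, applies a one-voxel morphological closing, and keeps the
largest connected component. If the admitted region floods ≥ 95% of the
bounding sphere the result is flagged low-contrast. All parameters are
exposed in `params`; the defaults give Dice ≥ 0.95 against ground truth on
noiseless phantoms and ≥ 0.90 at 10 HU channel noise. Reader edits are set
algebra (`edit_mask()`), and externally supplied masks bypass segmentation
entirely. The maximal diameter is the 3-D Feret diameter over
surface-voxel centers; volume is voxel count × voxel volume, exactly.

## Layer peeling and the distance convention

Layers are distance bands from the tumor boundary: outer layer $k$ collects
liver voxels outside the tumor at depth $((k-1)t, kt]$ mm, inner layer $k$
tumor voxels at the same depth inward, default $t = 2$ mm with a 4-mm
variant. Five VOIs follow by set algebra (tumor ± cumulative layers).
Outer layers are clipped to the liver minus reader-supplied exclusions
(large vessels, extrahepatic tissue); distance is measured from the tumor
surface *before* clipping, then clipped. Bands are half-open, so layers are
disjoint and merging two 2-mm bands reproduces one 4-mm band exactly. Empty
regions (e.g. the innermost VOI of a small tumor) propagate as missing
values, never zeros.

The distance field deserves care. A center-to-center Euclidean distance
transform — the default in most imaging toolkits — systematically
overestimates the distance to a binary surface by about a third of a voxel,
which at 0.5-mm voxels inflates/deflates 2-mm shell volumes by 5–9%
relative to analytic geometry. Measuring to the blocky half-voxel surface
instead *under*estimates, because staircase corners protrude. `dectpeel`
therefore uses an anti-aliased distance transform: the binary mask is
smoothed with a separable Gaussian of one voxel per axis, the 0.5-level
crossings are located to sub-voxel precision by linear interpolation along
each grid axis, and an exact separable EDT (Felzenszwalb–Huttenlocher, with
parabolas rooted at the off-lattice crossing positions) measures the
distance to that interface. On a 10-mm sphere rasterized at 0.5-mm voxels
this reproduces the analytic 2-mm shell volumes to about ±1.5%, versus
−8.7% for the center-to-center transform. The known residual is the
level-set curvature shift of Gaussian smoothing, of order $\sigma^2/R$:
negligible when the voxel pitch is small against the structure radius, but
worth remembering for structures only a few voxels across or for spacings
approaching the band thickness (bands should be at least two voxels wide on
every axis).

## The synthetic data generators

**Voxel phantoms** (`generate_phantom()`) place a spherical (optionally
lobulated) tumor inside a liver ellipsoid with an aortic cylinder
alongside, rasterize exact masks, and apply the linear forward model above
with independent Gaussian HU noise per energy channel. Tissue defaults were
chosen so the noiseless pipeline lands on a clinically plausible NIC scale:
0.7 mg/mL parenchymal iodine against a 10 mg/mL aortic pool gives
peritumoral NIC 0.07 — the scale reported for tumors without MVI — and
2.5 mg/mL in the tumor gives NIC 0.25. MVI-positive phantoms add a
peritumoral rim (default 2 mm, +0.5 mg/mL) emulating arterial-phase
peritumoral enhancement. The phantoms deliberately omit real CT physics:
no beam hardening, scatter, partial-volume blur, or correlated noise, and
no contrast kinetics. Passing phantom tests therefore validates the
*computational* chain — geometry, decomposition algebra, band placement,
normalization — not clinical image quality.

**Cohort tables** (`generate_cohort()`) draw each NIC feature per patient
from a normal distribution truncated at zero with the group's reported mean
and SD — the simplest generative model consistent with published summary
statistics for a non-negative quantity. At the reported parameters
(means ≥ 2.3 SDs above zero) the truncation bias is below 0.005, verified
by test. Features are independent across regions by default because no
inter-layer correlation structure is published; a `patient_effect`
parameter adds a shared per-patient latent factor for sensitivity analyses.
Binary reader scores are Bernoulli draws at the reported group rates. Group
sizes default to 22 MVI-negative / 14 MVI-positive, the published cohort.

## Statistical operations

* **Group comparison**: Mann–Whitney for continuous features (exact
  enumeration when there are no ties and $n_a n_b \le 400$, otherwise a
  tie-corrected normal approximation; fully tied input returns
  $U = n_a n_b / 2$, $p = 1$), Pearson chi-square *without* continuity
  correction for categorical ones — the uncorrected form reproduces the
  published p-values from the published counts; a Yates variant is
  available.
* **ROC**: trapezoidal AUC (identical to the tie-half-credit U statistic —
  property-tested), DeLong 95% CIs and DeLong paired tests (the de-facto
  standard for correlated ROC curves), and Youden-optimal cutoffs with ties
  broken toward higher specificity, consistent with the published
  sensitivity/specificity pair.
* **Odds ratios**: cross-product ratio with Woolf (log-normal) 95% CIs and
  the Haldane–Anscombe +0.5 correction when a single cell is zero.
* **Logistic regression**: `stats::glm` maximum likelihood with Wald
  intervals; continuous predictors are dichotomized at their Youden cutoffs
  before fitting (matching the published modeling choice); among NIC
  features only the highest-AUC one enters the multivariate model, a guard
  against the near-collinearity of overlapping layers. Coefficients beyond
  ±15 on the logit scale flag separation.
* **Reliability**: ICC in the two-way mixed-effects, absolute-agreement,
  single-measurement form (the form is not fixed by the source analysis;
  this is the standard conservative choice), and Cohen's κ; both map to the
  poor/moderate/good/excellent bands at 0.4/0.6/0.8.
* **Multiplicity**: no multiple-testing correction is applied, matching the
  source analysis; all p-values are reported raw.

`cohort_report()` chains these into the three standard tables (group
comparison, diagnostic performance, univariate screen at $p < 0.10$ plus
multivariate model), dropping missing cells pairwise per feature.

## Problem sizes and reproducibility

Simulation sizes were chosen to keep every analysis on a laptop scale:
64³-voxel phantoms at 1-mm spacing (a ~3 mL tumor, segmented and peeled in
about a second), 40-phantom end-to-end cohorts, 200-replicate cohort
simulations for AUC summaries, and 10⁴-replicate null simulations for
type-I-error checks. Every stochastic step takes an explicit integer seed
(`phantom_spec`, `cohort_spec`, `pipeline_config`), and identical seeds
give bit-identical outputs; the acceptance script derives all its seeds
from a single `--seed` argument.

## Known limitations

* The phantom forward model is linear and noise is uncorrelated between
  energy channels; real dual-source data have correlated, spatially
  structured noise and spectral nonlinearity.
* The vital-iodine threshold creates a selection bias on noisy maps (the
  mean over voxels above threshold exceeds the true regional mean). This
  affects both cohort arms equally in the phantom studies, but absolute
  NIC values from noisy data should be read with that in mind.
* Region growing assumes a roughly unimodal tumor intensity; rim-enhancing
  or strongly heterogeneous lesions need reader edits, exactly as in the
  clinical workflow.
* Band volumes degrade when voxel spacing approaches the band thickness
  (see the distance-convention section); keep spacing ≤ t/2.
* The cohort generator reproduces published group summaries, not real
  inter-feature dependence; statistics that hinge on cross-feature
  correlation (e.g. paired AUC comparisons between layers) are only
  qualitatively meaningful on simulated cohorts.
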