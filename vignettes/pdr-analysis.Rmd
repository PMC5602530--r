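---
title: "Detecting the perihematomal diffusion-restriction rim: models, thresholds and phantoms"
author: "pdrim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the perihematomal diffusion-restriction rim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdrim)
```

## The problem

A spontaneous intraparenchymal hemorrhage (IPH) is typically surrounded by
vasogenic perihematomal edema (PHE): FLAIR-hyperintense tissue with *elevated*
apparent diffusion coefficient (ADC). In the hyperacute window (within six
hours of symptom onset) a further structure is often visible at or just
outside the outer edema border: a thin rim that is hyperintense on b1000
diffusion-weighted images and *hypointense* on the ADC map — the
perihematomal diffusion-restriction rim (PDR). The rim is of interest because
restricted diffusion is the imaging signature of cytotoxic processes, yet in
this setting it appears to reflect transient oligemic or metabolic changes
rather than frank ischemia.

`pdrim` turns the manual reading-room procedure for this measurement into an
automated, reproducible pipeline:

1. co-register the modalities (integer-translation registration to the ADC
   grid),
2. contour the hematoma on T2*/SWI and refine its border against FLAIR
   (susceptibility blooming makes the clot look about 20% larger than it is),
3. contour the whole lesion (hematoma + edema) on FLAIR and obtain the edema
   by subtraction (`PHE = LESION − IPH`),
4. reflect the lesion across the midsagittal plane into healthy contralateral
   tissue and adjust it into a *mirror region*,
5. call a voxel rim tissue when it is **both** hypointense on ADC —
   at or below `mirror median − 1.5 × mirror SD` — and hyperintense on
   b1000 — at or above `mirror median + 1.5 × mirror SD`,
6. quantify: ROI volumes in cc, P25/mean/median/P75 of ADC, and relative ADC
   (rADC = ROI median ADC / mirror median ADC).

Because no patient images are distributed with the underlying study, the
package ships a synthetic-phantom and synthetic-cohort generator that
reproduces the *statistical* structure the procedure relies on, so that every
stage is testable end to end without any data download.

## The threshold rule

The detection rule quantifies "hypointense on ADC" against each patient's own
healthy tissue. With mirror-region median $m$ and voxelwise standard
deviation $s$ of the ADC map,

$$\text{rim candidate voxel } v:\quad
\mathrm{ADC}(v) \le m - k_a s
\quad\text{and}\quad
\mathrm{b1000}(v) \ge m_b + k_b s_b,$$

with $k_a = k_b = 1.5$ by default. Both cutoffs are inclusive. The reading
"1.5 standard deviations *of* the median" is implemented as
`median − 1.5 × SD` — the only interpretation that uses both statistics. The
SD is taken over mirror voxel values (not per-slice medians). The b1000
criterion mirrors the ADC rule symmetrically; the original visual criterion
("hyperintense") is not otherwise quantifiable.

Candidate voxels are restricted to the edema mask plus a 2-voxel shell
outside the lesion border — the rim is described both *within* the edema and
*adjacent to its outer border*, and both readings stay reachable through
`shellVoxels`. Components smaller than 0.05 cc are discarded
(26-connectivity throughout), and a case is called rim-positive when the
detected volume is at least 0.1 cc. The smallest typical rim reported in
patients is an order of magnitude larger (P25 ≈ 0.97 cc), so the cutoff is
conservative; it is configurable (`minPositiveCC`).

Raising $k_a$ can only shrink the candidate voxel set, so detected rim
volume is monotone non-increasing in the ADC factor — a property the test
suite asserts.

## The phantom generator

`defaultPhantomSpec()` describes a 64 × 64 × 48 lattice at 2 mm isotropic
spacing holding a left-right symmetric brain ellipsoid (semi-axes 58, 58,
44 mm). One hemisphere contains a solid hematoma ellipsoid (14 × 11 × 11 mm
semi-axes, ≈ 7 cc), a 7 mm edema shell and, when `pdrPresent`, a 4 mm rim
shell immediately outside the edema. Geometry is deterministic; lesions that
would touch the midsagittal plane or leave the brain are rejected.

Signals are rendered per compartment:

| compartment | ADC median (IQR), 10⁻⁶ mm²/s | FLAIR | b1000 | T2* |
|---|---|---|---|---|
| background brain | 790 (750–830) | 100 | 100 | 100 |
| IPH (clot) | 789 (710–890) | 140 | 100 | 40 |
| PHE (edema) | 1030 (948–1110) | 180 | 100 | 100 |
| PDR (rim) | 624.5 (598.5–670) | 100 | 140 | 100 |

The three lesion-compartment ADC distributions are the values measured in
hyperacute hemorrhage patients; background brain is set to a typical
supratentorial parenchyma value of 790 so that the mirror reference is
realistic and the printed rADC bounds (rim below 90%, edema above 110%)
emerge rather than being imposed. ADC is drawn from a *split normal*
parameterized by (median, P25, P75): separate normal scales below and above
the median, `σ = |quartile − median| / qnorm(0.75)`, which honours the
asymmetric printed IQRs exactly. Only medians and IQRs are published, so the
distribution family is a modeling decision, not a data fact.

FLAIR, b1000 and T2* are unitless signal levels — the pipeline only uses
their *contrasts*, never absolute values, so no MR physics is simulated.
Additive Gaussian noise (SD 20 for ADC, 5 for the unitless modalities)
is applied last. Note one consequence: convolving the asymmetric split
normal with symmetric noise shifts the sample median a few units towards the
longer tail (the pooled rim median recovers at ≈ 628 rather than 624.5),
well inside the recovery tolerance but visible.

T2* blooming is rendered by scaling the clot ellipsoid radii by
`(1 + f)^(1/3)` with `f = 0.20`, which inflates the hypointense footprint by
exactly 20% in volume. Discrete mask dilation was rejected because a
one-voxel shell at 2 mm spacing overshoots 20% by a factor of two.

The default 2 mm isotropic grid departs from the acquisition geometry of the
source protocols (≈ 0.9 mm in-plane, 6.5 mm slice spacing): the 4 mm rim and
the ≈ 1 mm blooming margin must be resolvable along every axis for shell
geometry and its tests to be meaningful. Anisotropic grids, with the slice
*spacing* as the third voxel dimension of a contiguous resampled grid, are
fully supported via `spacing`; volumetry always uses the spacing product.

### What the phantoms do not emulate

Phantom results demonstrate that the *procedure* is correct, not that it
works on arbitrary clinical data. The phantoms have exact left-right
symmetry, ellipsoidal compartments, spatially uncorrelated Gaussian noise,
no bias fields, no skull or CSF, no partial-volume mixing, and a rim that is
a complete shell rather than the patchy, incomplete rims seen in patients
(whose volumes are correspondingly smaller, ≈ 2 cc). Registration is
integer-translation only — adequate for phantoms, a simplification of
six-degree-of-freedom clinical registration.

## Hematoma border refinement

The T2* hypointense component includes the blooming margin. The FLAIR border
is recovered by splitting the FLAIR intensities inside the component into
two classes with quartile-initialized 1-D k-means and keeping the class that
dominates the one-voxel-eroded core: the clot is the interior of the
component, and the margin is a boundary shell of surrounding tissue whatever
its FLAIR contrast (brighter edema when an edema ring exists, darker
background when it does not). The refinement only engages when the class
centres are separated by more than twice the pooled within-class SD, so a
blooming-free clot is never eroded. K-means is initialized at the FLAIR
quartiles, making the whole segmentation deterministic.

## The synthetic cohort

`makeCohort()` draws patient records matching the marginal structure of an
83-patient hyperacute series: rim prevalence 56/83 (= 67.5%), 54/83 male,
gender-specific age distributions (males 64 [54.75–73.25] years, females 71
[58–80.5]), hematoma volume 12.9 (7.9–26.6) cc, admission NIHSS 11 (7–15),
onset-to-MRI bins weighted (19, 32, 10, 3, 2, 2, 15)/83 including a wake-up
stratum, locations 66 deep / 15 lobar / 2 infratentorial, removal 4/83 and
mortality 7/83. Skewed quantities (volumes) are log-normal with quartiles
matched on the log scale; bounded scores are split-normal draws rounded and
clamped to [0, 42].

Rim and hematoma volumes are coupled by a log-linear link whose log-scale
Pearson correlation defaults to 0.652. The correlation is defined and
reported on the log scale: volumes are log-normal, the multivariate model
enters hematoma volume as `log IPH volume`, and the raw-scale sample
correlation of log-normal pairs is a badly behaved estimator (its sampling
error is dominated by the heaviest observations even at thousands of
records).

Rim positivity is drawn independently of age and gender
(Bernoulli with the marginal prevalence): the generator reproduces the
baseline *marginals*, not the multivariate risk structure, so recovering the
published adjusted odds ratios from synthetic cohorts is out of scope; the
logistic machinery is instead validated by parameter recovery on designs
with known coefficients. Wake-up cases receive a latent onset time uniform
in (0, 6] h; whether their wider published ADC spread reflects onset-time
spread or measurement noise is not determinable from the source, and the
generator does not link ADC to time.

## The statistical battery

All tests are implemented in the package (base R's versions serve as
independent cross-checks in the test suite):

* **Pearson χ² (2×2)** — uncorrected; the continuity-corrected statistic
  would not reproduce the published gender value of 1.430.
* **Fisher exact (2×2, two-sided)** — point-probability ordering: the
  two-sided p is the sum of hypergeometric point probabilities not exceeding
  that of the observed table. This convention reproduces the published
  0.299 (removal) and 0.103 (supra/infratentorial) values by enumeration.
  One published value (mortality, p = .711) is *not* reproducible under this
  (or Yates/mid-p) convention from its printed counts [[5, 51], [2, 25]],
  for which enumeration gives 1.0; the package reports the computed value.
* **Mann–Whitney U** — exact two-sided p (doubled smaller tail of the exact
  U distribution) for untied samples with `min(n) ≤ 8`; otherwise normal
  approximation with tie and continuity corrections.
* **Kruskal–Wallis** — H with tie correction, χ² p on k − 1 df.
* **Pearson correlation** — product-moment r with the two-sided t-based p.
* **Logistic regression** — maximum likelihood by IRLS (tolerance 1e-8 on
  the log-likelihood, ≤ 100 iterations), Wald 95% CIs on the odds scale.
  Perfect separation is flagged (`converged = FALSE`) by the log-likelihood
  reaching numerical zero, and coefficients are reported with a warning.
  Covariates follow the published model: male gender, age per 10-year
  interval, deep location (deep = 1, all others 0; the two infratentorial
  patients are retained), onset-to-MRI time in hours (bin midpoints, wake-up
  cases at 3.0 h — the source does not state how they were entered), NIHSS
  at admission, log hematoma volume. The source labels the resulting
  exponentiated coefficients "HR"; they are odds ratios and are reported as
  such.

Two-sided p < .05 is the significance convention; no multiple-testing
correction is applied, matching the source analysis.

## Numerical conventions and degenerate inputs

* Quantiles: linear interpolation between order statistics
  (`type = 7`), applied to ROI statistics and generator calibration alike.
* PDR voxels are excluded from PHE statistics when the masks overlap
  (configurable via `excludePDRfromPHE`); the source does not state its
  handling.
* Inclusive comparisons for the detection thresholds and the positivity
  cutoff. The T2* hypointensity and FLAIR hyperintensity screens use strict
  inequalities so that a featureless (zero-variance) image selects nothing
  rather than everything; a hematoma below 0.1 cc yields an empty mask
  *flagged*, not an error, while an empty mirror region or a non-nested
  subtraction is a hard error.
* Registration ties are broken by smallest shift magnitude, then
  lexicographic order; zero-variance images are a registration error.
* Masks use 0-based voxel index semantics in all documentation; the
  reflection axis is the first lattice axis and the midsagittal plane its
  central plane.
* All randomness flows from explicit integer seeds; `(spec, seed)`
  regenerates any phantom or cohort bit-identically, and the pipeline writes
  a manifest with a configuration hash so any rim call can be audited
  against the thresholds actually applied.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations as follows:
compartment-recovery checks pool 20 default phantoms (≈ 56,000 rim voxels);
detection operating characteristics use 50 phantoms, half with a rim;
threshold monotonicity is evaluated on factor grid 1.0/1.5/2.0/3.0;
prevalence checks average 200 cohorts of n = 83; the volume-coupling
correlation pools 40 cohorts (≈ 2,250 rim-positive records); logistic
parameter recovery uses 20 synthetic designs of n = 500. These sizes give
the stochastic quantities sampling errors comfortably below the tolerances
asserted on them.

## Known limitations

* The rim is a geometric shell; patchy partial rims, and hence realistic
  per-case rim volumes, are not emulated (cohort-level rim volumes are drawn
  from the published distribution instead).
* Only translation misregistration is simulated and corrected.
* ADC values are not linked to time from onset, so the published step-wise
  ADC normalization over time has no synthetic counterpart.
* The SPSS importer requires an explicit column map because the layout of
  the supplementary patient file is undocumented.
* b1000 and FLAIR are unitless; any analysis depending on absolute
  signal calibration is out of scope, as is MR sequence simulation.
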