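---
title: "Compartmental uptake analysis of amino acid PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental uptake analysis of amino acid PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcu)
```

## The problem

Gliomas reprogram amino acid metabolism, and the spatial pattern of
O-(2-¹⁸F-fluoroethyl)-L-tyrosine (¹⁸F-FET) uptake on static PET carries
information about tumor genotype. `petcu` quantifies that pattern by splitting
a lesion's metabolic volume into two isocontour compartments relative to the
lesion's maximum standardized uptake value (SUVmax):

* **central compartment (ROI₈₀)** — voxels between 80% and 100% of SUVmax;
* **peripheral compartment (ROI₆₀)** — voxels between 60% and 75% of SUVmax;
* **total metabolic volume (MTV₆₀)** — voxels between 60% and 100%, which also
  contains the unnamed 75–80% "gap" band separating the two compartments.

The **compartmental uptake (CU) ratio** is peripheral over central, either as
a ratio of volumes (*volumetric CU ratio*) or of mean SUVs (*SUV CU ratio*).
IDH-mutant gliomas tend to carry a proportionally larger peripheral
compartment than IDH wild-type tumors, so the volumetric CU ratio acts as a
noninvasive genotyping biomarker. The package also computes the
absolute-threshold metabolic tumor volume (MTV, ≥ 1.8 × contralateral
background mean), the mean target-to-background ratio (TBR, mean SUV of
ROI₈₀ over the background mean), and Dice/Jaccard overlap between
segmentation masks.

Because no patient images are distributed with the study this package
re-implements, all quantitative claims are validated on a synthetic phantom
cohort with analytically known compartment volumes (below).

## Segmentation procedure

Given a co-registered SUV volume and a lesion mask (the package consumes
masks; it does not produce them from MRI):

1. optional exclusion masks (large intracranial vessels) are subtracted;
2. multifocal masks are reduced to the *target lesion*: the largest
   26-connected component, ties broken by higher contained SUVmax, then by
   lowest linear index. "Prominence" is not defined more finely than volume,
   so volume-then-peak is the deterministic reading we fixed;
3. SUVmax is the single hottest voxel inside the exclusion-corrected target
   lesion (a 26-neighbourhood-averaged "robust peak" is available behind
   `robust_peak = TRUE`, default off; by default SUVmax is measured *after*
   exclusion, switchable with `suvmax_before_exclusion`);
4. isocontour bands are thresholded inside the target lesion dilated by a
   2-voxel margin (configurable). The dilation decouples the result from the
   tightness of the anatomical mask while still forbidding distant
   false-positive voxels;
5. band bounds are inclusive on both ends: a voxel at exactly 0.75·SUVmax is
   peripheral, at exactly 0.80·SUVmax central. The 75–80% band belongs to
   MTV₆₀ only, so ROI₆₀ and ROI₈₀ are disjoint by construction;
6. the background is the mean SUV of a 2D region of the tumor's in-plane
   shape mirrored to the contralateral side on the axial slice with the
   highest mean uptake inside MTV₆₀. If the mirrored region overlaps the
   tumor or exits the grid, it is shifted to the nearest valid in-plane
   position (increasing shift magnitude, purely lateral moves preferred).
   A strictly left-right search would leave wide midline lesions with no
   valid placement at all — a situation our centered phantoms produce
   regularly — hence the two-dimensional fallback; if not even that finds a
   disjoint position the function errors and a manual background mask must
   be supplied. An empty central compartment is likewise a hard error
   ("no central compartment"), never a silent `NaN`, because every
   downstream biomarker divides by an ROI₈₀ statistic.

## The phantom generator

A phantom is a spherically symmetric lesion whose uptake, as a *fraction of
maximum* `f(r)`, is piecewise linear through the control points
`(0, 1.0), (r80, 0.80), (r75, 0.75), (r60, 0.60)` and decays linearly to the
background fraction `background_suv / suv_max` at `1.3·r60` (constant
beyond). Voxel values are `suv_max · f(distance to center)` evaluated at
voxel centers, with no anti-aliasing. The radii are solved from the requested
band volumes (sphere-shell formulas), so every compartment volume — and hence
the volumetric CU ratio — is known in closed form before any rendering.

Two design points deserve emphasis:

* **The profile scales the maximum, not the background-to-peak range.** Only
  `value = suv_max · f(r)` puts the 60/75/80% isocontours *of the rendered
  maximum* at the analytic radii; an additive
  `background + (peak − background) · f(r)` parameterization would shift
  every contour and break the ground truth. The far field still equals the
  background SUV exactly because `f` ends at the background fraction.
* **The lesion center snaps to a voxel center** (nearest the grid centroid by
  default). With an off-lattice center the rendered maximum underestimates
  `suv_max` by up to the profile drop across half a voxel, which propagates
  into every relative threshold; snapping makes the rendered maximum exact
  and the measured thresholds unbiased. An explicit `center_mm` overrides
  the snap when that bias is itself the object of study.

Default geometry is a 96×96×64 grid at 1.0×1.0×2.3 mm — a typical PET
reconstruction voxel — and the default `gap_fraction` (volume of the 75–80%
band as a fraction of the peripheral volume) is 0.25. Nothing constrains
that band in the source material; it is a free, documented knob and stays
configurable.

## Cohort calibration

`cohort_params()` encodes a two-genotype cohort of 21 IDH-mutant and 31
wild-type subjects. Per genotype the true volumetric CU ratio is log-normal:

* medians 7.84 (mutant) and 3.92 (wild-type);
* a common log-SD `sigma_log_cu = (ln 7.84 − ln 3.92) / (√2 · Φ⁻¹(0.88)) ≈
  0.417`, chosen so the *population* AUC of the two distributions is exactly
  0.88 (`population_auc()` gives the closed form). Calibrating to the AUC
  rather than to the reported IQRs is deliberate: the IQRs imply a slightly
  different overlap, and the AUC is the headline diagnostic claim.

Central-compartment volumes are log-normal with medians 5.33/7.84 ≈ 0.680 cm³
(mutant) and 2.78/3.92 ≈ 0.709 cm³ (wild-type), so that the median
peripheral volume — the product of two independent log-normal medians —
reproduces 5.33 and 2.78 cm³. `sigma_log_vc = 0.5` is a free spread
parameter that leaves the medians untouched. Peak SUV is uniform in 2–4 ×
background, consistent with a TBR scale around 2–3; background SUV is 1.

The calibrated cohort renders **noise-free**: the cohort parameterization
deliberately carries no noise term, because the calibration is defined on
the analytic profile and additive noise would bias the measured SUVmax (the
maximum of many noisy voxels) and hence every relative threshold. Gaussian
noise and hot vessel blobs are explicit per-phantom options for robustness
experiments, not part of the calibrated conditions. Draws whose outer radius
would not fit the grid margin are redrawn (bounded retries); on the default
grid this truncates only a negligible extreme tail, and the rare lesion too
large for any contralateral background placement is quarantined by the
pipeline rather than silently dropped.

What the phantom does *not* emulate: brain anatomy, scanner point-spread
(the ~6 mm FWHM of a real system), partial-volume effects, multifocality,
and non-spherical lesion shapes. Passing calibration tests therefore shows
that the *measurement chain* is unbiased on ideal geometry at clinical voxel
sizes — not that the biomarker's clinical effect size is reproduced in real
tissue.

## Statistical layer

* **DeLong ROC.** Empirical AUC via the Mann–Whitney estimator with ties
  counted ½ (phantom grids can produce ties even though clinical ratios
  rarely do), standard error from the placement-value variances, and a Wald
  95% CI on the AUC scale clipped to [0, 1] — the simplest defensible CI
  dialect; the original study's software CIs are not reproducible without
  its data. The direction is auto-chosen so AUC ≥ 0.5 and recorded
  (`"greater"`: score > threshold ⇒ positive; `"less"`: score ≤ threshold).
  Paired AUCs are compared with the DeLong covariance of placements.
* **Youden cutpoint.** Candidates are midpoints between consecutive sorted
  unique scores plus ±∞; ties in J resolve to the smallest threshold.
  Accuracy is reported at the chosen cutpoint (prevalence-dependent, as in
  the clinical report). `evaluate_threshold()` applies a frozen cutpoint to
  held-out data.
* **Nonparametric tests.** Mann–Whitney U (min-U convention; exact p from
  the null rank-sum distribution when n₁+n₂ ≤ 12 without ties, else normal
  approximation with tie and continuity correction), one-tailed Wilcoxon
  signed-rank (zeros dropped and counted; exact for n ≤ 12), Kruskal–Wallis
  (tie-corrected H via `kruskal.test`) with Dunn post hoc z tests, and
  Spearman correlation (exact permutation p for n ≤ 8, t approximation
  beyond). The n ≤ 12 / n ≤ 8 exactness cutoffs keep full enumeration
  desk-scale; beyond them the approximations are standard and documented.
  Multiplicity uses the Holm–Šídák step-down
  (`1 − (1 − p₍ᵢ₎)^{m−i+1}` with enforced monotonicity).
* **Logistic accuracy.** One-covariate maximum-likelihood logistic fit
  (IRLS via `glm`); *predictive accuracy* is the fraction classified
  correctly at predicted probability 0.5 — we read the ambiguous
  "P value cutoff of 0.5" as a probability cutoff, the only reading under
  which accuracy is well defined; complete separation is detected and
  flagged rather than hidden. A related oddity is deliberately not
  reproduced: matched-pair statistics labelled "Kendall W" with values like
  −165 in the source tables are not the Kendall coefficient of concordance;
  the package reports the standard signed-rank W instead.

## Pipeline and reproduction study

`run_cohort()` walks a manifest (CSV of subject → NIfTI paths → molecular
labels), quarantining failed subjects with reasons and aborting above 10%
failures. `genotyping_experiment()` mirrors the two-stage evaluation: a
stratified random split (largest-remainder allocation, even 26/26 split by
default; degenerate splits reshuffle with an incremented sub-seed), the
Youden threshold frozen on the training side, and
sensitivity/specificity/accuracy reported on the evaluation side at that
frozen threshold. `reproduce_study()` chains generator → renderer →
compartments → biomarkers → statistics, always measuring from the rendered
images and never from the sampled ground truth; `write_study_report()`
serializes records, comparisons, ROC curves and a JSON summary. Published
decision thresholds (5.49 whole-cohort, 5.43 training, TBR 2.73) ship as
`fet_reference_thresholds` for annotation only — no package decision ever
defaults to them.

Quantiles everywhere (medians, IQRs) use linear interpolation (type 7), the
R default, fixed and documented since the upstream software's rule is
unknown. All randomness flows through explicit integer seeds: one stream per
sampled cohort, one per split.

## Numerical choices and test scale

* Geometry checks demand identical shape and orientation and spacing within
  1e-4 relative; no resampling is ever attempted (inputs are co-registered
  upstream, and silent interpolation of masks would corrupt overlap
  indices).
* Volumes are exact voxel counts × voxel volume in double precision;
  rounding happens only in printed reports.
* On noise-free phantoms the measured volumetric CU ratio converges to the
  analytic value as resolution grows; the surface-voxel error is the only
  error source. The test suite asserts ≤ 10% recovery whenever
  r₈₀ ≥ 5 voxels and convergence on a 0.2/0.25/0.40 "linear cone" whose
  closed-form CU ratio is 6.046875.
* The calibration suite simulates 20 seeded 52-subject cohorts on the
  default grid (≈ 1,000 rendered lesions), the size at which seed-averaged
  medians stabilize to a few percent; statistical-validity checks use
  10,000 null simulations at the design group sizes (21 vs 31) and a
  2,000-replicate subject-level bootstrap against the DeLong SE.

## Known limitations

* The spherical, monotone-profile phantom cannot probe irregular lesion
  shapes, necrotic cores (non-monotone profiles), or PSF blur; the SUV CU
  ratio of the default profile sits near 0.78 but is not separately
  calibrated per genotype.
* The absolute MTV and TBR depend on the automated background ROI; on real
  images with inhomogeneous background the mirrored estimate can differ
  from a manually placed one, which the manifest accepts as an override.
* DeLong CIs are Wald-clipped, slightly anticonservative near AUC = 1 at
  small n.
* The package consumes lesion masks; MRI segmentation, registration and SUV
  computation from raw activity are out of scope.
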