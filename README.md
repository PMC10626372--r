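# petcu

Compartmental uptake (CU) analysis of static ¹⁸F-FET PET for glioma
genotyping, with a calibrated synthetic phantom cohort for end-to-end
validation.

## What it does, and for whom

Gliomas with different IDH genotypes distribute amino-acid tracer uptake
differently across the lesion. For imaging scientists working with
O-(2-¹⁸F-fluoroethyl)-L-tyrosine (FET) PET, `petcu` quantifies that spatial
heterogeneity from a co-registered SUV volume and a lesion mask (NIfTI):

- **Isocontour compartments** relative to the lesion maximum SUV:
  central ROI₈₀ (80–100% of SUVmax), peripheral ROI₆₀ (60–75%), total
  MTV₆₀ (60–100%), plus the absolute-threshold MTV (≥ 1.8 × contralateral
  background mean) and a mirrored 2D contralateral background ROI.
- **Biomarkers** per lesion: volumetric CU ratio
  `vol(ROI₆₀) / vol(ROI₈₀)`, SUV CU ratio
  `mean SUV(ROI₆₀) / mean SUV(ROI₈₀)`, mean target-to-background ratio
  `TBR = mean SUV(ROI₈₀) / background`, compartment volumes in cm³, and
  Dice `2|X∩Y|/(|X|+|Y|)` / Jaccard `|X∩Y|/|X∪Y|` overlaps between masks.
- **Inference**: DeLong ROC (AUC, SE, CI, paired AUC comparison),
  Youden-optimal cutpoints with frozen-threshold evaluation on held-out
  subjects, Mann–Whitney U / Wilcoxon signed-rank / Kruskal–Wallis + Dunn,
  Holm–Šídák adjustment, Spearman correlation, logistic predictive
  accuracy.
- **A phantom module**: single-lesion SUV volumes with a monotone radial
  profile whose compartment volumes are known in closed form, and a
  two-genotype cohort generator (21 IDH-mutant vs 31 wild-type) calibrated
  so the population medians of the volumetric CU ratio are 7.84 / 3.92,
  the median peripheral volumes 5.33 / 2.78 cm³, and the population AUC
  0.88. Every downstream stage is testable without patient data.

Tabular results are tibbles, stats verbs are data-frame-first, and fitted
objects have `tidy()` / `glance()` / `autoplot()` methods.

## Worked example

Render a phantom whose peripheral and central compartments match the
published mutant-group medians, then measure it back through the image
pipeline:

```r
library(petcu)

spec <- phantom_spec(v_central = 0.68, v_peripheral = 5.33, suv_max = 3)
ph   <- render_phantom(spec)
set  <- extract_compartments(ph$volume, ph$lesion)
lesion_record(ph$volume, set, subject_id = "phantom-01")
#> suv_max         3.000
#> v_mtv60_cm3     7.275
#> v_roi60_cm3     5.216
#> v_roi80_cm3     0.655
#> cu_volumetric   7.958
#> cu_suv          0.780
#> tbr_mean        2.483
ph$ground_truth[, c("volumetric_cu_true", "suv_cu_true")]
#>   volumetric_cu_true suv_cu_true
#>                7.838       0.782
```

The measured volumetric CU ratio (7.96) recovers the analytic truth (7.84)
to within the surface-voxel error of the 1.0×1.0×2.3 mm grid; the SUV CU
ratio (0.780) sits in the narrow band characteristic of this profile.

A full synthetic study — sample the calibrated cohort, render all 52
subjects, extract biomarkers from the images, compare groups, and run the
split/threshold genotyping experiment:

```r
report <- reproduce_study(cohort_params(seed = 11))
report
#> <cu_study_report> 52 subjects (21 mutant / 31 wildtype), seed 11
#>   volumetric CU ratio: median 8.01 (mut) vs 4.49 (wt), AUC 0.888
#>   genotyping split: train threshold 5.00, eval accuracy 0.77

glance(report$roc$cu_volumetric)
#> whole-cohort AUC 0.888 (95% CI 0.796-0.979), Youden threshold > 5.88

report$group_comparisons[1, c("biomarker", "median_mutant",
                              "median_wildtype", "p_value")]
#>   cu_volumetric  8.01  4.49  <0.001
```

Here the mutant group's larger peripheral compartment drives a volumetric
CU ratio roughly twice the wild-type median, and the Mann–Whitney test
rejects decisively; single-seed medians and AUCs scatter around the design
values (7.84 / 3.92, AUC 0.88) and stabilize when averaged over seeds.
`autoplot(report$roc$cu_volumetric)` draws the ROC curve with the Youden
operating point; `write_study_report(report, "out/")` serializes records,
comparisons, ROC curves, and a JSON summary.

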