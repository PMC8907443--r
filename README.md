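# deltarad

Delta-radiomics analysis of longitudinal low-field MR images acquired
during MR-guided radiotherapy (MRgRT), built for the question: *can the
change of quantitative GTV descriptors during neoadjuvant
chemoradiotherapy of locally advanced rectal cancer predict 2-year
disease-free survival (2yDFS)?* The intended users are radiation
oncology / medical physics groups who have longitudinal GTV
segmentations and want the complete, reproducible analysis chain — plus
a synthetic cohort generator so every stage can be exercised and tested
without patient data.

## What it computes

* **BED alignment.** Imaging timepoints are aligned across fractionation
  schemes by biologically effective dose,
  `BED = n·d·(1 + d/(α/β))` with `α/β = 10 Gy`, at the imaging levels
  13, 26, 40, 54, 67 Gy. For a 2.2 Gy × 25 boost scheme these fall on
  fractions 5, 10, 15, 20, 25 (weekly imaging).
* **Feature extraction.** An IBSI-style catalog of 97 features per
  (image, GTV-mask) pair: 15 morphological (volume, mesh surface area,
  the surface-to-volume ratio `AV` in mm⁻¹, sphericity, axes, …),
  22 first-order, 60 textural (GLCM at Chebyshev distances 1–2 averaged
  over the 13 unique 3D directions, plus run-length features). Over six
  timepoints this gives 582 basal features per patient.
* **Delta features.** Every feature as a ratio to its simulation-scan
  value, `f(t_k)/f(t_0)`, named `<feature>(d<k>)` — 485 per patient.
  `morph_av_ratio(d4)` is the AV change at the 54-Gy level.
* **Statistics.** Two-sided Wilcoxon–Mann–Whitney screening of every
  variable (no multiplicity correction, but the expected false-positive
  count is reported), per-feature AUC (`= U/(n₁n₀)`), Pearson redundancy
  analysis, logistic models (chemo-only, best delta feature, combined)
  with separation-safe IRLS, bootstrap ROC (2,000 stratified resamples,
  BCa 95% CI) and the Youden operating threshold.
* **ERI.** The early regression index from GTV volumes, screened per BED
  level.
* **Synthetic cohorts.** Six-timepoint shrinking, textured tumour
  phantoms (NIfTI + manifest + clinical CSV) whose outcome labels are
  drawn from a logistic model on the *measured* delta surface-to-volume
  ratio at the 4th BED level — a known-answer world for the whole
  pipeline.

## Worked example

```r
library(deltarad)

cohort <- simulate_cohort(cohort_config(n_patients = 48, rng_seed = 11))
cohort
#> mrgrt_cohort: 48 patients x 6 timepoints, 8 events (16.7%)

basal <- extract_cohort_features(cohort)           # 48 x 582
delta <- delta_from_basal(basal)        # 48 x 485
tab   <- assemble_variable_table(basal, delta,
                                 clinical_design(cohort$clinical))

sr <- screen_features(tab)
sr
#> screening: 1082 variables tested, 42 significant at p < 0.05
#> expected false positives under the global null: 54.1
#>                           variable class            p      auc rank
#>                 morph_av_ratio(d4) delta 1.317933e-05 0.993750    1
#>            morph_bbox_extent@bed54 basal 5.694233e-05 0.956250    2
#>               morph_sphericity(d4) delta 5.694233e-05 0.956250    3
#>  ...

set.seed(2)
build_models(tab, screening = sr)
#> best delta feature: morph_av_ratio(d4)
#>                      Model Sensitivity Specificity Threshold J_index   AUC AUC_Low AUC_High
#>                      Chemo        0.75       0.475     0.222   0.225 0.613   0.388     0.75
#>         morph_av_ratio(d4)        1.00       0.975     0.427   0.975 0.994   0.950     1.00
#>   Chemo+morph_av_ratio(d4)        1.00       0.975     0.404   0.975 0.994   0.950     1.00
```

Reading the output: the generator embedded its outcome signal in the
surface-to-volume change at the 54-Gy level, and screening recovers
exactly that variable at rank 1 (its functional relatives — sphericity,
compactness, the basal shape features at 54 Gy — line up right behind
it, as they must). The chemotherapy-only model is near chance on this
cohort; the delta-feature model dominates. Thresholds are on the
fitted-probability scale; `J_index = sensitivity + specificity − 1`.
Because events are rare (8 of 48), bootstrap CIs are wide and a strong
feature can separate the classes — separation is flagged and handled by
a ridge refit, never hidden.

The same chain can be driven stage by stage on disk artifacts
(NIfTI images + CSV manifests) with

```r
run_pipeline("all", default_pipeline_config(out_dir = "run1", seed = 1))
```

or from a shell: `inst/cli/deltarad all --config cfg.json --seed 1 --out run1`.

## More

The methods vignette (`vignettes/delta-radiomics-methods.Rmd`) documents
the model, every numerically consequential choice (mesh construction,
discretization, bootstrap CI flavour, tie-breaks), what the synthetic
cohort does and does not emulate, and known limitations.
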