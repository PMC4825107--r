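# puvfcd

Voxelwise detection of focal cortical dysplasia (FCD) lesions in T1-weighted
3D brain MRI by **positive unanimous voting** (PUV) over four Gaussian
discriminant classifiers.

FCD is a malformation of cortical development and a major cause of
drug-resistant epilepsy. On T1 images a lesion shows cortical thickening,
blurring of the gray/white junction, and a GM-like signal in the subjacent
white matter — each subtle, and each common enough in healthy cortex that
single voxel classifiers drown the lesion in false positives. This package
implements a detector built on intersection rather than averaging: a voxel
is called lesional only when naive Bayes, linear discriminant, quadratic
discriminant, and Mahalanobis discriminant classifiers *all* vote lesional,

    L_PUV(v) = ∏_j L_j(v),   L_j(v) ∈ {0, 1},

so the PUV positive set is contained in every single classifier's positive
set and per-subject false positives are bounded by the best individual
classifier — a property the test suite asserts on every run, not an
aspiration.

The classifiers run on voxelwise cortical feature maps — GM thickness (F1),
intensity gradient (F2), relative intensity (F3), gray/white boundary width
(F4) — and on their differences from a **normative model** of healthy
controls: the local mean over a 3×3×3 window averaged across the K controls,

    F_mu,i(v) = 1/(K·N) Σ_k Σ_n F_i^(k)(v_n),   Fd_i(v) = F_i(v) − F_mu,i(v).

Candidate voxel maps are refined by morphological opening (3³ window) and a
connected-region size filter (regions under 112.5 mm³ are relabelled
healthy, 26-connectivity); any surviving region makes the subject-level call
"patient". Evaluation is leave-one-out cross-validation with voxel- and
subject-level TPR/FPR/precision/F-score.

Because the original clinical cohort is not public, the package includes a
phantom generator: aligned cohorts of spherical-shell "brains" with
spherical-harmonic gyral perturbation, analytic partial-volume maps, and
lesions carrying the three FCD signatures with independent, ground-truthed
dials. See the methods vignette (`vignettes/puv-fcd-methods.Rmd`) for the
model, parameters, and design decisions.

## Worked example

Fit the detector on a small synthetic cohort and detect the lesion of one
patient:

```r
library(puvfcd)
cohort <- generate_cohort(5, 3, seed = 20)   # 5 controls + 3 patients, 64^3 @ 1 mm
config <- puv_config(seed = 2)
model  <- puv_fit(cohort, config)
print(model)
#> <puv_model> PUV detector on FG6 (Fd1, Fd3, Fd4)
#>   normative: 5 controls, N = 27; training voxels: 10230 pos / 102300 neg
#>   classifiers: NB + LDA + QDA + MDA; Lw = 3, Ts = 112.5 mm^3, 26-connectivity

det <- predict(model, cohort[[8]])
print(det)
#> <puv_detection> subject patient03
#>   NB   positives: 1774
#>   LDA  positives: 1287
#>   QDA  positives: 2785
#>   MDA  positives: 1618
#>   PUV  positives: 1287 (opened 1155, filtered 1155)
#>   call: patient

detection_voxel_metrics(det, "filtered")
#> <puv_metrics> TPR 0.3731  FPR 0.0000  precision 1.0000  F 0.5434
```

Reading the output: each single classifier marks 1.3k–2.8k of the ~35k
cortical-domain voxels; unanimity keeps their intersection (1287 voxels,
all inside the true lesion here — precision 1.0), opening trims 132 border
voxels, and the surviving region (1155 voxels ≥ 112.5 mm³) makes the
subject a patient. For honest numbers use `puv_loocv(cohort, config)`,
which refits normative model and classifiers without the held-out subject;
`plot(det)` shows a lesion slice with the truth outline.

A command-line wrapper for cohort generation, detection, and LOOCV lives at
`inst/scripts/puv-fcd.R`.

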