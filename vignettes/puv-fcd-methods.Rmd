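---
title: "Detecting focal cortical dysplasia by positive unanimous voting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting focal cortical dysplasia by positive unanimous voting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puvfcd)
```

## The problem

Focal cortical dysplasia (FCD) is a malformation of cortical development and
a leading cause of drug-resistant epilepsy. On T1-weighted MRI an FCD lesion
shows up as a combination of three subtle signatures: focal **cortical
thickening**, **blurring of the gray/white matter junction**, and an
**abnormal signal** in the subjacent white matter, whose T1 manifestation is
white matter drifting toward gray-matter intensity. Each signature alone is
weak and common in healthy variation; voxel classifiers built on such
features produce many false-positive voxels, and false positives are what
make automated candidate maps useless to a radiologist.

`puvfcd` implements a voxelwise detector built around a simple remedy:
classify every cortical voxel with **four different Gaussian discriminant
classifiers** and call a voxel lesional **only when all four agree** —
positive unanimous voting (PUV). Because the PUV positive set is the
intersection of the four single-classifier positive sets, its false-positive
count is bounded above by the best single classifier on every subject; that
containment is an algebraic fact, and the package asserts it on every
cross-validation run rather than merely hoping for it.

## Pipeline

The detector runs in five stages over a cohort of pre-aligned,
brain-extracted volumes on a common grid:

1. **Intensity normalization** (`standardize_intensity`,
   `histogram_peak_overlap`, `resample_trilinear`). Intensities are rescaled
   so the 1st/99th in-brain percentiles map to 0/255. A query volume is
   accepted when its GM/WM histogram peaks overlap a reference subject's by
   at least 90% (histogram intersection restricted to the peak support
   windows). Spatial registration is out of scope: the package consumes
   volumes already on one grid, and the phantom generator emits them
   directly.
2. **Feature maps** (`compute_features`). Four voxelwise maps: F1 = GM
   thickness (mm), F2 = intensity gradient magnitude (intensity/mm), F3 =
   relative intensity (proximity of the voxel's intensity to the gray/white
   boundary intensity, in [0,1]), F4 = gray/white boundary (GWB) transition
   width (mm).
3. **Normative differencing** (`fit_normative`, `feature_difference`). From
   the healthy controls, a per-feature normative map: the local average over
   a cubic 3×3×3-voxel window (N = 27), averaged over the K controls. A
   subject's difference maps Fd = F − F_mu remove the anatomy-dependent
   baseline (cortex is naturally thicker in some places); lesions stand out
   as local departures from the control norm.
4. **Unanimous voting** (`gda_fit`, `puv_combine`, `puv_decision`). Voxels
   inside the cortical domain are labelled by naive Bayes, linear
   discriminant, quadratic discriminant, and Mahalanobis-distance
   classifiers, and the four binary volumes are multiplied voxelwise. The
   closed-form decision product (`puv_decision`) is implemented separately
   from the label-volume product (`puv_combine`) and the two are required to
   agree bitwise — a consistency check between the two published forms of
   the rule.
5. **Region refinement** (`refine_labels`). Morphological opening with a
   3×3×3 window removes voxel noise and splits weak bridges; connected
   components (26-connectivity) smaller than Ts = 112.5 mm³ are relabelled
   healthy. A subject with any surviving voxel is called a patient —
   extending the voxel decision to the subject level.

Evaluation (`puv_loocv`) is leave-one-out: for each held-out subject the
normative model is refitted on the remaining controls and the classifiers on
all remaining subjects, so no information from the test subject leaks into
training. Voxel metrics (TPR, FPR, precision, F-score) are computed inside
the classification domain at three stages (raw, opened, filtered), plus
subject-level calls.

## The classifiers

All four classifiers model the two voxel classes w1 (lesional) and w2
(non-lesional) with Gaussian class-conditional densities on the feature
vector x, and differ only in the covariance structure:

* **NB** — independent features: per-feature, per-class means and SDs;
  decision by the product of univariate Gaussian likelihoods times priors.
* **LDA** — shared covariance: `g_i(x) = mu_i' S^-1 x - 1/2 mu_i' S^-1 mu_i
  + ln p(w_i)` with the pooled within-class covariance S.
* **QDA** — per-class covariances. The default is the standard quadratic
  discriminant (with the quadratic term and log-determinant). A reduced
  linear-only variant that keeps per-class covariances but drops the
  quadratic and log-determinant terms is available as
  `puv_config(qda_variant = "printed")`; both variants satisfy the voting
  equivalence, and the default is the full form because the reduced one is
  not a likelihood-based rule.
* **MDA** — nearest class mean in pooled-covariance Mahalanobis distance;
  ignores priors. Under equal priors MDA and LDA are algebraically the same
  rule (`D(w2,x) - D(w1,x) = 2 (g1(x) - g2(x))`), which the test suite
  checks to 1e-9.

Estimation is by sample moments. Numerical choices: every covariance gets a
ridge `1e-6 * trace(S)/d` on the diagonal; score ties vote negative
(conservative for a lesion detector); training negatives are subsampled to
at most 10 per positive voxel (`neg_per_pos`), with priors defaulting to the
training frequencies; features are z-scored with training statistics before
fitting (`zscore = TRUE`) — the discriminant rules are affine-covariant, so
this affects conditioning, not decisions.

## Feature groups

Features and their normative differences are organized in six candidate
groups:

| group | members | | group | members |
|---|---|---|---|---|
| FG1 | F1, F2, F3 | | FG4 | Fd1, Fd2, Fd3 |
| FG2 | F1, F2, F3, F4 | | FG5 | Fd1, Fd2, Fd3, Fd4 |
| FG3 | F1, F3, F4 | | FG6 | Fd1, Fd3, Fd4 |

`select_best_group` picks the group with the highest per-classifier F-score
average (ties broken toward the lower group index for determinism). The
package default is FG6 — the normative differences of thickness, relative
intensity, and boundary width — which drops the gradient feature: the
gradient is the one map where lesions move *down*, and its difference map is
dominated by the junction geometry that F4 already measures.

## Feature operators: concrete choices

The literature methods behind the four maps are surface- or PDE-based; this
package deliberately uses simpler volumetric operators with the same
monotone response to the lesion signatures:

* **F1 (thickness)** — paired Euclidean distance transforms: for a GM voxel
  (pv_gm ≥ 0.5), the distance to the nearest WM-side voxel plus the distance
  to the nearest CSF-side voxel. This overestimates a slab's width by about
  one voxel (distances are measured between voxel centres); the bias is flat
  and harmless to classification, and tests compare against analytic slab
  and shell geometry with that bias included. The distance transform is the
  exact Felzenszwalb–Huttenlocher separable algorithm (compiled, anisotropic
  spacing supported).
* **F2 (gradient)** — central differences scaled by voxel spacing, one-sided
  at the grid border; Euclidean norm over the three axes.
* **F3 (relative intensity)** — `1 - |Bg - I| / Bg`, clipped to [0,1], with
  Bg the midpoint of the GM and WM histogram peaks. Voxels whose intensity
  sits at the gray/white boundary intensity score 1, so junction blurring
  and GM-like lesional WM raise F3.
* **F4 (GWB width)** — the transition zone is `0.1 < pv_wm < 0.9` and
  `pv_gm > 0`; a zone voxel's width is twice its distance to the nearest
  non-zone voxel plus one voxel. A hard binary junction has an empty zone
  (F4 ≡ 0); a blurred junction widens the zone.

Classification is restricted to a **domain mask** — voxels with any GM
partial volume or inside the GWB transition zone. FCD is a cortical /
juxta-cortical pathology; classifying deep WM or CSF voxels would only
manufacture false positives from feature vectors that mean nothing there.
Voxels outside the domain are negative by construction, and metrics are
computed inside the domain, where the classifiers actually ran.

Normative windows truncated by the grid border are renormalized by their
actual size, so the local mean is unbiased at the boundary.

## The phantom generator

The clinical cohort behind the method (10 patients, 31 controls, 3T T1) is
not public, so the package ships a generator of synthetic cohorts that
reproduces the *geometry and contrast* the detector consumes: an inner WM
ball, a GM shell of configurable thickness (default 6 mm), an outer CSF
layer, T1-ordered mean intensities (WM 160 > GM 110 > CSF 30 on the 0–255
scale), additive Gaussian noise (default SD 4), and analytic partial-volume
maps obtained by 3×3×3 subvoxel sampling of the continuous geometry. A
low-order spherical-harmonic modulation of the shell radius (degrees 2–4,
peak 8% of the inner radius) stands in for gyral anatomy; within a cohort
the pattern is shared (subjects are "pre-registered") with a small
per-subject residual (1.5%), plus Gaussian jitter of tissue means (SD 2) and
ribbon thickness (SD 0.3 mm).

Lesions implement the three signatures with independent dials:
`thickening_factor` multiplies the shell thickness over a patch (plateau to
90% of the patch radius with a quadratic rim, so the nominal factor equals
the realized mean thickening); `junction_blur_sigma_mm` locally smooths the
PV maps with a Gaussian; `wm_intensity_shift` moves in-patch WM intensity
*toward* the gray/white boundary intensity — the T1 face of the
"hyperintensity" sign, which keeps the relative-intensity response
monotonically increasing in the shift. Ground truth is unambiguous: the
lesion mask is every voxel whose PV vector changed by more than 0.01 against
the unlesioned phantom, plus the shifted WM voxels.

What the phantom does **not** model: gyral folding topology, bias fields,
Rician noise, registration error beyond the residual harmonic, partial
head coverage. Tests passing on phantoms therefore demonstrate that the
machinery is correct and that the signatures are recovered where they are
present by construction — not that clinical sensitivity/specificity would
match. The published clinical numbers are used only as formula checks on
their printed counts (8/10 patients, 1/31 controls → TPR 80%, FPR 3.2%),
never as reproduction targets.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_edge` | 3 | voxels | normative window edge (N = 27 neighbours) |
| `feature_group` | FG6 | — | working feature set |
| `Lw` | 3 | voxels | morphological opening window |
| `Ts_mm3` | 112.5 | mm³ | minimum surviving region volume |
| `connectivity` | 26 | — | component adjacency (6/18/26) |
| `ridge` | 1e-6 | — | relative covariance ridge |
| `neg_per_pos` | 10 | — | training subsampling cap |
| `qda_variant` | full | — | standard vs reduced QDA discriminant |

The size threshold is configured in physical units because a voxel-count
threshold silently changes meaning with the working resolution; at 0.5 mm
isotropic spacing 112.5 mm³ is exactly 900 voxels (`ts_voxel_count`), at
the package's 1 mm working grid it is 112.5 voxels. The opening window and
Ts defaults match the published configuration; connectivity 26 is our choice
(the source does not state one), exposed in the config.

## Other numerical decisions

* **Standardization percentiles** are order statistics (inverse ECDF, no
  interpolation), which makes standardization exactly idempotent: clipping
  ties the tails at exactly 0 and 255, so repeated application is the
  identity.
* **Peak detection** smooths the 256-bin in-brain histogram with a width-5
  moving average and accepts modes in height order only when separated by ≥
  20 bins *and* by a genuine valley (dip below half the smaller peak); up to
  three modes are kept and the two brightest are the GM/WM pair, since CSF
  can out-count either tissue. A histogram without two such modes raises
  "bimodality not found".
* **Ties everywhere vote negative**: classifier score ties, the
  sign-of-zero case in the voting product, and Mahalanobis equidistance.
* **Degenerate inputs fail fast**: constant volumes (standardization),
  single-class training data, zero-variance features (named in the error),
  singular covariances after ridging, lesions clipped by the grid, folds
  without a patient or control.

## Problem sizes

The test suite exercises operators on analytic slabs and 16³ random
fixtures against brute-force oracles, phantom properties at 48³, and the
full detector by LOOCV on an 8-subject 64³ cohort (5 controls + 3 patients,
thickening 2×, blur 2 mm, WM shift 30, noise SD 4) — the same conditions
`scripts/acceptance.R` reruns from scratch. These sizes keep a full run in
a few minutes on one core while leaving every claim (containment, voting
equivalence, subject-level calls) asserted exactly, not sampled.

## Known limitations

* The spherical-shell phantom cannot probe sulcal geometry effects (buried
  lesions at the bottom of a sulcus, opercular partial volume).
* The thickness and width operators are voxel-scale approximations; at 1 mm
  spacing they carry a one-voxel bias that cancels in normative differences
  but would matter for absolute thickness reporting.
* A true lesion split by opening into sub-threshold fragments would be
  erased; region repair is deliberately out of scope.
* With very few controls the normative model inherits their idiosyncrasies;
  K ≥ 5 behaves well on phantoms, and the clinical design used K = 30
  training controls per fold.
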