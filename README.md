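# wsosvm

Weakly supervised ordinal support vector machines for mapping intra-tumoral
genetic heterogeneity from multiparametric MRI.

## The problem

Glioblastoma tumors are genetically heterogeneous: driver genes such as
EGFR, PDGFRA and PTEN can be altered in one part of a tumor and not in
another, which undermines therapies targeted at a single biopsy's genotype.
Image-localized biopsies tie a genetic label to a small MRI neighborhood,
but only a few exist per patient. This package is for researchers who want
to train a classifier on such sparse labeled data and then predict gene
status for *every* region of the tumor, producing a per-patient prediction
map.

## The model

The core is a three-source ordinal kernel classifier. Samples are 8×8-pixel
windows of five co-registered MRI contrasts (T1+C, T2, MD, FA, rCBV),
summarized by 280 radiomic features (statistical + GLCM + Gabor, 56 per
contrast). Three data sources with different supervision train one
maximum-margin model:

* labeled biopsy windows — class 1 (gene non-altered) or class 2 (altered),
* unlabeled tumoral windows — known only to be class 1-or-2,
* contralateral normal-brain windows — class 0.

The model learns a kernel decision function h(x) = wᵀφ(x) and two ordered
biases b₀ ≤ b₁; a window is class 2 if h ≥ b₁, class 1 if b₀ ≤ h < b₁,
class 0 otherwise. Labeled samples face the upper boundary with penalty C₁;
normal and all tumoral samples (labeled ones re-entered, so the class-1-or-2
block has m₁₂′ = n₁+n₂+m₁₂ members) face the lower boundary with penalty
C₂. Training solves the Lagrangian dual, a convex quadratic program in the
multipliers γ = (α⁽¹⁾, α⁽²⁾, β⁽⁰⁾, β⁽¹²⁾):

    min_γ  ½ γᵀYKYγ − 1ᵀγ
    s.t.   −Σα⁽¹⁾ + Σα⁽²⁾ − Σβ⁽⁰⁾ + Σβ⁽¹²⁾ = 0
           −Σα⁽¹⁾ + Σα⁽²⁾ ≥ 0
           0 ≤ α ≤ C₁,  0 ≤ β ≤ C₂

with Y the block sign matrix and K the Gram matrix. Around it the package
provides repeated stratified 10-fold cross-validation with two-stage
C₂→C₁ tuning, a one-sided Wilcoxon rank-sum comparison harness,
Shapley-value attribution aggregated to the MRI-contrast level, per-patient
personalization, stride-1 sliding-window prediction maps with two-gene
co-alteration maps, and synthetic cohort generators (feature-space and
image-mode) that make the whole pipeline testable without patient data.
See `vignettes/wsosvm-methods.Rmd` for the full model account.

## Worked example

```r
library(wsosvm)

ts <- generate_feature_cohort(feature_cohort_config(
  n1 = 60, n2 = 60, m12 = 60, m0 = 60, d = 10, separation = 5, seed = 42))
fit <- wsosvm_fit(ts, C1 = 1, C2 = 1, kernel = kernel_spec("rbf"))
fit
#> Weakly supervised ordinal SVM
#>   blocks: n1 = 60  n2 = 60  m12 = 60  m0 = 60
#>   kernel: rbf (gamma = 0.1)   C1 = 1  C2 = 1
#>   biases: b0 = -1.62361  b1 = 1.28968  support vectors: 78
```

The fitted object holds the support expansion of h, the two boundaries
(windows with h below b0 = −1.62 are called normal brain, above
b1 = 1.29 gene-altered), and the feature scaler. Training-set predictions
separate the labeled classes perfectly here because the synthetic classes
are 5 within-class SDs apart:

```r
table(true = rep(1:2, each = 60), predicted = classify(fit, rbind(ts$X1, ts$X2)))
#>     predicted
#> true  1  2
#>    1 60  0
#>    2  0 60

cv <- repeated_cv(ts, C1 = 1, C2 = 1, n_folds = 10, n_repeats = 5, seed = 1)
cv
#> Repeated cross-validation: 10 folds x 5 repeats  (C1 = 1, C2 = 1)
#>   accuracy             0.977 (0.004)
#>   sensitivity          0.987 (0.007)
#>   specificity          1.000 (0.000)
#>   screening_accuracy   0.988 (0.003)
```

Accuracy/sensitivity/specificity are mean (SD) across repeats on held-out
biopsies, with class 2 as positive; `screening_accuracy` is the
tumor-vs-normal separation the C₂ tuning stage screens on. Image-mode
workflows are analogous: `generate_image_cohort()` →
`cohort_biopsy_features()` + `sample_patient_windows()` → `wsosvm_fit()` →
`personalize()` → `generate_map()` / `co_alteration_map()`.

A thin command-line front end over the same functions is installed at
`inst/cli/wsosvm.R` (`simulate`, `fit`, `cv`, `explain`, `map`, `compare`).

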