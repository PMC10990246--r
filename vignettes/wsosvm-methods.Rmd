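---
title: "Weakly supervised ordinal SVMs for regional gene-status mapping: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised ordinal SVMs for regional gene-status mapping: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsosvm)
```

## The problem and the model

Glioblastoma tumors are genetically heterogeneous: the alteration status of
driver genes such as EGFR, PDGFRA and PTEN varies from region to region
within one tumor. Image-localized biopsies pair a genetic label with a small
MRI neighborhood, but only a handful of biopsies per patient exist. This
package trains a classifier that predicts, for any small window of a
multiparametric MRI exam, one of three *ordered* classes:

* class 0 — normal brain,
* class 1 — tumor, gene non-altered,
* class 2 — tumor, gene altered,

and then sweeps that classifier across the tumoral area of interest (AOI)
with a stride-1 sliding window to draw a regional gene-status map.

The training data come from three sources with different amounts of
supervision. Labeled biopsy windows provide classes 1 and 2. Un-biopsied
tumoral windows are *weakly* labeled — they are known to be class 1-or-2 but
not which. Contralateral normal-brain windows provide class 0. All three are
combined in one maximum-margin problem: a single direction $w$ in a
reproducing kernel Hilbert space and two ordered biases $b_0 \le b_1$ such
that

$$ h(x) = w^\top\phi(x), \qquad
   \hat y(x) = \begin{cases} 2 & h(x) \ge b_1 \\
                             1 & b_0 \le h(x) < b_1 \\
                             0 & h(x) < b_0. \end{cases} $$

Labeled class-1/2 samples face the upper boundary $b_1$ with hinge slack
penalized by $C_1$; normal samples and *all* tumoral samples (labeled ones
are re-entered into this block, so the class-1-or-2 block has
$m_{12}' = n_1 + n_2 + m_{12}$ members) face the lower boundary $b_0$ with
slack penalized by $C_2$. The constraint $b_0 \le b_1$ preserves the class
order. We treat the penalized form (penalty weights $C_1$, $C_2$) as the
canonical primal: those are the quantities the tuning procedure searches,
and they appear directly as box bounds in the dual. Aggregate slack budgets
are therefore never exposed as user parameters.

## The dual program and how it is solved

Training solves the Lagrangian dual, a convex QP in the multiplier vector
$\gamma = (\alpha^{(1)}, \alpha^{(2)}, \beta^{(0)}, \beta^{(12)})$ with
quadratic matrix $YKY$ ($Y$ the block sign matrix, $K$ the Gram matrix of
the stacked rows), one equality row, the order inequality
$-\sum\alpha^{(1)} + \sum\alpha^{(2)} \ge 0$, and boxes $[0, C_1]$ /
$[0, C_2]$. `assemble_dual()` builds it, `solve_dual()` solves it, and
`recover_biases()` extracts $(b_0, b_1)$.

Numerical design, in order of the problems each choice addresses:

* **Structural singularity.** Because labeled rows appear with both signs,
  $YKY$ always has exactly opposite column pairs; curvature along those
  directions comes only from the diagonal jitter ($10^{-8}$ by default).
  The QP is solved with the dual active-set method of Goldfarb and Idnani
  (`quadprog::solve.QP`), with an escalating-jitter retry because that
  factorization can fail or return an infeasible point on the nearly
  singular problem. Large problems (over 400 variables) start the ladder at
  $10^{-6}\times$ the diagonal scale, where the first attempt reliably
  succeeds.
* **Refinement.** The solver can also stall at a feasible but suboptimal
  point. Up to 400 variables, its point seeds a primal active-set
  refinement on the original problem (pseudoinverse KKT solves on the
  working set, step clipping at blocking bounds, multiplier-sign release)
  that only ever returns a feasible point with an objective no worse than
  the seed. Beyond that size the raw solution is already accurate at the
  level cross-validated error rates resolve.
* **Objective reporting.** The dual objective is evaluated on the
  jitter-free $YKY$: the regularized optimum carries a bias of
  $\tfrac12\,\text{jitter}\,\|\gamma\|^2$, which at large $C$ would
  otherwise dominate a duality-gap comparison.
* **Bias recovery.** Interior support vectors (multipliers strictly inside
  their box with tolerance $10^{-6}\max(C_1, C_2)$) sit exactly on their
  margin, so each gives a bias estimate ($b_1 = h(x) \pm 1$ from the labeled
  blocks, $b_0 = h(x) \pm 1$ from the normal/class-12 blocks); estimates are
  averaged. A boundary with no interior support vector falls back to the
  midpoint of the interval left feasible by the bound-active multipliers'
  KKT conditions; an interval empty beyond tolerance raises an error rather
  than guessing. Printed margin conditions of the form "$b = h(x) - y$" are
  read as this conventional margin-target condition with targets $\pm 1$;
  the penalized-primal oracle pins the interpretation in tests. Residual
  numerical violations of the order contract are repaired by
  $b_0 \leftarrow \min(b_0, b_1)$, preserving the upper boundary that drives
  the gene-status call. Boundary values take the higher class
  (sign(0) $\to$ +).
* **Verification.** `primal_oracle_fit()` solves the penalized primal
  directly (explicit $w$, linear kernel, small instances only), polished by
  the same active-set refinement; strong duality of the convex QP makes the
  two routes mutually checking, and the test suite holds them to a duality
  gap below $10^{-6}$ and decision-value agreement below $10^{-4}$ on random
  small instances. With $m_0 = m_{12} = 0$ the equality and order rows force
  $\sum\beta^{(12)} = 0$, collapsing the model to a standard binary
  soft-margin SVM — tested against an independent SVM implementation.

## Kernel and scaling

The default kernel is a Gaussian radial basis function. Nothing in the
model requires it; a linear kernel keeps $w$ explicit and is what the
verification oracle uses. When no bandwidth is given it is resolved as
$\gamma_k = 1/(d \cdot \text{median feature variance})$ on the full training
block — a heuristic that removes a free parameter and is insensitive to a
few wild features. Features are z-scored per feature using all training
samples (labeled, unlabeled and normal together) before kernel evaluation;
the scaler is stored in the fitted model and applied to every later input.
Kernel methods simply require commensurate feature scales, and the
280-dimensional radiomic vector mixes units as different as raw intensities
and co-occurrence entropies.

## The radiomic feature bank

Each sample is an 8×8-pixel window (about the physical footprint of a
biopsy). The window "centered" at pixel $(r, c)$ covers the half-open range
$[r-4, r+4) \times [c-4, c+4)$, 0-based — an even window has no central
pixel, so the convention must be fixed somewhere and this is it. Windows
that would cross the image boundary are an error, never padded: padded
texture is an artifact. Windows are *not* masked by the AOI; instead every
sampling rule (biopsies, auxiliary windows) keeps centers far enough inside
their region that the window fits.

Per contrast the default bank emits 56 features, 280 over the five
contrasts (T1+C, T2, MD, FA, rCBV):

* 8 statistical — mean, SD, skewness, excess kurtosis, min, max, median,
  IQR, with population moments and the convention that skewness and
  kurtosis are 0 for constant windows;
* 20 co-occurrence — windows are min-max quantized to 32 gray levels
  (standard radiomics practice), one symmetric normalized GLCM per
  distance-1 offset (0°, 45°, 90°, 135°), and 5 Haralick statistics
  (contrast, correlation, energy, homogeneity, entropy) reported per
  offset. Degenerate single-level windows give energy 1 and 0 elsewhere,
  with correlation defined as 0;
* 28 Gabor — 14 complex filters (4 orientations × 3 frequencies of
  0.15/0.25/0.40 cycles per pixel, plus two extra low-frequency filters at
  0.08) applied by circular cross-correlation, each summarized by the mean
  and SD of the response magnitude. Kernels are DC-free, so features are
  invariant to adding a constant.

The exact 56-feature composition is a *configuration*
(`feature_bank_config()`), recorded in model metadata, precisely because
only its size and family structure are pinned down by the pipeline design;
any alternative bank of the same shape can be swapped in without touching
the rest of the package.

## Cross-validation, auxiliary sampling and tuning

Evaluation is repeated stratified 10-fold cross-validation over the labeled
biopsy samples, 30 repeats by default, reporting the mean and SD of
accuracy, sensitivity and specificity across repeats (class 2 = altered is
the positive class). Folds are assigned at the biopsy-sample level;
`group_by_patient = TRUE` keeps a patient's biopsies in one fold for users
worried about within-patient leakage, but the default mirrors
biopsy-level splitting.

In every fold the training set is completed with freshly drawn auxiliary
samples: equal numbers of unlabeled tumoral and normal windows whose
combined total matches the labeled training count (the odd one goes to the
tumoral side), the tumoral half split equally between the CE and NE
compartments (odd counts favor CE). This keeps the auxiliary sources from
diluting the biopsies' influence while still representing both tumor
compartments.

Predictions of class 0 on labeled test biopsies count as errors against
their true class for accuracy and as negative-side calls for
sensitivity/specificity — they are neither class 1 nor class 2, and
anything else would flatter the accuracy.

Hyperparameters are tuned in two stages, reflecting that separating tumor
from normal brain is much easier than separating the two tumoral classes:
first $C_2$ on a coarse grid (default $\{0.01, 0.1, 1, 10, 100\}$,
evaluated at $C_1 = 1$), keeping settings whose cross-validated
tumor-vs-normal screening accuracy exceeds 0.80 — the screen is computed on
the held-out labeled fold plus a held-out auxiliary draw, since the
combined-set evaluation is not otherwise pinned down; then $C_1$ on a fine
grid (default 20 log-spaced points in $[0.01, 100]$) under each retained
$C_2$, maximizing labeled class-1-vs-2 accuracy with ties broken toward
smaller $C_1$, then smaller $C_2$ (smaller penalties, flatter models). If
nothing passes the screen the best-screening $C_2$ is used with a warning.

The method-comparison harness is the one-sided Wilcoxon rank-sum test on
per-repeat metric series. For combined samples up to 12 the p-value is
exact — enumeration of all assignments with midranks for ties, reporting
$P(W \ge W_{obs})$ — and larger samples use the tie-corrected normal
approximation. Note a discreteness subtlety: swapping the two series maps
$p \mapsto 1 - p + P(W = W_{obs})$, not $1 - p$.

## Personalization and prediction maps

Deployment re-trains the model per patient under the tuned $(C_1, C_2)$:
the cohort's labeled biopsies are kept, but the auxiliary unlabeled and
normal windows are drawn from the target patient's own image (same
size and CE/NE rules). `generate_map()` then classifies every AOI pixel
whose window fits in the image; pixels whose window would cross the image
boundary are skipped and counted, never padded. Class-0 calls inside the
AOI are retained and surfaced by `map_summary()` as a quality-control
fraction — the ordinal model permits them and they flag model–data
mismatch — rather than being forced into class 1. Two maps of the same
patient combine into a co-alteration map (`co_alteration_map()`), the joint
per-pixel state of two driver genes.

## The synthetic cohorts: what they emulate and what they do not

Two generators make every stage testable without patient data.

`generate_feature_cohort()` draws feature vectors directly: isotropic
Gaussian classes with collinear, ordered centroids ($\mu_0 < \mu_1 < \mu_2$
along one axis, adjacent spacing `separation` in units of the within-class
SD), an unlabeled block mixing the two tumoral generators with a
configurable class-2 share, and an optional concentric-shell mode to
exercise nonlinear kernels. Default block sizes (171/130 labeled,
150 + 151 auxiliary) mirror a single-gene biopsy cohort with an
equally-sized auxiliary pool.

`generate_image_cohort()` builds single-slice multiparametric "patients":
a disk AOI split into a CE core and an NE rim, a disjoint contralateral
normal disk, five contrast images with region-specific means, and two noise
layers (Gaussian-smoothed correlated texture plus i.i.d. pixel noise). The
latent gene-status field is a Gaussian-smoothed white-noise field
thresholded at its within-AOI median — spatially coherent subregions
without any tumor biology. Each gene's altered subregion shifts the
contrasts that gene is coupled to (by default each gene imprints on its own
pair of contrasts, so contrast-level attributions differ between genes, as
they do for real driver genes). Biopsies are sampled uniformly among AOI
pixels whose full window fits inside the AOI and carry the latent label at
their pixel.

What passing tests on these cohorts shows: the optimization, bias recovery,
decision rule, sampling rules, cross-validation accounting, attribution and
map machinery are correct, and the pipeline recovers planted structure when
it is recoverable. What they do not show: performance on real MRI, which
has acquisition artifacts, registration error, non-Gaussian texture,
between-patient batch effects and label noise from the genetic calling
pipeline, none of which are modeled.

Problem sizes used by the shipped verification runs were chosen to exercise
the full pipeline at the scale the method targets while staying
desk-sized: the feature-mode check uses 200/200/200/200 blocks
(separation 8) under 10-fold CV with 2 repeats, and the image-mode check
uses 16 patients with 4–10 biopsies each — about a hundred biopsies, the
order of magnitude real image-localized biopsy cohorts reach. The
prediction-map check uses a strongly separated single-gene cohort
(class effect several times the pixel noise, latent smoothing length 12
pixels) and compares map to latent field away from field discontinuities
(a band of the window radius around latent-region boundaries and the AOI
edge, where a window inevitably mixes populations).

## Shapley attribution

Attributions explain the continuous decision value $h(x)$, not the discrete
class: $h$ is the model's ordinal evidence, and the class is a step
function of it. Feature absence means replacement by background values
(the training auxiliary + labeled samples, subsampled to at most 100 with a
fixed seed). For up to 12 features the Shapley values are computed exactly
by subset enumeration; otherwise by permutation sampling, where each
permutation is paired with one sampled background row and the telescoping
sum makes per-sample local accuracy ($\sum_f \phi_f + \text{baseline} =
h(x)$) exact rather than approximate. Contrast-level scores aggregate as
the mean over samples of the summed absolute per-feature values within each
contrast's block — the order "absolute value, sum within contrast, average
over samples" is one of several defensible choices and is fixed and
documented here.

## Known limitations

* Single 2-D slice; no 3-D texture, shape or wavelet features.
* Dense QP solver: fine up to roughly a thousand multipliers (the scale a
  few hundred biopsies plus matched auxiliaries produce); decomposition
  methods (SMO-style) would be needed well beyond that.
* The two-stage tuner evaluates a grid product of cross-validation runs and
  is the most expensive step at realistic sizes.
* Each gene trains independently; no multi-task coupling across genes.
* Bias recovery on degenerate data (no interior support vectors on a
  boundary) returns an interval midpoint; the decision boundary is then
  only determined up to that interval, which is a property of the problem,
  not the implementation.
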