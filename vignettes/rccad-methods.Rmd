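---
title: "Methods: morphology, texture and kinetics profiling of renal tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology, texture and kinetics profiling of renal tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The diagnostic problem

Renal cell carcinoma (RCC) and benign angiomyolipoma (AML) can look similar on
contrast-enhanced CT, yet they demand opposite management; within RCC, the
clear-cell subtype (ccRCC) is treated differently from the pooled non-clear-cell
subtypes (nccRCC). `rccad` implements a computer-assisted diagnosis pipeline
that characterizes a segmented renal tumor by three complementary aspects —
boundary morphology, volumetric texture, and enhancement kinetics — and feeds
the combined 94-feature record into a two-stage neural-network classifier:
stage 1 separates malignant (RCC) from benign (AML); only malignant calls reach
stage 2, which separates ccRCC from nccRCC.

The package expects, per subject, three co-registered CE-CT phase volumes —
precontrast, portal-venous and delayed, acquired at 0, 80 and 300 s after
contrast injection (configurable) — plus one binary tumor mask valid for all
three phases. Masks may also be assembled from per-slice 2D delineations with
`stack_rois()`.

# Morphology: the SH reconstruction-error spectrum

The tumor boundary is triangulated from the binary mask and mapped one-to-one
onto the unit sphere; the per-vertex radius (distance to an interior origin)
then becomes a function on the sphere and is expanded in real spherical
harmonics (SH). Smooth, near-spherical surfaces are captured by low-degree
models; irregular, malignant-looking surfaces leave residual error up to high
degree. The feature vector is the reconstruction error at model orders 1
through 70.

Concrete choices, in pipeline order:

* **Triangulation.** Marching tetrahedra on the binary lattice at iso-level
  0.5 (6-tetrahedra cube decomposition, vertices at lattice-edge midpoints,
  scaled to mm). We chose marching tetrahedra over classic marching cubes
  because the tetrahedral cases have no ambiguous face configurations on
  binary data, so the mesh is watertight by construction — a requirement for
  the sphere mapping. If the digitized surface is not genus 0 (Euler
  characteristic ≠ 2), one pass of 3×3×3 morphological closing is applied and
  extraction retried once; persistent defects are an error rather than a
  silent repair.
* **Smoothing.** Laplacian filtering, default 10 iterations at step 0.5 —
  enough to remove voxelization staircase (a digitized 12 mm ball recovers
  the analytic sphere area within 1%) without eroding lobulation at the
  scales the SH model can represent.
* **Origin.** Centroid of the mask foreground; if that falls outside a
  non-star-shaped tumor, the interior voxel farthest from the background
  (chamfer distance transform) is used instead.
* **Spherical map.** The initial map projects vertices radially onto the unit
  sphere; the attraction–repulsion iteration then (a) pulls each node toward
  its mesh neighbors with weight `ca1 = 0.1` (plus a distance-normalized term
  `ca2 = 0.05`), (b) pushes all node pairs apart with an inverse-square
  repulsion of weight `cr = 0.2` scaled by `1/(2I)`, and (c) reprojects to
  unit norm. Iteration stops when the maximum per-vertex displacement falls
  below `threshold = 1e-4` or at the iteration cap. These weights are
  implementation-defined in the published description; the defaults here were
  fixed once for stable behavior on phantoms and are fully exposed in
  `ar_params()`. The published update rule is typographically ambiguous
  between multiplying and dividing the attraction term by the squared
  neighbor distance; both readings are implemented
  (`attraction_form = "product"` (default) or `"quotient"`). The repulsion
  displacement is taken along `C_i - C_j` (pushing nodes apart): the printed
  formula's sign would attract, contradicting its stated purpose of
  "inflating" the mesh. Repulsion distances are computed from the
  post-attraction positions.
* **SH fit.** Real orthonormal SH basis (sine branch for negative orders,
  cosine for positive, with the √2 factor absorbed so the basis is
  orthonormal), evaluated by stable normalized-Legendre recurrences valid far
  beyond degree 70. Coefficients solve a ridge-stabilized (`1e-10`)
  linear least squares over the mapped vertices. Quadrature-style projection
  was rejected because the attraction–repulsion map does not produce exactly
  uniform samples. With basis columns ordered by degree, one Cholesky
  factorization of the normal equations yields the residual of *every*
  nested lower-order model, so the 70-order error spectrum costs a single
  factorization.
* **SHRE definition.** The published text never defines the reconstruction
  error numerically. We use the RMS radial residual of the order-k model
  divided by the mean vertex radius, making the spectrum scale-invariant so
  tumors of different sizes are comparable; orders 1..70 are reported (the
  degree-0 term only encodes mean size). The spectrum is non-increasing in k
  by construction (nested least squares).
* **Vertex budget.** A degree-70 fit needs at least 71² = 5041 samples.
  Meshes below `ceiling(1.05 × 5041)` vertices are Loop-subdivided before
  mapping. We deliberately cap the subdivision target at 5% above the
  algebraic minimum rather than doubling it: the all-pairs repulsion step is
  quadratic in vertex count, and the extra samples do not change the fitted
  spectrum appreciably.

# Texture: first-order and co-occurrence features

Texture is computed on one phase (portal-venous by default, configurable).
The in-mask gray range is contrast-stretched onto 0..255 with
`floor(255 (g - gmin)/(gmax - gmin))`; a constant tumor maps to all zeros.
First-order features are the population moments (mean, variance, SD,
skewness, non-excess kurtosis — a normal distribution scores 3), Shannon
entropy in bits over the 256-level histogram, and the 10th–100th percentiles
in 10-point steps with linear interpolation. Percentiles are taken on the
stretched values, consistent with the histogram features.

The gray-level co-occurrence matrix is 256×256 and aggregates all directions
of the 26-connected voxel neighborhood at once — in-plane and across adjacent
planes — which is what makes the derived features rotation invariant. The
published description also mentions a ≤ 2 mm physical separation criterion,
which at the study's 2.5 mm slice thickness would exclude every
adjacent-plane pair and contradict the depicted 26-voxel neighborhood; the
package therefore defaults to the plain 26-neighborhood and offers the
physical cutoff as an option (`glcm_max_mm`) for near-isotropic data. Each
unordered voxel pair is accumulated into both (i, j) and (j, i), so the
matrix is symmetric by construction. From the normalized matrix we compute
the standard Haralick statistics: contrast, dissimilarity, homogeneity
(inverse difference moment), angular second moment, energy (= √ASM) and
correlation; a zero-variance (single-level) tumor is reported as perfectly
correlated, which keeps the feature finite and is logged as degenerate.

# Kinetics: wash-in and wash-out slopes

Enhancement kinetics summarize the mean in-mask attenuation across the three
phases: wash-in is `(HU_pv − HU_pre)/(t_pv − t_pre)` and wash-out
`(HU_pv − HU_del)/(t_del − t_pv)` (positive when attenuation falls), in HU/s.
With the default 0/80/300 s protocol the denominators are 80 s and 220 s.
Wash-out is deliberately not clipped at zero: a negative value flags a
still-enhancing lesion. Both slopes depend only on attenuation differences
and are invariant to a constant HU offset. The whole-tumor mean is used; no
sub-region selection is attempted.

# Classification: two-stage MLP

Both stages use a multilayer perceptron with hidden layers of 50 and 25 tanh
units, a logistic output thresholded at 0.5, and mean-squared-error loss.
Training criteria follow the published protocol: at most 500 epochs, loss
goal 0, minimum gradient 1e-7, and early stop after 6 validation failures on
a stratified 15% split of the training fold. The published optimizer is
Levenberg–Marquardt; LM solves normal equations in the ~6100 network
parameters each step, which is exact but quadratic in memory and cubic in
time, so the package trains small networks with LM and falls back to
resilient backpropagation (iRprop⁻, a standard first-order full-batch method
with the same stopping rules) above a configurable parameter cutoff — the
50+25 network on 94 inputs uses the fallback. Features are z-scored with
statistics of the training fold only, so cross-validation folds never leak
test information.

Evaluation runs leave-one-subject-out or randomly stratified 10-fold
cross-validation, repeated (default 10×, seeds `seed + repeat − 1`), and
reports sensitivity, specificity, Dice similarity coefficient and accuracy
as mean ± SD. Stage 1 treats malignant as the positive class over all
subjects; stage 2 is evaluated on the ground-truth malignant subjects with
ccRCC positive, so its denominator matches the malignant cohort rather than
compounding stage-1 errors (a cascaded deployment mode is available through
`two_stage_predict()`). LOSO folds are deterministic; repeats differ through
network initialization and validation splits. Under 10-fold, a stratification
that would leave a fold's training complement single-class is redrawn with
the next seed and logged. No feature selection precedes the classifier: all
94 features are used.

# The phantom generator

No public dataset exists for the study design this package targets, so the
generator produces synthetic subjects that emulate exactly the contrasts the
method claims to exploit, each from a recorded seed:

* **Shape.** A star-shaped region `rho ≤ R (1 + a·p(θ, φ))` with `p` a random
  SH perturbation of degrees 2..D normalized to unit angular SD. Class
  presets (versioned in `extdata/class_presets.json`): AML a = 0.02, D = 3;
  nccRCC a = 0.08, D = 8; ccRCC a = 0.15, D = 12. Base radius 12 mm
  (a ~2.4 cm lesion, typical of imaging cohorts), jittered ±15% per subject.
* **Texture.** A Gaussian random field (white noise smoothed by a Gaussian
  kernel of the class correlation length, standardized inside the mask)
  scaled to the class HU standard deviation: AML 12 HU @ 2 mm, nccRCC
  22 HU @ 3 mm, ccRCC 30 HU @ 4 mm. The same structural field underlies all
  three phases, with 10% independent per-phase fluctuation; the background is
  ~0 HU with 5 HU noise; values are rounded to integer HU.
* **Kinetics.** Mean phase attenuations (pre/pv/delayed): AML 25/60/50,
  nccRCC 32/110/85, ccRCC 35/145/95 HU, jittered per subject (SD 3/8/6 HU).
  These place the group-mean wash-in and wash-out in the strict order
  ccRCC > nccRCC > AML with AML weakly enhancing — the qualitative ordering
  the method expects.
* **Default cohort.** 70 AML / 40 ccRCC / 30 nccRCC on 96³ grids at 1 mm
  isotropic spacing (a 2.5 mm slice option exercises the anisotropic paths).

What the phantoms do *not* emulate: kidney/abdomen anatomy, partial-volume
and beam-hardening physics, segmentation error, scanner/protocol variation,
or the overlap structure of real class distributions. Passing the recovery
tests therefore demonstrates that the implementation extracts and combines
the intended signals faithfully — not that the published clinical accuracy
would be reproduced on patients; the published headline numbers come from a
private 140-patient dataset and are out of scope here.

# Numerical and budget choices

* The repository's end-to-end checks run the default 140-phantom cohort
  through feature extraction and single-repeat LOSO. For that cohort-scale
  run the configuration caps the attraction–repulsion at 10 iterations and
  the SH fit at 5045 seeded-subsampled vertices in single precision
  (`acceptance_config` in the test helpers and `scripts/acceptance.R`).
  These are problem-size settings chosen to keep a ~200-model LOSO
  experiment on a single CPU pleasant to rerun: the capped map is already
  bijective and well spread (the iteration plateaus long before the 1e-4
  displacement threshold), and the single-precision spectrum agrees with the
  double-precision one to ~1e-3 absolute, far below the class contrasts
  (~1e-1). Interactive single-subject use can simply keep the defaults
  (double precision, all vertices, 10 000-iteration cap).
* In single precision the normal-equation ridge is floored at ~50 ulp of the
  Gram diagonal, since a 1e-10 ridge is below float resolution.
* The residual spectrum is computed as `RSS_p = y'y − Σ z_i²` from the
  Cholesky forward solve; the running sum makes monotonicity structural, and
  a max(0, ·) clamp absorbs the cancellation floor (~1e-10 relative in
  double).
* Ties and degenerate cases: coincident node pairs contribute no
  attraction/repulsion force and are counted (a collapse aborts with a
  diagnostic); a constant tumor stretches to all-zero, has entropy 0 and
  correlation 1; single-voxel tumors are rejected for moment features.
* Determinism: every stochastic step (phantom draws, fit subsampling, weight
  initialization, validation splits, fold assignment) consumes an explicit
  seed derived from the run seed; rerunning a configuration reproduces
  feature tables and reports exactly.

# Known limitations

* The attraction–repulsion fixed point depends on its weights; the defaults
  produce a well-spread bijection but are not a mathematically guaranteed
  conformal or area-preserving map.
* SHRE at order 70 on meshes near the 5041-vertex floor leaves the highest
  orders weakly constrained; they contribute little class signal and are kept
  mainly for layout fidelity.
* The GLCM treats the 26-neighborhood as one aggregate; per-direction
  matrices (and hence anisotropy-sensitive texture) are intentionally out of
  scope.
* Only AML vs. RCC and ccRCC vs. nccRCC are modeled; oncocytoma and the
  papillary/chromophobe split are out of scope.
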