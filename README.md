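# rccad

Two-stage computer-assisted diagnosis of renal tumors from three-phase
contrast-enhanced CT (CE-CT). Given co-registered precontrast, portal-venous
and delayed volumes (Hounsfield units) and a binary tumor mask, `rccad`
extracts three complementary feature families and classifies the tumor first
as malignant renal cell carcinoma (RCC) vs. benign angiomyolipoma (AML), and —
if malignant — as clear-cell (ccRCC) vs. non-clear-cell (nccRCC) carcinoma.
It is aimed at quantitative-imaging researchers who want a transparent,
fully scripted re-implementation of this class of radiomics pipeline, plus a
seeded phantom generator so everything can be exercised without patient data.

## The feature model

Each subject is reduced to a 94-element record built from five blocks:

| block | size | content |
|---|---|---|
| histogram | 6 | mean, variance, SD, skewness, kurtosis (normal = 3), entropy of the contrast-stretched tumor gray levels |
| percentiles | 10 | 10th–100th gray-level percentiles in 10-point steps |
| GLCM | 6 | Haralick statistics (contrast, dissimilarity, homogeneity, ASM, energy = √ASM, correlation) of a 256×256 co-occurrence matrix aggregated over the 26-voxel neighborhood, making them rotation invariant |
| SHRE | 70 | spherical-harmonic reconstruction errors e(1..70): the tumor surface is mapped one-to-one onto the unit sphere by an attraction–repulsion iteration, the radius function r(θ, φ) is fit with real spherical harmonics Y<sub>τβ</sub> up to degree N, and e(N) is the RMS radial residual normalized by mean radius — a spectrum that decays slowly for complex malignant surfaces |
| kinetics | 2 | wash-in (HU<sub>pv</sub> − HU<sub>pre</sub>)/80 s and wash-out (HU<sub>pv</sub> − HU<sub>del</sub>)/220 s slopes of mean tumor attenuation |

The combined record feeds a multilayer perceptron (hidden layers 50 + 25,
tanh, logistic output; trained to the published criteria: ≤ 500 epochs, min
gradient 1e-7, ≤ 6 validation failures; Levenberg–Marquardt for small
networks, resilient backpropagation beyond that) evaluated under
leave-one-subject-out (LOSO) or stratified 10-fold cross-validation with
sensitivity, specificity, Dice coefficient and accuracy reported as
mean ± SD over repeats.

## Worked example

```r
library(rccad)

# one synthetic ccRCC-like subject: three phases + mask on a 96^3 grid
subj <- generate_subject(phantom_spec("ccRCC", seed = 42))

cfg <- rccad_config(ar = ar_params(max_iterations = 10),
                    sh_precision = "single", sh_fit_max_vertices = 5045)
feats <- extract_subject_features(subj, cfg, subject_id = "demo")
feats[, c("subject_id", "label", "shre_01", "glcm_contrast", "wash_in", "wash_out")]
#> # A tibble: 1 x 6
#>   subject_id label shre_01 glcm_contrast wash_in wash_out
#>   <chr>      <chr>   <dbl>         <dbl>   <dbl>    <dbl>
#> 1 demo       ccRCC   0.137          175.    1.38    0.228
```

`shre_01 = 0.137` says the order-1 spherical-harmonic model leaves a ~14%
RMS radial error — a strongly non-ellipsoidal surface (a smooth AML phantom
scores ~0.02). `wash_in = 1.38` HU/s and a positive `wash_out` are the steep
enhancement profile typical of clear-cell carcinoma; `glcm_contrast` reflects
its heterogeneous texture.

A full experiment — simulate a cohort, extract all features, run the
two-stage cross-validated evaluation — is one call:

```r
ex <- run_experiment(rccad_config(repeats = 1, seed = 17),
                     n_aml = 70, n_ccrcc = 40, n_nccrcc = 30)
glance(ex$report)   # mean +/- SD per stage and metric
autoplot(ex$report) # per-repeat metric distributions
```

`tidy()`/`glance()` methods cover evaluation reports, SHRE spectra and
trained networks; `autoplot()` draws the SHRE spectrum, enhancement curves
and evaluation summaries. A thin command-line front end
(`inst/cli/rccad`) exposes `simulate`, `mesh`, `extract`, `evaluate` and
`run` subcommands over NIfTI/PLY/CSV/JSON files.

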