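---
title: "Methods: DTI feature extraction and diagnostic modeling for breast lesions"
author: "breastdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DTI feature extraction and diagnostic modeling for breast lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastdti)
```

# Scope and model overview

`breastdti` implements the quantitative chain used to ask whether diffusion
tensor imaging (DTI) adds diagnostic value over clinical and dynamic
contrast-enhanced (DCE) MRI features when characterizing suspicious
(BI-RADS 4/5) breast lesions. The chain has four stages:

1. **Tensor estimation.** Diffusion-weighted MRI follows the
   mono-exponential signal model $S = S_0 e^{-b\,g^\top D g}$, where $D$ is
   the voxel's symmetric diffusion tensor, $b$ the diffusion sensitization
   (s/mm$^2$) and $g$ the unit gradient direction. Taking logs gives a
   linear model in the six unique elements of $D$ plus $\log S_0$, solved
   per voxel by least squares. Eigendecomposition yields
   $\lambda_1 \ge \lambda_2 \ge \lambda_3$, from which the five scalar maps
   are computed: ADC (mean diffusivity) $(\lambda_1+\lambda_2+\lambda_3)/3$;
   fractional anisotropy
   $\mathrm{FA} = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\mathrm{ADC})^2} / \sqrt{\sum_i \lambda_i^2}$;
   axial diffusivity $\lambda_1$; radial diffusivity
   $(\lambda_2+\lambda_3)/2$; and the empirical difference
   $\lambda_1-\lambda_3$.
2. **Lesion features.** A single-slice seed region on the combined
   diffusion-weighted image (the geometric mean of the unidirectional
   $b=800$ images) is refined by excluding voxels below a configurable
   fraction of the in-seed maximum; the mean voxel value of each scalar map
   over the refined ROI characterizes the lesion. DCE kinetics are
   classified per voxel from the relative signal change between the 120 s
   and 480 s post-contrast scans (>10% decrease: washout; >10% increase:
   persistent; otherwise plateau) and reduced to the lesion's most
   suspicious ("worst") class.
3. **Diagnostic models.** Univariate associations with malignancy use
   logistic regression with an independence working correlation and
   patient-clustered sandwich variance, because a woman can contribute
   several correlated lesions. Multivariate models use the LASSO with the
   penalty chosen by leave-one-patient-out cross-validated deviance.
4. **Internal validation.** Discrimination is summarized by the
   Mann-Whitney AUC with Harrell-style bootstrap optimism adjustment and
   patient-level resampling; model comparisons use paired patient-level
   bootstrap differences in AUC.

Because the patient data such an analysis runs on are typically not
shareable, the package ships a first-class synthetic-data module that
emulates every input: DWI phantoms with known tensors, enhancement curves
with known kinetic class, and clustered lesion cohorts with known effect
structure.

# Acquisition model and tensor fitting

The default gradient scheme mirrors a clinical breast DTI protocol: six
directions at $b = 100$ and $800$ s/mm$^2$ plus one $b = 0$ volume
(13 volumes). The six-direction set is the balanced dual-gradient scheme
$\{(1,1,0),(1,0,1),(0,1,1),(1,-1,0),(1,0,-1),(0,1,-1)\}/\sqrt2$, whose
outer products sum to $2I$, making the 7-parameter log-linear design full
rank. Published protocols rarely print their direction tables, so a
balanced standard set is the sensible default; alternative tables can be
supplied directly or read from FSL-style `bvec` files (directions are
interpreted in the image frame and re-normalized if stored unnormalized).

Fitting choices:

* **OLS on log-signals** is the default (`fit_tensor(method = "ols")`). It
  is unbiased on noiseless data and at high SNR, and is exactly
  reproducible. A weighted variant (`"wls"`, weights $\propto S^2$, the
  first-order variance correction for log-transformed noise) is available.
* **All shells enter one joint fit** by default. Whether a low-$b$ shell
  (perfusion-sensitive) should enter the tensor fit is a genuinely open
  protocol question, so `shells =` restricts the fit (e.g.
  `shells = c(0, 800)`); on noiseless phantoms both modes recover the
  generating tensor to numerical precision.
* **Degenerate voxels.** Any voxel with a non-positive signal among the
  used acquisitions is excluded from the fit mask (the log transform is
  undefined and such voxels are noise-dominated); negative eigenvalues are
  clamped to zero and flagged, which keeps FA within $[0,1]$. Eigenvalues
  are sorted descending before any scalar computation, so the scalar maps
  are sort-stable under ties.
* FA of the zero tensor is defined as 0.

# ROI refinement

The study workflow this mirrors drew a manual ROI on the combined DWI at
the lesion's central slice and used a semi-automated threshold to exclude
low-signal voxels (fat, normal fibroglandular tissue). The published
account does not state the threshold value, so `refine_roi()` exposes it as
a calibration knob with default `threshold_fraction = 0.5` of the in-seed
maximum. Thresholding uses the combined $b=800$ image only (not
per-direction images). ROIs are single-slice by construction; multi-slice
seeds are rejected with a clear error. Mean FA is always the mean of
voxel-wise FA — never FA of mean eigenvalues, which differs because FA is
nonlinear in the eigenvalues. (This also explains why a lesion's reported
mean ADC need not equal the mean of three reported representative
eigenvalues.)

# The synthetic cohort generator

`simulate_cohort()` draws a lesion-level table whose defaults are fixed to
the study conditions the package is tested under:

* 1/2/3 lesions per patient with probabilities 0.809/0.155/0.036;
  patient-level covariates: age $\mathcal N(51, 11.8^2)$ years,
  post-menopausal 0.521, known-cancer indication 0.649, dense breasts
  0.732, BPE categories (1-4) with probabilities 0.299/0.407/0.191/0.103.
* Lesion-level DCE features: log-normal size (median 1.1 cm,
  $\sigma_{\log} = 0.85$, chosen to reproduce a right-skewed size
  distribution with the reported median and a plausible 0.4-11 cm range),
  mass type 0.567, worst-curve kinetics persistent/plateau/washout
  0.025/0.143/0.832, BI-RADS 5 at 0.084.
* Malignancy is Bernoulli with logit equal to an intercept plus
  per-feature log-odds plus a patient-level Gaussian random intercept
  (default SD 0.5 — the source analysis states only that within-patient
  correlation exists, so a moderate random intercept is assumed). Default
  coefficients follow the multivariate odds-ratio pattern of the combined
  clinical+DTI model (e.g. washout 2.43, BI-RADS 5 2.36, dense breasts
  0.61 per level; age 1.17 and log-size 1.85 per SD; BPE 0.66 per
  category). The intercept is calibrated numerically
  (`calibrate_intercept()`, fixed-seed Monte-Carlo population of 20,000
  patients + root finding) to a marginal prevalence of 0.399.
* DTI features are class-conditional: ADC is normal with mean $\pm$ SD
  $1.26 \pm 0.32$ (malignant) and $1.55 \pm 0.30$ (benign) in
  $10^{-3}$ mm$^2$/s; FA is log-normal, moment-matched per lesion type
  and class (mass/malignant $0.31 \pm 0.17$, mass/benign $0.21 \pm 0.12$,
  non-mass/malignant $0.24 \pm 0.11$, non-mass/benign $0.26 \pm 0.14$).
  ADC and FA are coupled through a Gaussian copula with latent correlation
  $2\sin(-0.5\,\pi/6) \approx -0.518$, which induces a Spearman rank
  correlation of $-0.5$ within each type-by-class stratum, matching the
  negative ADC-FA correlation seen in vivo. Pooling strata attenuates the
  rank correlation slightly because the FA marginal shifts with type.
* Axial and radial diffusivity and $\lambda_1 - \lambda_3$ are derived
  from (ADC, FA) through a prolate (axially symmetric) tensor with
  $\delta = \mathrm{FA}/\sqrt{3 - 2\,\mathrm{FA}^2}$,
  $\lambda_1 = \mathrm{ADC}(1+2\delta)$,
  $\lambda_{2,3} = \mathrm{ADC}(1-\delta)$. This makes the five DTI
  features exactly as collinear as their definitions imply, reproducing
  the strong empirical collinearity among DTI parameters.

Lesion DTI features can be generated either directly at lesion level (fast,
used for statistical tests) or through the full phantom → tensor fit → ROI
chain (`simulate_lesion_phantom_features()`, used for integration tests);
both paths agree to numerical precision on noiseless data.

What the generator deliberately does **not** emulate: echo-planar imaging
distortion, susceptibility/fat-suppression artifacts, motion, partial
volume, or radiologist variability in BI-RADS assignment. Passing tests on
this generator therefore validate the computational pipeline and the
statistical machinery under the stated effect structure — not robustness to
real-world image quality problems.

Noise defaults to additive Gaussian per acquisition; Rician (magnitude)
noise is available by flag for magnitude-MRI realism. Gaussian keeps the
log-linear fit unbiased at high SNR, which is what the recovery tests
exercise.

# Modeling conventions

* **Feature preparation.** Lesion size, FA and $\lambda_1-\lambda_3$ are
  natural-log transformed (right-skewed); odds ratios for continuous
  features are reported per 1-SD on the analysis scale
  ($\mathrm{OR}_{SD} = e^{\beta \cdot SD}$, an exact reparameterization);
  BPE stays ordinal and is reported per category; binary features pass
  through raw. The `size_large` indicator dichotomizes size at 1 cm before
  the log transform.
* **Cluster-robust univariate models.** Independence working correlation
  with a patient-clustered sandwich covariance. This choice reproduces the
  2×2 cross-product odds ratio exactly for a single binary predictor and
  is robust to misspecification of the within-patient correlation.
  Perfectly separated predictors are flagged with an infinite-OR marker
  rather than reported as a finite estimate.
* **Interactions.** Subgroup analyses use product columns between a binary
  moderator (mass vs non-mass; size ≥ 1 cm) and a continuous DTI feature;
  the base combined model has 12 parameters (intercept included) and the
  four interaction terms bring it to 16. Subgroup odds ratios are
  recovered as $e^{(\beta_{main}+\beta_{int})\cdot SD}$. The Wald
  comparison of subgroup ORs is a z-test on the interaction coefficient
  with its cluster-robust SE.
* **LASSO with leave-one-patient-out CV.** The penalty grid is 100
  log-spaced values from the smallest penalty that zeroes all coefficients
  down to $10^{-4}$ of it. For each penalty, the model is fit with each
  patient's lesions held out in turn and the held-out binomial deviance
  accumulated. Features are standardized inside the solver; a penalty of
  exactly 0 reduces to the unpenalized MLE (verified to $10^{-6}$).

## Penalty selection: minimum vs one-standard-error

Two conventions are exposed. `selection = "min"` (the default) takes the
strict deviance minimum. Because the cross-validated deviance curve is
typically very flat near its minimum, this rule is model-selection
inconsistent: in simulation it retains a conditionally uninformative
feature roughly a third of the time, essentially choosing at random along
the flat region. `selection = "1se"` takes the largest penalty within one
standard error (computed across patient folds) of the minimum — the
standard convention for sparse variable selection and the default
reporting rule of `cv.glmnet`. Effect-estimation results (coefficients of
the selected model) are reported under `"min"`; variable-selection
experiments in the test suite use `"1se"`, where a truly null FA is
excluded from the DTI-only model in ~97% of replicates while the
discriminating ADC is always kept.

The same instability affects bootstrap optimism adjustment. Harrell's
estimator subtracts the *average* optimism of the fitting procedure from
the run's apparent AUC; when the deviance-minimum rule happens to select
several noise features on the observed data, the run-specific overfitting
exceeds that average and the adjusted AUC remains optimistic. Under the
1-SE convention the selection is stable and the correction returns a
pure-noise model to chance performance, so the simulation suite exercises
the optimism machinery under `"1se"`.

# Internal validation

The apparent AUC of a model selected and fit on the same data is
optimistic. `bootstrap_optimism_auc()` implements the Harrell loop:
resample **patients** (not lesions) with replacement, rerun the *entire*
fitting procedure — including penalty re-selection — on the resample,
and record the difference between the refit's AUC on the resample and on
the original data. The adjusted AUC subtracts the mean optimism; the
percentile interval comes from the resample AUCs. Resampling by patient
preserves the within-patient correlation structure; in simulation,
duplicating every lesion under one patient ID yields visibly wider
intervals than treating the copies as independent patients, as it should.
Inside a resample, each patient *draw* becomes a distinct cluster (the
standard Efron convention): the refit, including its leave-one-patient-out
CV, treats the resample exactly as it would a fresh cohort of the original
size. The alternative — holding all copies of a multiply-drawn patient out
jointly — avoids identical copies straddling CV folds but systematically
reduces the number of folds inside resamples relative to the original fit,
making the bootstrap refits more conservative than the procedure being
validated and hence underestimating optimism.

`bootstrap_auc_diff()` compares two model specifications on paired
patient resamples; the two-sided p-value is twice the smaller tail mass of
the bootstrap distribution beyond zero, capped at 1, with a flagged
normal-approximation fallback when a tail is empty. This matches a
bootstrap comparison without asserting normality. B defaults to 1000;
the test suite runs at B = 200 and the bundled pipeline demo at B = 200,
sizes chosen so the full simulation suite completes in minutes on one
core while leaving the bootstrap distributions well resolved.

Resamples that contain a single outcome class are redrawn and counted.

# Numerical and degenerate-input conventions

* Deviance uses probabilities clamped to $[10^{-10}, 1-10^{-10}]$.
* glmnet paths that stop early (non-convergence at small penalties on tiny
  resamples) are handled by linear interpolation in the path, and failed
  folds or grid points are skipped with a logged warning.
* Ties in the CV deviance resolve to the larger (sparser) penalty.
* Kinetic boundary cases (exactly 10% change) classify as plateau,
  following the strict inequalities of the rule; classification is scale
  invariant.
* An all-excluded ROI is reported with an explicit empty flag so the
  caller can declare the lesion non-evaluable; the in-seed maximum always
  survives thresholding, so refinement alone cannot empty a valid seed.
* All simulators take explicit integer seeds and restore the caller's RNG
  state; identical configurations are bit-reproducible.

# Problem sizes used in the test suite

Deterministic worked examples run on single voxels or 4-6 voxel grids.
Simulation-based checks use: 500 replicates for the interaction-test
type-I error (194 patients each); 100 replicates for robust-CI coverage
(400 patients); 20 runs of the pure-noise optimism experiment
(100 patients, 10 features, B = 200, a 30-point penalty grid — the grid
resolution does not affect the correction property); 50 replicates of the
selection-consistency experiment (400 patients); tensor recovery on 100
random tensors. These sizes keep the whole suite to a few minutes of
simulation while leaving the binomial uncertainty of each pass criterion
small relative to its margin.

# Known limitations

* No eddy-current/motion registration, multi-compartment or kurtosis
  models, or tractography; the tensor model is mono-exponential.
* No pharmacokinetic (Tofts-type) DCE modeling; kinetics use the
  two-timepoint rule only, and no minimum-enhancement gate is applied by
  default (an optional threshold can be imposed upstream).
* ROI refinement implements only the intensity rule; cyst/necrosis/fat
  exclusion against T1/T2 references is a manual step outside the package.
* The cohort generator produces marginal distributions and a logistic
  effect structure; it does not model reader variability, scanner drift,
  or missing data (cases with incomplete data are assumed excluded
  upstream).
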