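# breastdti

Quantifying what diffusion tensor imaging (DTI) adds to clinical and
dynamic contrast-enhanced (DCE) MRI when deciding whether a suspicious
(BI-RADS 4/5) breast lesion is malignant. Malignant lesions tend to
restrict water diffusion — lower apparent diffusion coefficient (ADC) —
and may alter diffusion directionality (fractional anisotropy, FA). This
package implements the full analysis chain a breast-MRI research group
needs to test that question, plus a synthetic-data module so every stage
is exercisable without patient data. It is aimed at imaging scientists and
biostatisticians working on quantitative breast MRI.

## What it computes

**Tensor estimation and scalar maps.** Per voxel, the mono-exponential
model *S* = *S*₀ e^(−b gᵀDg) is linearized and solved by least squares
over a multi-shell, multi-direction acquisition (default: 6 directions at
b = 100 and 800 s/mm², one b = 0 volume). From the eigenvalues
λ₁ ≥ λ₂ ≥ λ₃ of D:

- ADC (mean diffusivity) = (λ₁ + λ₂ + λ₃)/3
- FA = √(3/2) · √Σ(λᵢ − ADC)² / √Σλᵢ²  (unitless, 0 = isotropic)
- axial diffusivity λ₁, radial diffusivity (λ₂ + λ₃)/2, and λ₁ − λ₃

**Lesion features.** A combined diffusion-weighted image (geometric mean
of the b = 800 directions) supports semi-automated ROI refinement: voxels
below a fraction of the in-seed maximum are excluded, and scalar maps are
averaged over the refined ROI. DCE curves are classified
persistent/plateau/washout by the ±10% rule between the 120 s and 480 s
post-contrast scans, with the lesion's "worst curve" the most suspicious
class present.

**Modeling and validation.** Univariate odds ratios (per 1-SD for
continuous features) come from logistic regression with patient-clustered
sandwich variance; multivariate models use the LASSO with the penalty
chosen by leave-one-patient-out cross-validated deviance; discrimination
is summarized by Mann-Whitney AUC with Harrell-style bootstrap optimism
adjustment, resampling by patient to respect within-patient correlation.

**Synthetic data.** DWI phantoms with known tensors (Gaussian or Rician
noise), DCE curves with known kinetic class, and clustered lesion cohorts
with a known logistic effect structure (~40% malignancy prevalence, 1-3
lesions per patient, class-conditional ADC/FA with a negative copula
dependence).

## Worked example

Simulate a homogeneous benign-mass phantom with eigenvalues
(2.20, 2.00, 1.80) × 10⁻³ mm²/s, fit tensors, refine an ROI on the
combined image and summarize:

```r
library(breastdti)

scheme <- make_gradient_scheme(6, c(0, 100, 800))
cfg <- phantom_config(
  grid_shape = c(5, 5, 3),
  regions = list(tensor_region(c(2.20, 2.00, 1.80) * 1e-3,
                               direction = c(1, 1, 0))),
  s0 = 1000, noise_sigma = 0)
sim  <- simulate_dwi_phantom(cfg, scheme)
maps <- scalar_maps(fit_tensor(sim$dwi))
comb <- combined_dwi(sim$dwi, b_target = 800)
roi  <- refine_roi(comb, as.matrix(expand.grid(1:5, 1:5, 2)), 0.5)
lesion_summary(maps, roi)
#>   mean_adc mean_fa mean_axial mean_radial mean_lambda_diff n_voxels
#> 1    0.002  0.0997     0.0022      0.0019            4e-04       25
```

The lesion reads ADC = 2.00 × 10⁻³ mm²/s and FA = 0.10 — a high-diffusivity,
near-isotropic profile typical of a benign mass.

Simulate a 194-patient cohort, fit univariate and multivariate models, and
validate:

```r
cohort <- simulate_cohort(cohort_config(n_patients = 194, seed = 1))$cohort
fm <- prepare_features(cohort)

univariate_table(fm, c("adc", "fa", "washout", "birads5"))
#>   feature   auc    or or_lo or_hi        p
#> 1     adc 0.689 0.468  0.35 0.625 2.75e-07
#> 2      fa 0.586 1.390  1.07 1.802 1.28e-02
#> 3 washout 0.542 1.792  0.85 3.779 1.25e-01
#> 4 birads5 0.502 0.953  0.35 2.592 9.24e-01
```

Lower ADC is strongly associated with malignancy (OR 0.47 per 1-SD
increase, so higher diffusivity is protective); higher FA is modestly
associated. At 194 patients the binary DCE features are too rare to reach
significance in this draw.

```r
lasso_logistic_lopo(fm, c("adc", "fa"))
#> LASSO logistic fit: 2 candidates, 1 selected (lambda = 0.01261)
#>  adc   fa
#> 0.50   NS

bootstrap_optimism_auc(lasso_spec(c("adc", "fa")), fm, B = 200, seed = 2)
#> AUC: apparent 0.689, optimism-adjusted 0.686 (95% CI 0.632-0.765; B = 200)
```

The DTI-only LASSO keeps ADC (OR 0.50 per 1-SD) and drops FA ("NS");
bootstrap optimism adjustment barely moves the AUC because the model has
only two candidates.

`run_pipeline(pipeline_config(out_dir, seed = 1, n_patients = 200))` runs
the whole chain (simulate → features → models → validation → report) and
writes a report bundle: `cohort.csv`, `univariate.csv`, `multivariate.csv`,
per-model ROC coordinates, AUC comparisons and a JSON manifest that
suffices to re-run the analysis bit-identically. A thin command-line
wrapper lives at `inst/scripts/breastdti-pipeline.R`.

## Documentation

The methods vignette (`vignettes/breast-dti-methods.Rmd`) documents the
signal model, the generator's distributions and their provenance, the
penalty-selection conventions (deviance-minimum vs one-standard-error),
the bootstrap validation design, and known limitations.
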