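# oncospectra

Chemometric analysis of liquid-phase FTIR absorption spectra of blood serum
and plasma ("infrared molecular fingerprints", IMFs) for case/reference
diagnostics. The package is aimed at spectroscopists and biostatisticians who
need a tested, reproducible pipeline from raw absorbance tables to
cross-validated detection efficiencies and per-wavenumber spectral
signatures, without shipping any clinical data: a synthetic serum-spectra
generator with known ground truth stands in for measured cohorts, so every
stage is verifiable at desk scale.

## What it computes

Given a wide spectra table (rows = samples, columns = wavenumbers in cm⁻¹), a
measured pure-water reference spectrum, and a sample metadata table (group,
age, sex, BMI, site, tumour T class), the pipeline runs:

1. **Water-displacement correction.** A liquid sample containing less water
   than the pure-water reference shows apparently negative absorption. Dried
   serum has no significant absorption over 2000–2300 cm⁻¹, so a solute
   spectrum is flat there; the correction adds α·water with the closed form
   α = −slope(s)/slope(water) (OLS slopes over the flat window), zeroing the
   window slope.
2. **Truncation and masking** to 1000–3000 cm⁻¹ with the silent region
   (1750, 2800) removed (endpoints kept), then **L2 vector normalization**,
   optionally a Savitzky–Golay **second derivative** per contiguous segment.
3. **Spectral QC** with a from-scratch local outlier factor (LOF): k-distance
   neighbourhoods (ties included), reachability distances,
   lrd(p) = 1/mean reach, LOF(p) = mean(lrd(neighbours))/lrd(p). Scored on
   water-corrected, masked, *unnormalized* features so abnormally low
   absorbance remains visible.
4. **Covariate matching:** logistic propensity scores on age + sex + BMI,
   Mahalanobis distance on the pooled within-group covariance, and optimal
   1:1 (or 1:k) pair matching within propensity-score calipers
   (default 0.2 × SD of the logit propensity), solved exactly as a
   rectangular assignment problem.
5. **Evaluation:** linear SVM under stratified 10-fold cross-validation
   repeated 10×, reporting fold AUCs (mean ± SD), the pooled ROC, the
   operating point minimizing the distance to the upper-left corner, the
   sensitivity at 95% specificity, and one-vs-one confusion matrices for
   multiclass questions.
6. **Spectral statistics per wavenumber:** differential fingerprint
   Δ(ν) = mean_case − mean_ref against the reference SD, pooled-variance
   Student t p-values, Mann–Whitney AUC = U/(n₁·n₂) with ties counted ½,
   standardized effect sizes Δ/SD_ref, the trapezoidal area under |Δ|
   (never bridging the silent-region gap), and a PCA check for clinical-site
   clustering with a permutation p-value.

## Worked example

Simulate a confounded cohort with a stage-scaled disease signature and 2%
injected artifacts, then run the full study:

```r
library(oncospectra)

sig <- disease_signature(wavenumber_grid())
cfg <- study_config(sim = sim_config(n_cases = 120, n_refs = 150, seed = 7,
                                     covariate_confounding = 1,
                                     outlier_fraction = 0.02),
                    signature = sig, folds = 10, repeats = 10, seed = 7)
report <- run_binary_study(cfg)
report
#> <study_report> 270 -> 261 (QC) -> 192 (matched) samples
#> <cv_evaluation> AUC 0.840 +/- 0.102 (10 x 10 CV); optimal sens/spec 0.75/0.83; sens@95%spec 0.41
report$balance
#>   covariate smd_before  smd_after
#> 1       age  0.6591732 0.05566121
#> 2       sex  0.1053334 0.02099002
#> 3       bmi  0.2943042 0.05427509
report$stats[which.min(report$stats$p_t), ]
#>     wavenumber    delta  sd_ref      p_t auc_w effect
#> 319       1636 -0.00641 0.00373 5.05e-21 0.133  -1.72
```

Reading the output: QC removed 9 spectra (the injected artifacts plus a few
borderline inliers); matching kept 96 case/reference pairs and shrank the
age imbalance from 0.66 to 0.06 standardized mean differences; the
cross-validated detection efficiency is AUC 0.840 ± 0.102; the strongest
spectral feature sits at 1636 cm⁻¹ with a per-wavenumber AUC of 0.13
(equivalently 0.87 for the reference direction) and standardized effect −1.7.

Stage-stratified performance (the tumour-load dependence) comes from
`run_stage_comparison(cfg)`; multiclass questions from
`run_multiclass_study()`.

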