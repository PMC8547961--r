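---
title: "Methods: infrared molecular fingerprinting of blood-based liquid biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infrared molecular fingerprinting of blood-based liquid biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and the diagnostic question

Fourier-transform infrared (FTIR) transmission spectroscopy of liquid blood
serum or plasma yields a broadband mid-infrared absorption spectrum — an
*infrared molecular fingerprint* (IMF) — that integrates contributions from
all abundant molecular species at once. The diagnostic hypothesis is that a
disease process (here, a solid tumour) leaves a reproducible compositional
footprint in peripheral blood that shifts the IMF of cases relative to
carefully matched reference individuals, and that the shift grows with
tumour load.

`oncospectra` implements the complete analysis chain for that question:
chemometric preprocessing, spectral quality control, covariate-balanced
cohort construction, cross-validated linear-SVM evaluation, and
per-wavenumber statistics, plus a synthetic cohort generator so the whole
chain is testable without clinical data.

## Preprocessing model and assumptions

Spectra live on a uniform wavenumber grid, by default 950–3050 cm⁻¹ sampled
every 2 cm⁻¹ (an acquisition at 4 cm⁻¹ optical resolution is conventionally
sampled at half the resolution; the spacing is configurable).

**Water-displacement correction.** Absorbance is measured against a
pure-water reference. A sample that contains less water than the reference
(because solutes displace it) shows an apparently negative water absorption
component. Dried serum and plasma show no significant absorption over
2000–2300 cm⁻¹, so the *solute* part of a spectrum is flat there and any
residual slope in that window is attributed to displaced water. We add
α·water and choose α to zero the ordinary-least-squares slope of the
corrected spectrum over the window. Minimizing the absolute average slope
has the closed form α = −slope(s)/slope(water); a grid search over
α ∈ [−2, 2] confirms the closed form in the tests. The correction is
undefined when the water reference itself has (numerically) zero slope over
the window; that case raises an explicit error rather than returning a
garbage coefficient. α may legitimately be negative (a sample *more* dilute
than the reference).

**Truncation and masking.** Features are restricted to 1000–3000 cm⁻¹ and
the silent region between 1750 and 2800 cm⁻¹ is removed. Whether the
printed endpoints themselves survive is a convention choice; we keep them
(closed keep-range, open silent interval), so the default grid retains
376 + 101 = 477 points. The operation is idempotent.

**Normalization and derivative.** Spectra are scaled to unit Euclidean (L2)
norm, which removes overall concentration/pathlength scale. An optional
Savitzky–Golay second derivative (default window 9 points, polynomial order
3 — a common chemometrics choice, configurable; no authoritative values
exist) is computed per contiguous grid segment, so the two retained ranges
are never smoothed across the silent-region gap.

Every preprocessing step is strictly per-sample: no statistics are shared
across samples, so preprocessing cannot leak information from test folds
into training folds downstream. Order is fixed: water correction →
masking → normalization → derivative.

## Spectral quality control

Anomalous spectra (abnormally low absorbance from a failed measurement,
spurious contamination bands) are flagged with a local outlier factor (LOF)
implemented from first principles: the k-distance neighbourhood includes
every point tied at the k-th distance; reachability distance
reach(p, o) = max(kdist(o), d(p, o)); local reachability density is the
reciprocal mean reachability; the LOF score is the mean ratio of neighbour
densities to the point's own density (≈1 for inliers). Duplicated points are
handled by the reachability construction; in the fully degenerate case of
more than k exact copies the ratio of two infinite densities is taken as 1,
keeping all scores finite.

Two details were genuinely open and are decided as follows:

* **Feature space.** QC is scored on water-corrected, masked,
  **unnormalized** features. Both the water correction and L2 normalization
  are scale-equivariant/invariant, so a globally scaled-down spectrum is
  mapped exactly onto its unscaled twin after normalization — an
  "abnormally low absorbance" anomaly only exists before normalization.
* **Flagging rule.** Either a fixed cutoff (default 1.5) or a top-fraction
  rule; exactly one may be active, and the rule is recorded in provenance.
  The removal count reported for any given clinical dataset is data-specific
  and not transferable, hence no attempt to reproduce one.

The default neighbour count is k = 20, the conventional default of standard
LOF implementations.

## Statistical matching

Observational case/reference contrasts are confounded by age, sex and BMI.
We build balanced cohorts by optimal pair matching: a logistic propensity
model of group membership on the three covariates, Mahalanobis distance on
their pooled within-group covariance, and an exact solution of the
rectangular assignment problem restricted to pairs whose logit-propensity
difference is within a caliper (default 0.2 × SD of the pooled logit
propensity — the standard observational-studies convention; the width used
in any particular prior study is not published). Out-of-caliper pairs enter
the solver as large finite penalties and are verified and stripped
afterwards, so infeasibility degrades gracefully into unmatched cases. The
assignment is solved by shortest augmenting paths with potentials
(Jonker–Volgenant style), checked in the tests against exhaustive
enumeration on all instances up to 7×7. 1:k matching replicates each case k
times; a case that cannot secure all k admissible references is reported
unmatched. Ties are broken deterministically by sample-id order. Sex enters
the distance as a 0/1 indicator inside the pooled covariance; exact matching
on categories and matching with replacement are out of scope.

Balance is reported as standardized mean differences (SMD), with the pooled
SD taken from the full pre-match sample for both columns (the usual
diagnostic convention, so before/after are on the same scale).

A known behaviour worth stating plainly: the optimal-total-distance
objective under a caliper will trade a few sex mismatches for closer age and
BMI, so when the *realized* sex imbalance of a drawn cohort is already near
zero, its post-match |SMD| can exceed the pre-match value even though age
and BMI improve dramatically. Matching improves the *mean* |SMD| essentially
always; strict per-covariate improvement for a weakly confounded binary
covariate is a coin flip by construction.

## Classification and evaluation

The classifier is a soft-margin linear SVM (libsvm via e1071, C = 1 by
default, no internal feature scaling), exposing continuous decision scores
("disease likelihood") rather than only hard labels. Evaluation is
stratified k-fold cross-validation (default 10 folds) repeated (default 10×)
with fold assignment re-randomized per repeat from one seed. We report the
per-fold AUC distribution (mean ± SD) and build ROC *curves* from the pooled
held-out decision scores — fold AUCs answer "how variable is performance",
the pooled curve answers "what operating points exist"; which of the two a
given published curve used is rarely stated, and the package computes both.

AUC is the Mann–Whitney probability estimate with ties counted ½, computed
via midranks; it equals the trapezoidal area under the threshold-sweep ROC
exactly, and is invariant under strictly monotone transforms of the scores.
The optimal operating point minimizes the Euclidean distance of realized ROC
vertices to the upper-left corner (ties broken toward higher sensitivity);
sensitivity-at-95%-specificity uses the conservative step convention (the
best realized vertex with specificity ≥ 0.95, no interpolation).

Multiclass questions use one-vs-one linear SVMs with majority vote, vote
ties broken by the aggregate signed decision score; confusion counts
accumulate over all held-out folds, per-class accuracy is class recall, and
the overall accuracy is reported as mean ± SD over fold accuracies. For
three balanced classes with no signal the chance level is 1/3.

One caveat the tests encode explicitly: with unit-norm features and C = 1
the SVM can sit in an underfit regime where margins are unattainable and the
intercept is pinned only by class counts. Rank-based metrics (AUC) are
unaffected, but hard votes are only trustworthy when classes are genuinely
separated — which is how the multiclass positive controls are constructed.

## Per-wavenumber statistics

For two groups of spectra we compute, per retained wavenumber: the
differential fingerprint Δ = mean(cases) − mean(references) against the
reference-group SD (ddof = 1); the two-tailed p-value of the pooled-variance
Student t-test (the classical equal-variance form; Welch is available behind
a flag but off by default); the Mann–Whitney AUC = U/(n₁n₂) with
U = #{case > ref} + ½#{ties}, computed exactly (no normal approximation) and
reported *oriented* (cases as positive class, values < 0.5 meaning cases run
lower) rather than folded about 0.5 — folding is a display choice;
the standardized effect Δ/SD_ref, whose binormal relation
AUC = Φ(effect/√2) for Gaussian equal-variance groups is verified in the
tests; and the trapezoidal area under |Δ| summed over contiguous segments,
never integrating across the silent-region gap. Zero-pooled-variance
wavenumbers yield p = 1 when the means agree and p = 0 (a degenerate
perfect separation, worth flagging) otherwise. No multiple-testing
correction is applied to the per-wavenumber p-values by default; a
Benjamini–Hochberg view is a one-liner with `p.adjust` if wanted.

The site check runs PCA on the centered spectra of one diagnosis group,
keeps the smallest number of components reaching 95% cumulative explained
variance, and tests between-site centroid separation in that subspace with a
label-permutation p-value (999 permutations by default).

## The synthetic cohort generator

The generator emulates the statistical structure of liquid-serum FTIR
cohorts, not serum chemistry:

* **Band model.** Eight Gaussian absorption bands (amide I 1652 cm⁻¹
  dominant, amide II 1545, CH deformations 1455/1400, carbohydrate region
  1080/1160, lipid ester 1740, C–H stretch 2930) with per-person log-normal
  amplitudes (mean 1, CV 5–15% per band) modelling between-person biological
  variability of the underlying concentrations.
* **Water displacement.** A deterministic synthetic water reference (bending
  band at 1640 cm⁻¹, rising O–H stretch flank, weak association band, and a
  gentle linear ramp that keeps the 2000–2300 cm⁻¹ slope identifiably
  nonzero) is subtracted with a log-normal deficit β whose mean is
  proportional to the realized total solute load — more solute displaces
  more water. The generator returns the true β per sample so the correction
  can be tested for exact recovery.
* **Noise.** Additive Gaussian measurement noise, default SD 0.002 AU. No
  authoritative number exists (only the qualitative statement that
  measurement error is small against between-person variability); 0.002 AU
  keeps the measurement-to-biological variance ratio well below 1%.
* **Disease signature.** A unit-L2-norm differential shape (amide II up,
  amide I down, carbohydrate up, C–H stretch up) scaled by a per-T-class
  amplitude δ(T1..T4) = 0.10, 0.15, 0.22, 0.30 AU. The shape deliberately
  lies largely in the span of the biological band variation, so detection
  difficulty is governed by between-person variability rather than by
  instrument noise; the amplitudes were calibrated once against the measured
  along-signature biological SD so the stage ladder spans weak-to-strong
  detectability (cross-validated AUC roughly 0.6–0.95) and then frozen.
* **Confounding.** Age and BMI always scale the amide II and lipid ester
  bands with small fixed coefficients (physiology leaking into spectra);
  the `covariate_confounding` knob shifts only the case-vs-reference
  covariate distributions (+5 y age, +0.10 sex probability, +1.5 BMI per
  unit). With δ = 0 and confounding 0 the generator is an exact null.
* **Artifacts.** `inject_artifacts` replaces a chosen fraction of spectra
  with either ×0.2 globally scaled absorbance or an added narrow
  contamination band centered inside the retained analysis windows — a band
  confined to the discarded silent region would not be an anomaly in the
  analysed data.

What passing tests on this generator do **not** show about real data:
real serum has hundreds of overlapping bands, heteroscedastic and
batch-structured noise, instrument drift, and disease signatures that are
neither a single shape nor stage-proportional. The generator establishes
that the *pipeline machinery* is correct and calibrated, not that any
particular clinical AUC is reproducible.

## Numerical choices and degenerate inputs

* Water correction requires |slope(water)| > 1e-12 over the flat window;
  corrected windows are flat to better than 1e-9 relative to the spectrum
  maximum.
* Grid uniformity is enforced to 1e-9; contiguous segments are split where
  the spacing jumps by more than 1.5×.
* The assignment solver demands finite costs; forbidden pairs use a penalty
  two orders above the dummy-unmatched cost so cardinality is prioritized
  before total distance, and results are verified against the caliper after
  the solve.
* LOF requires n > k; zero distances are absorbed by the reachability
  construction and infinite-density ratios resolve to 1.
* Zero pooled SD in the balance table yields SMD 0 when means agree and an
  error otherwise; a singular pooled covariance in the Mahalanobis step
  raises an error advising to drop the constant covariate.
* Determinism: one integer seed drives cohort generation and every fold
  assignment; identical configurations reproduce byte-identical cohorts and
  fold AUCs.

## Pipeline order

The study runners fix the stage order: QC → preprocessing → matching →
evaluation → statistics. QC precedes matching so removed spectra never
consume references. Matching is performed once per clinical question on the
retained cohort, *before* cross-validation: it uses only covariates, never
spectra, so it cannot leak spectral information across folds; this is a
deliberate, documented departure from nesting every selection step inside
the resampling loop.

## Problem sizes used in the tests

Unit tests run at small scale (tens of samples; exhaustive oracles up to
7×7 matchings, 30-point LOF instances, group sizes ≤ 8 for pair-enumeration
AUC). The end-to-end calibration checks use the scales the methods are meant
for: 100/class three-group chance-level runs and 200/200 null and
stage-ladder runs under 10×10 cross-validation, with null-calibration bands
assessed on means over three independent cohorts because a single fixed
cohort carries an irreducible AUC spread of about ±0.03.

## Known limitations

* The linear-SVM intercept is only count-calibrated in the underfit regime
  (see above); operating points on weak signals should be read from the
  pooled ROC, not from hard votes.
* Strict per-covariate balance improvement cannot be guaranteed for
  covariates whose realized pre-match imbalance is already within sampling
  noise of zero; the matcher optimizes total Mahalanobis distance under the
  caliper, not per-covariate SMDs.
* No EMSC/scatter correction, atmospheric-line correction, nonlinear
  kernels, probability calibration, or external-validation workflow; the
  per-wavenumber statistics are descriptive (no multiplicity correction by
  default).
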