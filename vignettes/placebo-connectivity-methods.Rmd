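---
title: "Methods: resting-state connectivity prediction of placebo antidepressant response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state connectivity prediction of placebo antidepressant response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sham ("placebo") transcranial magnetic stimulation produces clinically
meaningful but heterogeneous antidepressant responses. This package
implements, as a reusable and tested pipeline, a baseline resting-state fMRI
analysis that asks whether a patient's pre-treatment functional connectivity
predicts that placebo response, measured as the fractional reduction of the
17-item Hamilton Depression Rating Scale:

HDRS\_%change = (HDRS\_baseline − HDRS\_post) / HDRS\_baseline.

The pipeline comprises (1) CONN-style temporal denoising, (2) two
per-subject connectivity summaries — voxelwise global brain connectivity
(GBC) and rostral-ACC seed-based Fisher-z functional connectivity (FC) —
(3) a covariate-adjusted group t-map with cluster-extent family-wise-error
(FWE) inference, and (4) elastic-net leave-one-out (LOOCV) prediction of
HDRS\_%change with permutation inference. Because the study data this analysis was designed around cannot be
shared, the package ships a synthetic cohort generator with
planted ground truth; every stage is validated against what was planted.

## Denoising model

Per run, the nuisance design contains: the six rigid-body motion parameters
and their backward-difference temporal derivatives (first frame = 0);
per-outlier scrubbing indicators; and either (a) *aCompCor* — the top five
principal component time series from the white-matter mask and five from
the CSF mask, always computed from **unsmoothed** data, each voxel series
mean-centered and linearly detrended before the PCA — or (b) *global signal
regression* — the brain, WM and CSF mean signals. With no outliers this
yields 22 (aCompCor) or 15 (GSR) columns.

Outliers are frames whose composite motion (framewise displacement,
FD = Σ|Δtranslation| + 50 mm · Σ|Δrotation|) **or** z-scored global-signal
change strictly exceeds the within-subject empirical 97th percentile of the
respective series. The external tool that inspired this rule uses normative
thresholds that are not reproducible outside that tool; within-subject
empirical percentiles are self-contained and monotone in the same
parameter. Strictness at the threshold means a constant series flags
nothing. Flagged frames are regressed (indicator columns), not deleted —
deletion-versus-regression is unspecified in the published recipe, and
regression keeps the time axis intact for the band-pass.

The post-regression chain runs in a fixed order: OLS confound regression
(intercept added, rank-deficient columns dropped with a warning) → linear
detrend → tanh despiking → band-pass. The despiker maps x to
c + a·tanh((x − c)/a) with c = median and a = k·1.4826·MAD (k = 3): robust
statistics make the operation insensitive to the spikes it removes, and
the published recipe names only the function family, not its parameters. The band-pass is
an ideal (boxcar) frequency-domain filter retaining bins in [0.01, 0.1] Hz
inclusive and always removing DC; it was chosen over a Butterworth design
because its attenuation properties are exactly testable (retained ≥ 0.99,
rejected ≤ 0.01 on on-grid sinusoids). Spatial smoothing (6-mm FWHM
separable Gaussian, kernels renormalized at the grid boundary so constants
are preserved) is applied to the BOLD input before connectivity; whether
smoothing precedes or follows temporal denoising is not stated in the
published recipe — this package smooths first (SPM convention), and aCompCor always
sees unsmoothed data (asserted by a wiring test).

## Connectivity measures

GBC_i = (1/n) Σ_j r_ij², the mean squared Pearson correlation of voxel i
with all n in-brain voxels, self-term included — exactly as the formula
prints. The printed superscript is typographically ambiguous; the squared
reading is the default and a signed-mean variant (mean of r) is available
behind a flag. Excluding the self-term would change values by O(1/n); it is
included as printed. GBC is computed in chunks with a tested contract that
the result is independent of chunk size, and equals a brute-force double
loop to 1e−10.

Seed FC uses a 6-mm-diameter sphere centered at MNI (0, 38, 4) (rostral
ACC); the seed series is the mean of in-mask voxels whose centers lie
within the radius (inclusive), and z_i = atanh(r_i) with r clipped to
±(1 − 1e−7). Constant voxel series get z = 0 with a warning.

## Group inference

The group map is a voxelwise one-sample t-test of the subject FC maps with
mean-centered age, sex and mean-FD covariates; the statistic is the
intercept t at df = n − 1 − #covariates. Cluster-extent FWE replaces the
original random-field-theory correction (RFT smoothness estimation is out
of scope) with Freedman–Lane sign-flip permutation: subject maps are
residualized on the covariate-only model, residuals sign-flipped, the
covariate fit re-added, the full model refit, and the maximum
supra-threshold cluster size recorded; corrected
p = (1 + #{max null ≥ observed}) / (1 + n_perm). The voxel-forming
threshold is two-sided p < .001 at the model df; clusters use
18-connectivity (SPM convention; 6 and 26 available); positive and negative
clusters are reported separately.

## Prediction model

Voxel maps predict HDRS\_%change under LOOCV. Per fold: the outcome is
residualized on age/sex/mean-FD fitted on the training subjects only (the
published description says only that covariates were included; residualization on
training folds is the leakage-safe common reading, and appending covariates
as unpenalized predictors is available by flag); features are standardized
by training-fold mean/SD; the elastic-net mixing (grid {0.1, 0.5, 0.9}) and
penalty strength (20 log-spaced values per mixing, fold-specific
lambda-max) are chosen by inner LOOCV MSE; the held-out residual is
predicted and its covariate component re-added. Performance is Pearson r
and MSE between predicted and observed outcomes on the fraction scale
(matching the magnitude of the printed MSE ≈ 0.05; whether the published analysis
used percent or fraction scale is inferred from that magnitude).

Permutation inference shuffles the outcome vector only (covariates stay
with their subjects) and re-runs the full procedure; p-values use the
add-one formula and are never zero. Whether the published analysis re-selected
hyperparameters per shuffle is unstated: both modes exist
(`reuse_hyperparams`), with full re-selection the default and reuse the
documented speed reduction for desk-scale simulations. A one-point
hyperparameter grid makes observed and permuted runs exactly exchangeable,
which the null-calibration acceptance test exploits. When a permutation
yields constant predictions (maximal penalty), its r is defined as 0.

The final weight map is a whole-sample fit at the modal fold-selected
hyperparameters, with coefficients mapped back to unstandardized voxel
scale; reporting thresholds nonzero-weight clusters at 100 voxels,
labeling positive and negative weights separately so adjacent
opposite-sign blobs never merge. A specificity control runs the identical
procedure with HDRS\_baseline as outcome.

## The synthetic world

The generator emulates the published cohort description: n = 22, 16/22
female, age ~ N(43, 12.24) truncated to [18, 61], HDRS\_baseline ~
round(N(22, 6)) ≥ 8, outcome mean ≈ 9.3% and SD ≈ 26% of baseline. Runs are
desk-scale by default (20×20×14 grid of 3-mm voxels, 150 volumes at
TR = 2 s; the full 300-volume acquisition is one config field away). The brain
is an ellipsoid with an interior CSF blob and WM shell; the seed region
(radius 6 mm) sits at (0, 38, 4) on the default grid with two target
regions (precuneus/PCC- and MFG-like analogs), scaled to fractions of the
brain half-extent on other grids.

Signals: the seed shares a band-limited latent s(t) (sum of sinusoids in
[0.015, 0.095] Hz, unit SD); target voxels carry β_s·s(t) with β_s ~
N(0.8, 0.25) across subjects; every brain voxel additionally has its own
*spatially smooth* band-limited intrinsic signal (SD 0.6) plus white noise
(SD 0.8); WM and CSF share compartment signals that leak (weight 0.15)
into gray matter; drift is a per-voxel linear slope plus per-voxel
half-cosine (amplitude 1.5). Two of these choices were corrections made
after diagnosing unrealistic behaviour, and are worth knowing about when
interpreting green tests: (1) without intrinsic in-band power, band-passed
voxels contain almost nothing but the latent and Fisher-z saturates near
its ceiling, hiding coupling differences; (2) a perfectly global drift
leaks through the ideal filter as a rank-one common signal that drives
region-mean correlations to ~0.98 regardless of coupling. Both fixes make
the world harder, not easier, and no acceptance threshold moved.

Artifacts: spikes occur at rate 0.02 per frame (below the ~3% capacity of
a 97th-percentile scrubbing rule — a rule can only recover artifacts rarer
than its flagging budget), adding a global intensity jump of 5 noise-SD and
a persisting motion step; motion is otherwise a bounded random walk.

The outcome is intercept − here −0.467 − plus 0.7·β_s plus optional
covariate terms plus N(0, 0.19) noise, then mapped to integer HDRS pairs so
the percent-change formula is exact. The intercept field is an addition to
the configured model: without it, matching the printed outcome mean (9.31%)
and keeping coupling predominantly positive (required for the planted
seed-FC margin property) are incompatible. With these defaults the outcome
mean is ≈ 0.093 and SD ≈ 0.258, mirroring the printed 9.31% ± 26.04%.

What a green test does **not** establish: the generator has no scanner
physics, slice timing, susceptibility distortion, anatomical variation,
registration error, or physiological (cardiac/respiratory) noise; its
"brain" is an ellipsoid and its artifacts are caricatures. Green tests
establish that the *pipeline machinery* is correct and calibrated on a
world whose ground truth is known — not that the original study's effect
sizes would replicate.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based internally; all reported coordinates are world
  mm via the affine; `world_to_voxel` rounds half-way ties toward +Inf.
* TR comes from configuration, not NIfTI headers (headers are unreliable);
  a conflicting header TR warns.
* NIfTI-1 I/O is implemented in-package (no R NIfTI package is available in
  the target environment) and is cross-checked against nibabel in the test
  suite; float32 round-trips are tested at 1e−6, float64 exactly.
* Zero-variance voxels: dropped from the GBC mask (warning), z = 0 in seed
  FC (warning), excluded from prediction features (count logged).
* All-identical subject maps: the group t is reported as an infinite marker
  with a warning rather than an error.
* Identical pre/post HDRS vectors give paired t = 0, p = 1; constant
  *nonzero* differences are an error (undefined t).
* Published-table conventions: the published demographics table mixes t-test
  conventions — its age-row p (0.55) reproduces only under Welch, its
  percent-change row (0.71) only under pooling. `two_sample_t_summary`
  defaults to pooled and offers `var_equal = FALSE`; the tests assert each
  row under the convention that reproduces it.
* Short desk-scale runs (300 s) are below ten cycles of the 0.01 Hz cutoff;
  validation emits a warning finding rather than refusing, since the
  full acquisition-length run is available by config.

## Limitations

Permutation counts in shipped simulations are reduced (199–999) relative
to the published 1,000 for runtime; the p-value floor scales accordingly.
GSR-based denoising interacts with the planted latent on small grids
(planted regions are a non-trivial fraction of the global mean), so
strategy-agreement checks run on the default grid where that fraction is
realistic. The real-data headline values (r ≈ .49, MSE ≈ .05) are not
reproduction targets: the data are unavailable, and this package's claims
are about machinery, calibration and recovery of planted effects.
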