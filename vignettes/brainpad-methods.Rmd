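---
title: "Brain-age prediction and brain-PAD analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age prediction and brain-PAD analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainpad)
```

## The problem

Structural MRI carries a robust ageing signature: grey-matter (GM) and
white-matter (WM) volumes decline from young adulthood onwards in a
spatially patterned way. A model trained to predict chronological age from
tissue maps of healthy individuals therefore defines a *normative brain
age*. Applying that model to a clinical group and subtracting chronological
age yields the **brain-predicted age difference**,

$$\text{brain-PAD} = \hat{a} - a \quad [\text{years}],$$

positive when a brain appears older than its owner. Group differences in
brain-PAD — for example between adults with Prader-Willi syndrome (PWS) and
matched controls — quantify premature or accelerated brain ageing, and the
same model supports single-subject comparison against a normative cohort,
which matters for very rare genotypes (e.g. a SNORD116 microdeletion
carrier) where only one case may exist.

`brainpad` implements this chain end to end: tissue-map handling and
vectorization, similarity-kernel Gaussian-process regression (GPR) of age,
10-fold cross-validation with permutation significance, brain-PAD scoring,
and the downstream cohort statistics (pooled t-tests from raw data or
printed summaries, chi-squared, Mann-Whitney U, Pearson correlation,
covariate-adjusted group effects, interaction tests, BMI-matched
subcohorts, single-subject z-scores). Because raw clinical scans cannot be
redistributed, the package also ships a synthetic-data generator that
emulates normalized tissue maps with a known ageing signal, so every stage
is testable and every reported quantity is recomputable from code alone.

## The prediction model

Each subject's normalized GM and WM tissue-probability maps are masked and
concatenated into one feature vector $x_i$ (GM block first, WM block
second, column-major voxel order; the ordering is irrelevant to a
dot-product kernel but is fixed for determinism). The model works entirely
through the $N \times N$ similarity kernel

$$K_{ij} = x_i \cdot x_j,$$

by default divided by the feature length (`by_voxel_count`) so entries are
O(1) regardless of grid size. The kernel is validated as symmetric and
positive semidefinite (tolerances $10^{-10}$ relative asymmetry,
$-10^{-8}\,\mathrm{tr}(K)/N$ minimum eigenvalue).

Age regression is a Gaussian process with constant mean
$\mu = \overline{y}$ (the training-age mean) and covariance
$C = s\,K + \sigma_n^2 I$:

$$\hat{a}_* = \mu + s\,k_*^\top (s K + \sigma_n^2 I)^{-1} (y - \mu),$$

where $k_*$ is the test subject's cross-kernel row. For fixed
hyperparameters this is exactly closed-form kernel ridge regression — the
test suite exploits this as the module's primary oracle, requiring
agreement within $10^{-8}$ on random small instances. The two
hyperparameters (signal scale $s$, noise variance $\sigma_n^2$ in years²)
are chosen by maximizing the Gaussian log marginal likelihood with L-BFGS-B
on log-parameters from three fixed starting points. All solves run through
one symmetric eigendecomposition of $K$, so repeated likelihood evaluations
cost $O(N^2)$; if the decomposition reports eigenvalues below
$-10^{-8}\,\mathrm{tr}(K)/N$, a jitter of that magnitude is added once to
the diagonal.

Numerical consequences worth knowing:

* multiplying all features by $c > 0$ rescales $K$ by $c^2$ and is absorbed
  by the optimizer — predictions are invariant (tested);
* adding a constant to all training ages shifts every prediction by exactly
  that constant (tested);
* a test subject with a zero cross-kernel row reverts to the prior mean
  $\mu$;
* constant training ages produce constant predictions.

### Cross-validation and permutation testing

`cv_gpr()` assigns subjects to 10 near-equal folds by a seeded random
permutation (fold sizes differ by at most one; fewer folds with a warning
when $N < 10$). Hyperparameter optimization happens *inside each training
fold only*, so no information leaks from the held-out fold — whether the
original toolchain optimized per fold or globally is not documented
anywhere we could rely on, and per-fold is the leakage-free default.
Accuracy is summarised by Pearson $r$, $R^2 = r^2$, MAE and RMSE of the
out-of-fold predictions.

`permutation_test_gpr()` permutes the age labels uniformly and repeats the
full cross-validation per permutation. A dot-product kernel does not
depend on the labels, so the kernel and fold assignment are computed once
and reused; only the per-fold solves are repeated. The statistic is the CV
Pearson correlation, one-sided upper tail, with add-one smoothing:
$p = (1 + \#\{r_\pi \ge r_{obs}\}) / (1 + n_{perm})$.

No "regression-to-the-mean" correction is applied to brain-PAD: the
reference analysis applies none, and the package mirrors that. (GPR
shrinkage means predictions are slightly compressed toward the training
mean; with a wide training age range the resulting attenuation of group
differences is small — the recovery experiment below quantifies it.)

## The synthetic-data generator

`atrophy_model()` defines a linear-atrophy phantom on a desk-scale grid
(default $24 \times 28 \times 24$ voxels at 4 mm; the acceptance
experiments use $12 \times 14 \times 12$ at 8 mm to keep 50-replicate runs
in the minutes range — these sizes are the package's own choice of problem
scale). The grid is treated as the intracranial bounding region: baseline
GM forms the outer shell and WM the core of an ellipsoid, scaled so
GM + WM < 1 everywhere, and CSF fills the remainder, which makes
$\mathrm{gm} + \mathrm{wm} + \mathrm{csf} = 1$ exactly at every voxel
before noise (a tested invariant) and gives a realistic litre-scale
intracranial volume without a separate head mask.

For a subject with effective age $a$:

$$\mathrm{gm} = \mathrm{clip}_{[0,1]}\!\big(B_{gm} - S_{gm}\,(a + \eta) +
\varepsilon\big),$$

and analogously for WM, with

* $S = \text{rate} \times B$: fractional loss per year (defaults 0.4 %/y
  GM, 0.15 %/y WM — the order of magnitude reported for adult GM/WM
  decline), guaranteeing non-negative probabilities up to `age_max` (90 y);
* $\eta \sim N(0, \texttt{subject\_sd\_years}^2)$, default SD **5 years**:
  a per-subject brain-age deviate shared between GM and WM. This is the
  biological heterogeneity that makes control cohorts show brain-PAD SDs
  of several years in practice; without it, synthetic brain-PAD variance
  collapses to voxel noise and group CIs become unrealistically narrow;
* $\varepsilon$: i.i.d. per-voxel noise, default SD 0.02 probability
  units;
* optional Gaussian smoothing, default FWHM 4 mm, matching the common
  preprocessing choice, with $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$
  per axis and nearest-edge replication at the boundary (the boundary mode
  is unstated in the reference pipeline; replication is documented here and
  conserves tissue mass for interior-supported content, a tested
  invariant).

The group-level ageing offset $\Delta$ (`delta_years`) enters **only** the
patient group's effective age, $a = \text{chronological} + \Delta$, never
the recorded chronological age — this is precisely the signal brain-PAD is
supposed to detect, so the generator provides the ground truth for
recovery experiments. The per-subject deviate $\eta$ likewise lives only in
the maps; the cohort table's `effective_age` column remains exactly
chronological age plus $\Delta$.

Demographics emulate the reference case-control design: n = 20 patients /
40 controls, ages uniform on 19–29, 70 %/65 % male, BMI and IQ from
normals truncated to the printed ranges (only mean/SD/range are published,
so a truncated normal is the minimal faithful choice). The normative
training cohort defaults to n = 300 with ages uniform on 18–90, mirroring
the wide age span of the real training population; a wide span also keeps
GPR shrinkage of group differences small.

### Seeding

One master seed drives everything. Subject $j$ of group $g$ receives the
sub-seed $(\text{master} \cdot 1000003 + g \cdot 65537 + j) \bmod
(2^{31}-1)$, so enlarging a cohort appends subjects without reshuffling
existing ones (tested). Demographics are drawn directly from the
sub-seed's stream; map noise uses a fixed Lehmer scramble
($\text{seed} \cdot 48271 \bmod 2^{31}-1$) of the same sub-seed. The
scramble matters: the first draws of two streams seeded with the *same*
integer coincide, which would make the subject's brain-age deviate a
near-deterministic function of their age and let the model "predict" age
from what should be independent noise. Decoupling the streams is what
makes the synthetic CV error honest (≈ the 5-year deviate, matching the
MAE scale reported for real cohorts) rather than spuriously near zero.

### What the generator does and does not emulate

It reproduces: spatially varying, monotone-in-age tissue loss; subject
heterogeneity in apparent brain age; voxel noise and smoothing; tissue
closure; realistic group designs and covariate distributions. It does
**not** emulate scanner artefacts, field-strength or site effects,
registration error, non-linear ageing trajectories, or spatially
structured disease effects beyond a uniform ageing offset. Passing
recovery tests therefore shows the *pipeline* is unbiased and calibrated
under its stated model — it does not certify accuracy on real scans, and
the published real-data CV metrics (r = 0.94, MAE 5.01 y on n = 2001
scans) are context, not targets, since the original scans and exact mask
are unavailable.

## Cohort statistics

* **Pooled (Student) t-test**, raw or from (n, mean, SD) triples. The
  pooled rather than Welch variant is used because it exactly reproduces
  the published effect ± SEM chain for the brain-PAD comparison
  (7.24 ± 2.20, t = 3.29 from the printed group summaries) — reproducing
  the printed numbers identifies the variant. `t_test_from_summary()` and
  `t_test_pooled()` agree to $10^{-10}$ by construction (tested), which is
  what lets published tables stand in for unavailable raw data.
* **Chi-squared (2×2)** without Yates correction by default — the
  convention that matches the printed sex-table p ≈ 0.70; a flag enables
  the correction.
* **Mann-Whitney U** via `stats::wilcox.test`: exact for small tie-free
  samples (both n < 20), otherwise normal approximation with tie
  correction; U is reported as pair wins. The test oracle is exhaustive
  pair enumeration.
* **Covariate adjustment** by OLS of brain-PAD on intercept + group +
  covariates on their *raw* scale (published coefficients are raw-scale;
  standardization would change them). Rank deficiency is an error naming
  the collinear terms. No multiple-testing correction is applied,
  mirroring the reference analysis; this is a deliberate fidelity choice.
* **Interaction tests**: OLS with a group × covariate product term; the
  interaction p answers "do the groups share a slope?".
* **BMI matching**: patients are kept when BMI ≤ the control maximum,
  controls when BMI ≥ the patient minimum. The published description
  prints strict inequalities yet retains subjects exactly at the
  boundary, so ≤/≥ is the documented convention here.
* **Single-subject comparison**: z-score against normative mean/SD plus a
  mid-rank empirical percentile.

The packaged fixture `pws_reference_stats()` stores the printed per-group
summaries, keeping two published inconsistencies verbatim rather than
resolving them: the cohort-2 control brain-PAD SD appears as both 6.48
(results) and 6.52 (abstract), and the cohort-1 age-comparison P as both
0.74 (table) and .73 (text). Accessors default to the results printing.

## The pipeline and its validation experiments

`run_pipeline()` chains simulate → features/mask → kernel → CV → final fit
→ predict → statistics under one master seed and returns a manifest of
content hashes; identical configs give identical manifests (tested). The
analysis mask (cohort-mean GM + WM > 0.05 — no published mask exists, so
the threshold is configurable) is derived from the *training* cohort and
applied unchanged to test subjects, as a deployed model requires.

Three seeded experiments back the acceptance suite, at sizes chosen to
run in minutes on one core:

1. **Delta recovery** (`evaluate_delta_recovery()`): 50 replicates of
   train-n = 300 (Δ = 0, ages 18–90), test 20 patients (Δ = 7) vs 40
   controls (ages 19–29), reduced grid. Checks the mean estimated group
   difference lands within ±1.5 y of 7 and the 95 % CIs cover the truth
   ≥ 90 % of the time. Residual GPR shrinkage biases the mean estimate
   slightly below Δ (≈ 0.5 y at these settings), well inside the band.
2. **Permutation calibration**
   (`evaluate_permutation_calibration()`): 200 pure-noise datasets,
   n_perm = 99; the rejection rate at α = 0.05 must sit inside the exact
   binomial 95 % interval. Fixed hyperparameters are used inside this
   loop: under label exchangeability the permutation test is exact for
   *any* fixed fitting procedure, and this keeps 200 × 100
   cross-validations tractable; per-fold optimization remains the default
   everywhere else.
3. **Null CI coverage** (`evaluate_ci_coverage()`): 500 two-group null
   datasets; the pooled-t 95 % CI must cover zero at the nominal rate
   within exact binomial bounds.

A fourth, cheap check reproduces the published summary-statistic chain
end-to-end from the fixture (effect 7.24, SEM ≈ 2.20, t ≈ 3.29; IQ effect
49.8, |t| ≈ 15.9; BMI effect 6.0; single-subject +12.87 = 37.36 − 24.49,
z ≈ 1.86 against 0.84 ± 6.48).

## Degenerate inputs and edge behaviour

Empty masks vectorize to length-0 with a warning; all-equal samples make
the pooled t-test error (zero pooled variance) rather than return NaN;
constant covariates are rejected as rank-deficient; zero-variance
normative cohorts cannot be used for z-scores; effective ages outside the
atrophy model's validity range warn and clip; disjoint BMI ranges empty
both groups with a warning. Ties in the Mann-Whitney U switch the exact
enumeration off in favour of the tie-corrected normal approximation.

## Known limitations

* The linear-atrophy phantom is the simplest generative model consistent
  with a linear-kernel age predictor; real ageing is non-linear at the
  age extremes and spatially more heterogeneous.
* Tissue closure holds before noise; with noise and clipping, closure is
  approximate (CSF is defined as the clipped residual).
* The GPR implementation targets cohort sizes in the hundreds-to-low
  thousands (dense eigendecomposition, $O(N^3)$ once per fit); it is not
  meant for biobank-scale N.
* Brain-PAD is reported without age-bias correction, matching the
  reference analysis; users comparing cohorts with very different age
  ranges should be aware of the residual age dependence this leaves.
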