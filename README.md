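# brainpad

Brain-age prediction and brain-PAD group analysis for voxel-based
morphometry cohorts, in R.

## What it does

A model trained to predict chronological age from normalized grey- and
white-matter tissue-probability maps of healthy adults defines a normative
brain age. Applied to a patient cohort, the **brain-predicted age
difference**

> brain-PAD = predicted age − chronological age  (years)

is positive for older-appearing brains, and group differences in brain-PAD
measure premature brain ageing — e.g. in adults with Prader-Willi syndrome
(PWS) versus matched controls, or for a single rare-genotype case (such as
a SNORD116 microdeletion carrier) against a normative cohort.

The package implements the whole chain:

* **Volumes** — NIfTI-1 I/O, Gaussian smoothing (FWHM in mm, σ =
  FWHM/2√(2 ln 2)), cohort masking, GM+WM vectorization, tissue volumes
  and ICV in ml.
* **Model** — subject-by-subject similarity kernel `K[i,j] = x_i · x_j`,
  Gaussian-process age regression on the kernel (marginal-likelihood
  hyperparameters; for fixed hyperparameters identical to closed-form
  kernel ridge), 10-fold cross-validation (r, R², MAE, RMSE) and a
  label-permutation significance test.
* **Statistics** — pooled t-tests from raw data *or* printed (n, mean, SD)
  summaries, Mann-Whitney U, chi-squared, Pearson correlation,
  covariate-adjusted group effects with interaction tests, BMI-matched
  subcohort filtering, and single-subject z-scores against norms.
* **Synthetic data** — a seeded linear-atrophy phantom (baseline − slope ×
  effective age, per-subject brain-age deviate, voxel noise, smoothing)
  whose patient group carries a known ageing offset Δ, so the pipeline's
  accuracy and calibration are checkable without any scans. Printed
  summary statistics of the reference PWS case-control design ship as a
  fixture (`pws_reference_stats()`).

Everything is tibble-in/tibble-out and pipe-friendly, with `tidy()` /
`glance()` methods for fitted objects and `autoplot()` / `plot_*()`
figures.

## Worked example

A full synthetic study — train a normative GPR age model (n = 300, ages
18–90), apply it to a case-control cohort (20 patients with a true Δ = 7 y
ageing offset vs 40 controls, ages 19–29), score brain-PAD, and run the
group and covariate statistics:

```r
library(brainpad)

run <- run_pipeline(run_config(seed = 1))
make_report(run)
```

```
brainpad pipeline report
========================
master seed: 1

Training CV (10-fold, n = 300): r = 0.965, R^2 = 0.932, MAE = 4.30 y, RMSE = 5.33 y

Brain-PAD by group (years):
  Control    n =  40  mean   0.53  sd  4.69
  PWS        n =  20  mean   9.65  sd  5.79

Group comparisons:
  group              effect   9.12  se  1.39  CI [  6.33,  11.90]  t   6.56  p 1.626e-08
  group_adj_bmi      effect  10.10  se  1.98  CI [  6.14,  14.07]  t   5.10  p 3.977e-06
  group_adj_iq       effect   6.44  se  2.88  CI [  0.67,  12.20]  t   2.24  p 0.02933
  group_adj_gm       effect   2.79  se  1.21  CI [  0.37,   5.21]  t   2.30  p 0.02488
...
```

Reading this: the cross-validated model predicts age in the training set
with r = 0.97 and a mean absolute error of 4.3 years (the error is
dominated by the generator's 5-year per-subject brain-age deviate, which
is the point — brain age is *supposed* to deviate from chronological age).
Controls score ≈ 0 brain-PAD; the patient group, generated with a 7-year
offset, is estimated at +9.1 y with a 95 % CI that covers the truth. The
covariate-adjusted rows re-estimate the group effect controlling for BMI,
IQ or GM volume; the GM-adjusted effect shrinks because GM loss *is* the
causal path from the ageing offset to the prediction.

Group comparisons can also be reproduced directly from published summary
tables, with no raw data:

```r
t_test_from_summary(ref_summary("brainpad", "PWS"),
                    ref_summary("brainpad", "Control"))
#> # A tibble: 1 x 8
#>   effect    se ci_lo ci_hi statistic    df p_value method
#>    <dbl> <dbl> <dbl> <dbl>     <dbl> <dbl>   <dbl> <chr>
#> 1   7.24  2.20  2.84  11.6      3.29    58 0.00168 pooled t (from summary)
```

which recovers the printed effect +7.24 ± 2.20 years, t = 3.29, and the
single-subject chain `brain_pad(37.36, 24.49)` → +12.87 y, z ≈ 1.86
against norms of 0.84 ± 6.48 y.

## Repository layout

```
R/                  implementation (simulation, volumes, kernel, GPR,
                    cross-validation, statistics, pipeline, plots)
inst/extdata/       packaged reference summary statistics (CSV)
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/          methods vignette: model, generator, design decisions
```
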