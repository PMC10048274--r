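---
title: "Calibrating and validating an FT-MIR assay with accuracy profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and validating an FT-MIR assay with accuracy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirprofile)
```

## The problem

Mid-infrared (MIR) spectroscopy is the workhorse of routine milk analysis:
a spectrum over roughly 900--5000 cm^-1 is acquired in seconds and carries
absorbance signatures of fat, protein, lactose and individual fatty acids.
Quantifying a single fatty acid such as linoleic acid from such a spectrum
is an inverse problem: the analyte's ester and acyl bands overlap with
everything else in the matrix, so a multivariate calibration (PLSR, PCR or
a small neural network) must be trained on samples of known concentration
-- here a standard-addition design, spiking skimmed milk at 1--100
mg/100 mL -- and then *validated*: before the assay is used, one must know
over which concentration range a future single measurement can be trusted
to land within a stated tolerance of the truth.

`mirprofile` implements that entire workflow: a synthetic spectra
generator with known ground truth, spectral preprocessing, calibration
model selection by cross-validation, random-forest permutation selection
of informative bands, and ICH Q2(R1)-style validation through beta-content
tolerance intervals and the accuracy profile.

## What the simulator emulates -- and what it does not

No public spectra accompany this problem, so the package generates its
own. The generator (`sim_config()`, `simulate_calibration_set()`,
`simulate_validation_set()`, `simulate_blanks()`) is a Beer--Lambert
stand-in for the instrument:

* a fixed baseline made of Gaussian bands (water bending/stretching,
  lactose, protein, residual fat);
* analyte bands whose height is exactly linear in concentration, placed
  inside the fatty-acid-associated windows 940--1215, 1342--1489,
  1720--1766 and 2823--2935 cm^-1, so that band selection has a
  recoverable truth;
* interferent bands scaled by a lognormal per-sample nuisance covariate
  (a residual fat/protein proxy), so that feature selection is not
  trivially easy;
* an additive per-day baseline offset shared by all spectra of a day
  (`sigma_day`, default 0.004 AU) -- the simplest random-effects
  structure compatible with the between/within-day variance decomposition
  used in validation; a multiplicative gain variant is available but off
  by default;
* iid per-point Gaussian noise (`sigma_noise`, default 0.02 AU), with
  each sample the average of two acquisitions, mirroring the usual
  acquire-twice-and-average instrument protocol.

The default grid has 1060 uniform points over 926--5012 cm^-1; after the
water regions (1618--1705 and above 3025 cm^-1) are masked, 523 points
remain, matching the scale of a real filter-based milk analyser. Band
magnitudes and noise levels are free parameters chosen once so that a
competent pipeline reaches external R^2 >= 0.95 on the 105-sample
calibration design -- the order of magnitude reported for real
milk calibrations -- while low validation levels (5--10 mg/100 mL) fail
the +/-20% acceptance band, as they do in practice.

The simulator does **not** model interferograms, apodisation, scattering,
baseline drift within a day, wavelength miscalibration, or the true
covariance structure of milk constituents. Consequently, passing tests
demonstrate that the *statistical machinery* is correct and that the
pipeline recovers planted structure; they say nothing about how well any
particular real instrument predicts linoleic acid.

## Preprocessing

Seven standard transforms plus the identity are provided
(`preprocess_method()`, `apply_method()`): SNV, 11-point Savitzky--Golay
smoothing, SG first and second derivatives, and SNV followed by each SG
variant. Decisions worth recording:

* **SNV divisor** is the sample SD (n-1); configurable only by editing,
  since nothing downstream is sensitive to the choice.
* **SG polynomial order** defaults to 2 (quadratic), the common choice
  for spectra at this resolution; the window (11 points) and order are
  arguments.
* **SG edges** use a truncated-window fit at the boundaries rather than
  padding: no data are fabricated, at the price of noisier first/last few
  points.
* **Composition order** is SNV first, then the SG step, matching the
  usual naming ("SNV + SG + first derivative"); the derivative is
  computed inside the SG filter (the derivative of the local polynomial),
  not as a difference of smoothed values.
* **Masking convention**: omit intervals are open, so the retained grid
  is the closed union [926, 1618] and [1705, 3025] cm^-1. On masked
  grids the SG filter is applied per contiguous segment and never spans
  the gap.

## Calibration models and selection

The spectra are split 80/20 (test size `round(0.2 n)`, so 105 gives
84/21), and every (preprocessing, algorithm, hyperparameter) cell is
scored by 10-fold cross-validation with a shared fold assignment
(`grid_search()`). `rmse_cv` is the mean of per-fold RMSEs (its SD is
reported alongside), and R^2 is defined as `1 - SS_res/SS_tot` on pooled
held-out predictions -- a squared-correlation variant would flatter
miscalibrated models. The cell with the lowest `rmse_cv` is refit on the
full training portion and scored once on the held-out test set.

* **PLSR** is single-response NIPALS with y-deflation, written so one fit
  yields coefficients for every truncation 1..25; at full rank it
  reproduces ordinary least squares, which the tests exploit as an
  oracle. Components beyond the effective rank are truncated with a
  warning rather than an error.
* **PCR** regresses on `prcomp` scores; the smallest component count
  explaining 95% of spectral variance is reported informationally
  (`n_pc_95`), but the grid search -- not that rule -- picks the model
  order, since the two criteria need not agree.
* **ANN** is a single sigmoidal hidden layer with linear output
  (`nnet`), inputs standardised, response scaled to [0, 1], L2 penalty
  `decay`, deterministic given a seed. The default size grid is 1..6:
  published milk-calibration work quotes tuning ranges up to 5 but
  reports a winning size of 6, so the bound is kept configurable with 6
  as the default ceiling. ANN cells are costly and are therefore not in
  the default algorithm set of `run_config()`; they drop into the same
  grid when requested.

## Band selection

`permutation_pvalues()` fits a 500-tree regression random forest
(`ranger`), records each point's OOB permutation importance, then refits
the forest `B` times with the *response* permuted, giving each point a
null importance distribution. The p-value uses the add-one estimator
`(1 + #{null >= observed})/(B + 1)`, which cannot be zero; points with
`p <= 0.05` are selected (the boundary is inclusive) and adjacent
selected points merge into reported regions. No multiple-testing
correction is applied -- the procedure is a screening step, and its
type-I behaviour (selected fraction on null data close to alpha) is
checked directly in the test suite. The desk default is `B = 1000`; the
tests and the bundled studies run `B` of 100--200, which the add-one
estimator handles gracefully (the smallest attainable p is then 1/101).
Refits after selection apply each preprocessing method on the full masked
grid first and subset the selected columns afterwards, so derivative
windows never straddle the gaps between selected regions.

## Validation statistics

Validation uses a balanced 3 replicates x 5 levels x 3 days design.
Per level (`level_data()`):

* trueness: `bias% = 100 (mean - nominal)/nominal`, recovery = bias + 100;
* precision from the one-way ANOVA mean squares, between days (MSB) and
  within days (MSE). When MSB > MSE the repeatability variance is MSE,
  the between-day component is `(MSB - MSE)/n`, and the
  **intermediate-precision variance is their sum**. Defining intermediate
  precision as the between-day component alone would allow it to fall
  below repeatability, which is incoherent (and contradicts every
  published validation table in this field, where IP >= repeatability at
  all levels); the total-variance definition is therefore used. When
  MSB <= MSE both precisions collapse to the pooled SD with divisor
  `mn - 1`, and negative variance components are truncated at zero.

The beta-content tolerance interval at each level is
`bias% -/+ chi_k x RSD_IP%`, with

* `R' = max(0, (MSB/(MSE F_0.85;m(n-1),m-1) - 1)/n)`, a shrunken estimate
  of the between/within variance ratio: the day component enters only
  when the observed ratio clears the 0.85 F-quantile;
* `k`, the Satterthwaite effective degrees of freedom of the IP variance
  (the package verifies algebraically and numerically that the closed
  form equals the generic two-mean-squares Satterthwaite formula);
* `lambda^2 = (nR'+1)/(mn(R'+1))`, the standardised variance of the grand
  mean;
* `chi_k = sqrt(k Q_ncchisq(beta; 1, lambda^2) / Q_chisq(1-gamma; k))`,
  with beta = 0.667 and gamma = 0.9 by default. The denominator is the
  *lower* (1-gamma) chi-square quantile: confidence must widen, not
  shrink, the interval, and the normal limit (k large, lambda small)
  recovers the central two-sided factor z_0.8335 ~ 0.967.

A level is valid when its relative interval sits inside the +/-20%
acceptance band; the LLOQ is found by piecewise-linear interpolation of
the limits between the last invalid and first valid level, and the ULOQ
is the highest valid level. Levels whose intermediate-precision CV
exceeds 20% are flagged separately.

### How honest are these intervals?

`coverage_simulation()` draws balanced one-way datasets, builds the
interval for each, and computes the true content of the underlying
normal distribution inside it. The construction is approximate, and the
simulation (2000 datasets, m = n = 3) shows it is **anti-conservative
when the between-day variance is comparable to the within-day variance**:
with equal components the fraction of intervals achieving 66.7% content
is about 0.81 against a nominal 0.90. The root cause is the F-shrinkage
in `R'`: with only three days the 0.85 F-quantile is large, the estimated
ratio is truncated to zero in most datasets, and the day component is
understated. An upper confidence bound on the ratio (multiplying by an
F-quantile instead of dividing) would widen the intervals in exactly this
regime, but that is not the published construction, so the package keeps
the printed form and documents the behaviour. When day effects are small
relative to repeatability the simulation puts the empirical confidence
back above 0.9 at the same design size. Users validating assays with
m = 3 days and visible day-to-day variation should treat the confidence
level as optimistic by several points.

## Numerical choices and degenerate inputs

* All random stages fan out from one master seed to named sub-seeds, so
  any stage can be reproduced in isolation; identical configuration and
  seed give bit-identical output, and the caller's RNG state is never
  disturbed.
* Predictions are not clipped; negative concentrations are reported.
* A constant spectrum is an error in SNV (zero variance); an all-masked
  grid is an error; `mse = 0` (identical replicates) degenerates the
  tolerance interval to the bias point rather than erroring.
* Ties and boundaries: selection uses `p <= alpha`; masking intervals are
  open; acceptance comparison uses closed inequalities.

## Problem sizes used by the test suite

The bundled studies are sized for a desk run: ten independently seeded
105-sample calibrations with `B = 100` permutations for the
selection-recovery and parity checks, `B = 200` on 200 null bands for
type-I control, 2000 datasets for the coverage simulation, and `B = 25`
with 100 trees for the end-to-end pipeline smoke runs. These sizes are
the package's own trade-off between statistical resolution and a test
suite that runs in minutes; the defaults exposed to users
(`B = 1000`, 500 trees) are the full-scale settings.

## Known limitations

* The spectra generator is linear and Gaussian; real milk spectra have
  correlated, heteroscedastic residuals and nonlinear matrix effects.
* Only balanced validation designs are supported; unbalanced data are
  rejected rather than approximated.
* The tolerance-interval confidence is approximate (see above); no
  beta-expectation (Student-t) intervals or Bayesian alternatives are
  provided.
* No instrument file readers: CSV in, CSV/JSON out. JCAMP-DX import
  would be a natural extension.
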