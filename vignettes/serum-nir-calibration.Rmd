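---
title: "Calibrating serum proline from NIR spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating serum proline from NIR spectra: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirproline)
```

## The problem

Proline circulates in serum at a few micrograms per millilitre
(approximately 0.002--0.008 mg/ml). Its reference quantification — HPLC
with pre-column derivatization — is accurate but slow and expensive.
Near-infrared (NIR) transmission spectroscopy of serum is fast and
non-destructive, but the proline signal is buried: serum is ~90% water,
whose broad O--H combination and overtone bands dominate the 4000--10000
cm$^{-1}$ range, and dozens of other solutes absorb throughout it. The
calibration problem is therefore a hard chemometric one: 1557 correlated
absorbance variables, roughly 200 samples, and a target whose spectral
contribution is orders of magnitude below the background.

`nirproline` implements the complete workflow for this problem — synthetic
data generation with known ground truth, derivative preprocessing, outlier
screening, representative set partitioning, a PLS regression engine, and
three wavelength-selection strategies — so that every stage is testable
without access to clinical serum spectra.

## The synthetic-data generator

Real serum NIR spectra are not publicly deposited, so the generator is a
first-class module: it defines the study conditions under which everything
else is validated. Each sample is built by Beer--Lambert mixing:

$$
x_i(\nu) = s_i \Big( B_i(\nu) + c_i \, A(\nu) +
\textstyle\sum_j \ell_{ij} \, I_j(\nu) \Big) + a_i + b_i \tilde\nu +
\varepsilon_i(\nu)
$$

* $A(\nu)$ — the analyte's pure-component spectrum, a sum of Gaussian
  bands in wavenumber. Defaults place narrow bands (widths 35--45
  cm$^{-1}$) at 7352, 8620 and 5988 cm$^{-1}$, the characteristic regions
  reported for proline in aqueous solution. Gaussian shapes are an
  approximation chosen because they make the module analytically checkable
  (band maxima, linearity, additivity); true NIR bands are approximately
  Voigt-shaped.
* $c_i$ — the proline concentration, drawn from a normal law with mean
  0.005234 and SD 0.001866 mg/ml, rejection-truncated to
  [0.001917, 0.008198] mg/ml. These four constants reproduce the reported
  cohort. Note a structural limitation: a normal law truncated at roughly
  $\pm1.7\sigma$ has a sample SD of about $0.8\sigma$, so the simulated
  cohort's empirical SD (~0.0015) is below the configured 0.001866; mean,
  range and rough spread cannot all be matched simultaneously by a
  truncated normal.
* $B_i(\nu)$ — the water-dominated background: two broad Gaussians (widths
  300--400 cm$^{-1}$) near 5200 and 6900 cm$^{-1}$ with amplitudes ~1 and
  ~0.6 AU, hundreds of times the analyte contribution. The background is
  *per-sample*: each band's level is jittered by 5% (water content varies)
  and its centre by 10 cm$^{-1}$ (the broad water bands displace with
  temperature and solvation — the reason the original acquisition
  controlled room temperature and humidity). This variability is what
  makes raw-spectrum calibration genuinely hard.
* $I_j(\nu)$, $\ell_{ij}$ — the serum matrix: a fixed panel of 25 broad
  (100--300 cm$^{-1}$) interferent bands spread over the working range
  (`serum_matrix_bands()`), each with an independent per-sample level
  $\ell_{ij} \sim N(1, 0.15)$. Serum proteins, lipids and small
  metabolites contribute exactly this kind of broad, overlapping,
  independently varying absorption.
* $s_i \sim N(1, 0.01)$ — multiplicative scatter; $a_i, b_i$ — affine
  baseline drift (offset and tilt, SD 0.01 AU across the span);
  $\varepsilon_i \sim N(0, 2\times10^{-4}\,\mathrm{AU})$ — instrument
  noise, a realistic figure for a 64-scan FT-NIR transmission measurement
  at 8 cm$^{-1}$ resolution.

The reference concentrations carry an additive $N(0, 0.02 \times
\bar c)$ error standing in for HPLC uncertainty, so even a perfect
spectral model cannot reach $R_p = 1$.

**Difficulty calibration.** Band amplitudes relative to the background are
not constrained by any published pure-component measurement, so they were
set by anchoring the workflow's behaviour to the difficulty regime the
original study reports: with the default analyte amplitude (1.5 AU per
mg/ml; peak analyte absorbance ~0.008 AU), full-spectrum PLS on *raw*
spectra achieves $R_p \approx 0.2$--0.3 — matching the reported raw-spectrum
performance — while derivative preprocessing and wavelength selection
recover most of the available signal. Without the broad-matrix interference
and background jitter, every strategy saturates near $R_p = 0.995$ and
comparisons between strategies are meaningless.

What the generator does *not* emulate: instrument line-shape and
resolution effects, detector nonlinearity, temperature/humidity trends
over an acquisition session (drift is iid per sample, not serially
correlated), non-Gaussian band shapes, and any nonlinear
concentration--absorbance relationship. Passing benchmarks here therefore
demonstrates correctness of the algorithms under realistic-magnitude
corruption, not clinical performance.

## Preprocessing

Five treatments are compared, mirroring the standard table: raw spectra,
and first or second derivative with either filter.

* **Savitzky--Golay** (`savitzky_golay()`): per-row local least-squares
  polynomial fits; defaults window 11, polynomial order 3. Edge points use
  the polynomial fits of the boundary windows.
* **Norris gap-segment** (`norris_derivative()`): a centred moving average
  of `segment` points (default 5) followed by a gap difference (default
  gap 5) — the forward difference quotient for the first derivative, the
  central second difference across two gaps for the second. Affine
  baselines are annihilated exactly; edge points where the stencil leaves
  the grid take the nearest valid value.

Both are expressed per cm$^{-1}$ (scaled by the grid spacing), so results
do not depend on sampling density. The parenthetical "(5th degree
polynomial, 5 point window)" in the source description is not well-posed
for a Savitzky--Golay filter (the order must be below the window length)
and appears to conflate the two filters; the defaults here (SG 11/3,
Norris 5/5) are conventional, and all four numbers are configurable.

Why derivatives help: differentiating twice suppresses a Gaussian band by
$1/\sigma^2$, so broad background structures (widths 100--400 cm$^{-1}$)
are attenuated 4--60 times more strongly than the narrow analyte bands,
at the cost of amplifying white noise (which the smoothing step limits).
Raw-spectrum PLS must instead model the background variation with latent
variables, and with ~30 independently varying matrix components and only
118 calibration samples it cannot.

## Outlier screening

Spectra are ranked by Mahalanobis distance computed in a PCA score space
(default: components covering 99% of spectral variance) because the full
1557-variable covariance is singular for ~200 samples. Two classical
rejection rules are then applied to the distances: Dixon's Q test
(gap/range against Rorabacher's two-tailed critical values, with the
standard variant switch by sample size) and Chauvenet's criterion (flag
when the expected count of equally extreme values under a fitted normal
falls below one half). A sample is excluded when either test flags it; the
source describes both tests without stating a combination rule, and OR is
the conservative screening choice. Dixon's tables stop at $n = 30$, so for
larger cohorts the test is applied to the 30 largest distances — only the
extreme tail can be flagged, so smaller distances are irrelevant to it.

## Set partitioning

The calibration/validation split uses Kennard--Stone (default 118/89): the
two most distant spectra seed the calibration set and each subsequent
selection maximizes its minimum Euclidean distance to the already-selected
set, ties to the lower sample index. A seeded random split is available as
an option. Per-subset summaries (n, max, min, mean, SD, CV = SD/mean) and
a two-sided Welch t-test on the subset means document that the partition
is balanced; Welch's variant is used because nothing guarantees equal
variances.

## The PLS engine

`fit_pls()` implements NIPALS for a univariate response on mean-centred
data (no variance scaling — conventional for absorbance spectra, where the
units are already common). With one response the algorithm needs no inner
iteration; for component $a$: $w_a \propto X_{a-1}' y_{a-1}$, $t_a =
X_{a-1} w_a$, followed by deflation of $X$ and $y$. The final model is the
affine predictor $\hat y = \bar y + (x - \bar x)' \beta$ with $\beta = W
(P'W)^{-1} q$; at full rank it coincides with ordinary least squares, and
the test suite verifies agreement with an independently coded SIMPLS on
random problems. Extraction stops early (with the component count reduced)
if the residual covariance vanishes, e.g. on noiseless rank-one data.

Latent-variable counts are chosen by k-fold cross-validation
(`cross_validate_pls()`, default 10 folds, seeded-random assignment;
contiguous blocks available): RMSECV per count from pooled out-of-fold
residuals, choosing the global minimum with ties resolved toward the
smaller count. The original work reports only final LV counts (4--5), not
its CV scheme; 10-fold is the field default.

## Wavelength selection

**SMLR** (`smlr()`): classical forward-entry/backward-removal stepwise OLS
on individual wavelengths, restricted to a wavenumber window (default
9503.48--7347.46 cm$^{-1}$, the window reported for this problem). One
deliberate deviation from the naive procedure: entry p-values are
Bonferroni-adjusted for the number of candidates scanned. Scanning
hundreds of null wavelengths makes the minimum raw p-value almost surely
"significant", and an unadjusted stepwise fills to its variable cap on
pure noise; the adjustment restores the expected null behaviour (no or
almost no selections) while leaving real signals — whose p-values are
many orders of magnitude smaller — untouched.

**iPLS** (`ipls()`): the grid is cut into equal-width contiguous intervals
(default 9, i.e. 173 variables each on the default grid); a
cross-validated PLS model is fitted per interval and on the full spectrum,
and the interval with the lowest RMSECV wins. Intervals too narrow for the
requested component count get a reduced count with a notice; an interval
whose variables carry no covariance with the response (possible on clean
synthetic data) is scored RMSECV $= \infty$ rather than erroring.

**Simulated annealing** (`anneal()`): the search state is a binary
retention vector $V$ over the 1557 variables with $m$ ones. Each proposal
redraws a uniformly random mask with the current $m$; the objective is the
correlation $R_p$ between predictions of a PLS model fitted on the
retained calibration columns (5 latent variables by default) and the
validation reference values. Moves are accepted by the Metropolis
criterion with $\Delta E$ = previous objective − new objective, so
improvements ($\Delta E \le 0$, ties included) are accepted surely and
worsening moves with probability $e^{-\Delta E / T}$. Whenever a proposal
improves on the global best, $m$ shrinks to $\lceil 0.95\,m \rceil$
(floored at the LV count), steering the search toward sparser masks; the
procedure stops after `max_iterations` proposals (default 500) and returns
the best-ever mask refit on the calibration set, plus the full trace.

Schedule choices (the source specifies none): geometric cooling $T_{k+1} =
0.95\,T_k$ every 50 proposals; the initial temperature is calibrated in a
short warm-up so that roughly 80% of observed worsening moves would be
accepted; the initial $m$ is half the grid (the construction requires only
$m$ below the full count).

One caveat is inherited deliberately: the objective is evaluated on the
same validation set used to report $R_p$, exactly as the original
procedure describes. The selected mask's $R_p$ is therefore
selection-biased (it is the maximum of hundreds of validation-set
evaluations), and the report labels it as such; an unbiased estimate
requires a third held-out set.

## Metrics

For predictions $\hat C_i$ against reference values $C_i$:

* RMSEC / RMSEP / RMSECV $= \sqrt{\frac{1}{n}\sum_i (\hat C_i - C_i)^2}$
  on the calibration set, validation set, and pooled out-of-fold residuals.
* $R = \sqrt{\max(0,\, 1 - \mathrm{SSE}/\mathrm{SST})}$ — for
  least-squares-calibrated predictions this equals the absolute Pearson
  correlation (both are reported; the explained-variance form is
  canonical here). The printed source formulas omit the square and root
  (an evident typesetting loss); the standard forms are implemented.
* SEC / SEP — the bias-corrected SD of the residuals, so that
  $\mathrm{RMSE}^2 = \mathrm{SE}^2 (n-1)/n + \mathrm{offset}^2$.
* offset — the mean residual (bias).
* RPD $= \mathrm{SD}(C)/\mathrm{SEP}$, the residual predictive deviation.
  The source's footnote calls RPD a "relative percentage difference" and
  prints values near 14 that are inconsistent with its own $R$ values;
  the standard SD/SEP definition is used.

## Reproducibility mechanics

`run_pipeline()` derives a deterministic sub-seed for every stochastic
stage by hashing (global seed, stage name), so stage results do not depend
on execution order and two runs with the same configuration are
numerically identical. Each run can write all intermediate tables plus a
JSON manifest recording the stage seeds.

## Problem sizes used by the test suite

Unit tests run on small grids (15--400 variables, 8--60 samples) where
brute-force oracles are feasible: dense polynomial fits per window for
Savitzky--Golay, an independent SIMPLS for the PLS engine, exhaustive
per-step argmax for Kennard--Stone ($n \le 12$), exhaustive best-subset
for SMLR, and closed-form truncated-normal moments for the concentration
law. The benchmark suite runs the full study geometry — 207 samples, 1557
variables, 118/89 Kennard--Stone split — over 20 generator seeds for the
stochastic properties (annealing vs full-spectrum PLS, iPLS band
localization, derivative vs raw preprocessing), with the annealing runs
shortened to 150 proposals per seed; medians over seeds are compared so
single-seed flukes do not decide outcomes.

## Known limitations

* Gaussian bands and a two-band water background are idealizations; no
  instrument line shape, serial drift or nonlinearity is modelled.
* The truncated-normal concentration law cannot reproduce the reported
  mean, SD and range simultaneously (see above).
* Dixon's test applies only to the top-30 distance tail for cohorts above
  its tabulated range, and its critical values are hard-coded at the 0.05
  and 0.01 levels.
* SA's reported $R_p$ is selection-biased by construction (see above);
  the package mirrors the original procedure rather than fixing it.
* The SMLR entry rule is Bonferroni-guarded; with very weak signals this
  is more conservative than the classical uncorrected procedure.
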