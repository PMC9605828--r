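# nirproline

Chemometric calibration of **serum proline (mg/ml) from near-infrared
absorbance spectra**, for analytical chemists and chemometricians who want a
tested, reproducible implementation of the full workflow: synthetic
serum-like spectra with known ground truth, derivative preprocessing,
outlier screening, calibration/validation partitioning, a partial least
squares engine, and three wavelength-selection strategies.

Serum NIR spectra (4000–10000 cm⁻¹, 1557 variables) are dominated by broad
water bands and the overlapping absorption of the serum matrix; the proline
signal is confined to a few narrow bands (near 7352, 8620 and 5988 cm⁻¹)
and is orders of magnitude below the background. The package implements and
compares four calibration strategies on top of second-derivative
preprocessing:

* **SMLR** — stepwise multiple linear regression on individual wavelengths
  inside a wavenumber window;
* **PLS** — full-spectrum partial least squares (NIPALS, mean-centred),
  `ŷ = ȳ + (x − x̄)ᵀ β` with `β = W (PᵀW)⁻¹ q`, latent-variable count
  chosen by k-fold cross-validated RMSECV;
* **iPLS** — interval PLS: the grid is cut into equal intervals (default
  9), one PLS model per interval, lowest RMSECV wins;
* **SA** — simulated annealing over a binary retention vector `V` of length
  1557 (`m` = number of retained variables): proposals redraw a uniform
  mask at the current `m`, the objective is the validation-set correlation
  `Rp` of a 5-LV PLS fit on the retained variables, and moves are accepted
  by the Metropolis criterion

  ```
  P = 1             if ΔE ≤ 0      (ΔE = R_previous − R_new)
  P = exp(−ΔE / T)  if ΔE > 0
  ```

  with geometric cooling; on each global improvement `m` shrinks by 5%.

Models are reported with Rc, Rp (R = √(1 − SSE/SST)), RMSEC, RMSEP, RMSECV,
SEC, SEP, offset and RPD = SD(reference)/SEP.

## Worked example

```r
library(nirproline)

cfg <- pipeline_config(generator = sparse_signal_config(seed = 1), seed = 2)
res <- run_pipeline(cfg)
res$comparison[, c("label", "n_lv", "Rc", "RMSEC", "Rp", "RMSEP")]
```

On this synthetic cohort (207 samples, one narrow analyte band at 7667
cm⁻¹, realistic serum-matrix interference, second-derivative + Norris
preprocessing, 118/89 Kennard–Stone split) the run prints:

```
 label n_lv     Rc     RMSEC     Rp     RMSEP
  SMLR   NA 0.9895 2.279e-04 0.9805 0.0002620
   PLS    9 0.9998 3.153e-05 0.9548 0.0003965
  iPLS    3 0.9958 1.449e-04 0.9934 0.0001534
    SA    5 0.9960 1.402e-04 0.9751 0.0002959
```

Reading the numbers: full-spectrum PLS overfits 1557 mostly-uninformative
variables (highest Rc, lowest Rp); the selection strategies beat it on
validation. iPLS localizes the signal to its window 7335.5–7998.7 cm⁻¹ —
the interval actually containing the implanted band — and SA retains ~600
of 1557 variables with a validation Rp above full-spectrum PLS (its Rp is
selection-biased: the annealing objective is evaluated on the validation
set, so judge generalization on a third set where available). RMSEP is in
mg/ml on a cohort whose reference SD is ~0.0015 mg/ml.

The numbered drivers under `analysis/` run the full study as a narrative —
`01` simulates the cohort, `02` screens outliers and splits it (printing
per-subset CV and the Welch p-value), `03` compares the five preprocessing
treatments (raw spectra collapse to Rp ≈ 0.09 under background drift while
derivative treatments reach Rp ≈ 0.98–0.99), `04` runs the four-strategy
comparison above — writing their tables under `results/`.

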