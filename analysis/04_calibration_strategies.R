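#!/usr/bin/env Rscript
# The four-strategy comparison: SMLR, full-spectrum PLS, iPLS (9 intervals)
# and simulated-annealing wavelength selection, all on second-derivative +
# Norris preprocessed spectra with a 118/89 Kennard-Stone split.

suppressMessages(library(nirproline))

cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg)

write.csv(res$comparison, "results/strategy_comparison.csv",
          row.names = FALSE)
write.csv(res$anneal$trace, "results/anneal_trace.csv", row.names = FALSE)
write_retention(res$anneal$mask, res$data$spectra$grid,
                "results/retained_wavenumbers.csv")
bi <- res$ipls$intervals[res$ipls$best, ]
write.csv(res$ipls$intervals, "results/ipls_intervals.csv",
          row.names = FALSE)

print(res$comparison[, c("label", "n_lv", "Rc", "RMSEC", "Rp", "RMSEP")],
      digits = 4, row.names = FALSE)
message(sprintf(
  "iPLS window: %.2f-%.2f cm-1 (interval %d of %d); SA retained %d of %d variables (selection-biased Rp %.4f)",
  bi$wn_low, bi$wn_high, res$ipls$best, nrow(res$ipls$intervals),
  attr(res$anneal$mask, "m"), length(res$anneal$mask),
  res$anneal$objective))

# Under the default three-band analyte the full-spectrum model already sits
# at the reference-error ceiling and selection mainly prunes variables.
# The sparse benchmark -- one narrow band, ~5% informative variables --
# is the regime where wavelength selection pays off.
message("\nSparse single-band benchmark:")
cfg_sparse <- pipeline_config(generator = sparse_signal_config(seed = 1),
                              seed = 2)
res_sparse <- run_pipeline(cfg_sparse)
write.csv(res_sparse$comparison, "results/strategy_comparison_sparse.csv",
          row.names = FALSE)
print(res_sparse$comparison[, c("label", "n_lv", "Rc", "RMSEC", "Rp",
                                "RMSEP")],
      digits = 4, row.names = FALSE)
bs <- res_sparse$ipls$intervals[res_sparse$ipls$best, ]
message(sprintf(
  "Sparse run: iPLS window %.2f-%.2f cm-1; SA retained %d variables, Rp %.4f vs full-spectrum PLS Rp %.4f",
  bs$wn_low, bs$wn_high, attr(res_sparse$anneal$mask, "m"),
  res_sparse$anneal$objective,
  res_sparse$comparison$Rp[res_sparse$comparison$label == "PLS"]))
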