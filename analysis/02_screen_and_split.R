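#!/usr/bin/env Rscript
# Outlier screening and calibration/validation partitioning of the simulated
# cohort from 01_simulate_cohort.R: second-derivative + Norris
# preprocessing, Mahalanobis ranking with Dixon and Chauvenet tests, then a
# 118/89 Kennard-Stone split with per-subset statistics and a Welch t-test
# on the subset means.

suppressMessages(library(nirproline))

spectra <- read_spectra("scratch/cohort_spectra.csv")
reference <- read_reference("scratch/cohort_reference.csv")
y <- join_reference(spectra, reference)

pre <- apply_preprocess("2d-no", spectra)
scr <- screen_outliers(pre)
write.csv(
  data.frame(sample_id = pre$sample_ids, mahalanobis = scr$distance,
             chauvenet_flag = scr$chauvenet_flag,
             excluded = pre$sample_ids %in% scr$excluded),
  "results/screening.csv", row.names = FALSE
)
message(sprintf("Screening: %d of %d spectra excluded (%s)",
                length(scr$excluded), length(pre$sample_ids),
                if (length(scr$excluded)) paste(scr$excluded, collapse = ", ")
                else "none"))

keep <- !(pre$sample_ids %in% scr$excluded)
pre <- spectrum_set(pre$sample_ids[keep], pre$grid,
                    pre$absorbance[keep, , drop = FALSE])
y <- y[keep]

n_cal <- min(118L, nrow(pre$absorbance) - 1L)
split <- kennard_stone(pre, n_cal)
cal <- cohort_stats(y[split$calibration_idx])
val <- cohort_stats(y[split$validation_idx])
p <- compare_groups(y[split$calibration_idx], y[split$validation_idx])

tab <- data.frame(
  subset = c("calibration", "validation"),
  n = c(cal$n, val$n), max = c(cal$max, val$max), min = c(cal$min, val$min),
  mean = c(cal$mean, val$mean), sd = c(cal$sd, val$sd), cv = c(cal$cv, val$cv),
  welch_p = p
)
write.csv(tab, "results/split_summary.csv", row.names = FALSE)
write.csv(
  data.frame(sample_id = c(split$calibration, split$validation),
             subset = rep(c("calibration", "validation"),
                          c(cal$n, val$n))),
  "results/split_assignment.csv", row.names = FALSE
)

message(sprintf(
  "Kennard-Stone %d/%d split: calibration CV %.4f, validation CV %.4f, Welch p = %.3f (means not distinguishable at 0.05: %s)",
  cal$n, val$n, cal$cv, val$cv, p, p > 0.05))
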