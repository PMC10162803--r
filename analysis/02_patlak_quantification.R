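#!/usr/bin/env Rscript
# Quantify dopamine synthesis capacity from the simulated dynamic PET data:
# reference-region Patlak fit over 24-89 min, compared with the analytic
# ground-truth influx rate.

library(dopaproxy)
dir.create("results", showWarnings = FALSE)

target <- read_tac_csv("results/synthetic/tac_target.csv", "striatum")
reference <- read_tac_csv("results/synthetic/tac_reference.csv", "cerebellum")
truth <- kinetic_ground_truth()

fit <- patlak_fit(target, reference, t_star = 24)
asy <- patlak_asymptote(truth)
cat(sprintf("Patlak fit (noisy frames): ki_cer = %.5f min^-1 over %d frames\n",
            fit$ki_cer, fit$n_frames_used))
cat(sprintf("analytic asymptote %.5f min^-1; relative error %.2f%%\n",
            asy, 100 * (fit$ki_cer - asy) / asy))

# noise-free recovery across t* choices: the linearization error shrinks as
# the fit window moves later into the scan
clean <- simulate_pet_study(truth, noise_scale = 0)
tstars <- c(24, 30, 40, 50, 60)
rec <- data.frame(
  t_star = tstars,
  ki_cer = vapply(tstars, function(ts)
    patlak_fit(clean$target, clean$reference, ts)$ki_cer, numeric(1)))
rec$rel_error_pct <- 100 * (rec$ki_cer - asy) / asy
write.csv(rec, "results/patlak_recovery.csv", row.names = FALSE)
print(rec, digits = 4)
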