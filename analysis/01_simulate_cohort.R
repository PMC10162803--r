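#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a 94-participant cohort with the
# study's per-measure Ns and inter-ROI correlation structure, one dynamic
# PET study (target + cerebellar reference TACs on the 24-frame protocol),
# and one 10-minute vEOG recording with known blink count.

library(dopaproxy)
dir.create("results/synthetic", showWarnings = FALSE, recursive = TRUE)
seed <- 20260925

cohort <- simulate_cohort(cohort_spec(seed = seed))
write_cohort_csv(cohort, "results/synthetic/cohort.csv")
cat(sprintf("cohort: %d participants; complete n per measure: %s\n",
            nrow(cohort),
            paste(sprintf("%s=%d", c("digit_span", "listening_span", "bis11",
                                     "sebr", "bas"),
                          vapply(c("digit_span", "listening_span", "bis11",
                                   "sebr", "bas"),
                                 function(v) sum(!is.na(cohort[[v]])),
                                 integer(1))), collapse = " ")))
cat(sprintf("ki_caudate: median %.4f, IQR %.4f min^-1\n",
            median(cohort$ki_caudate), IQR(cohort$ki_caudate)))

truth <- kinetic_ground_truth()
study <- simulate_pet_study(truth, noise_scale = 0.01)
write_tac_csv(study$target, "results/synthetic/tac_target.csv")
write_tac_csv(study$reference, "results/synthetic/tac_reference.csv")
cat(sprintf("PET study simulated; analytic influx asymptote %.5f min^-1\n",
            patlak_asymptote(truth)))

sp <- veog_spec(duration_s = 600, fs = 200,
                blink_times_s = random_blink_times(170, 600, 1.2, seed = seed),
                seed = seed)
trace <- simulate_veog(sp)
write_eog_csv(trace, "results/synthetic/veog.csv")
cat(sprintf("vEOG trace: %d true blinks in %d s (%.0f blinks/min)\n",
            trace$n_blinks_true, trace$duration_s,
            sebr_from_blinks(trace$n_blinks_true, trace$duration_s)))
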