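#!/usr/bin/env Rscript

# Simulate example sEMG recordings and a small cohort, and write them in
# the interchange formats the rest of the workflow consumes.

library(myofactors)

dir.create("results", showWarnings = FALSE)

model <- muscle_model()
cat("Five-muscle forward model; loadings peak at electrodes:",
    paste(model$peak_channels, collapse = ", "), "\n")

profile <- subject_profile(co_activation = 0.2, attenuation = 0.9)
rec <- simulate_recording(model, profile, standard_sequence(), seed = 1)
print(rec)
write_recording(rec, "results/example_recording.csv")

fs <- rms_windows(rec)
print(fs)
write_features(fs, "results/example_features.csv")

cohort <- simulate_cohort(4, seed = 1)
cat(sprintf("Simulated %d subjects; co-activation range %.2f-%.2f, body fat %.1f-%.1f%%\n",
            length(cohort),
            min(sapply(cohort, function(s) s$profile$co_activation)),
            max(sapply(cohort, function(s) s$profile$co_activation)),
            min(sapply(cohort, function(s) s$profile$bf_index)),
            max(sapply(cohort, function(s) s$profile$bf_index))))
cat("Wrote results/example_recording.csv and results/example_features.csv\n")
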