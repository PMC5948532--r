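#!/usr/bin/env Rscript

# The cohort study: per-subject classifier error (E_MS, Re), SAC, body
# fat, game score, and the three latent-factor regressions.

library(myofactors)

res <- run_synthetic_study(study_config(n_subjects = 20, seed = 1),
                           progress = TRUE)
print(res)
write_study(res, "results/study")
cat("Wrote results/study/{subjects.csv, regressions.csv, summary.json}\n")
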