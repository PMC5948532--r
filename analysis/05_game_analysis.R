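#!/usr/bin/env Rscript

# Decision quality in the pursuit game: angular deviation from the best
# interception direction, its circular statistics, and the optimal /
# incorrect gesture rates -- contrasting a clean user policy with one that
# has a problematic "up" gesture.

library(myofactors)

dir.create("results", showWarnings = FALSE)
scenario <- random_scenario(seed = 9, duration = 60)

run_policy <- function(label, profile, seed) {
  tr <- simulate_game_trace(scenario, profile, seed = seed)
  ds <- downsample_trace(tr)
  ad <- angular_deviation(ds)
  st <- decision_stats(ad$alpha)
  gf <- gesture_fidelity(tr)
  cat(sprintf("%s: score %d, peak %.2f rad, spread %.2f rad, optimal fraction %.2f\n",
              label, game_score(tr), st$peak_location, st$spread,
              gf$optimal_fraction))
  list(hist = cbind(policy = label, st$histogram),
       rates = cbind(policy = label, gf$rates),
       summary = data.frame(policy = label, score = game_score(tr),
                            peak = st$peak_location, spread = st$spread,
                            optimal_fraction = gf$optimal_fraction))
}

clean <- run_policy("clean",
                    subject_profile(reaction_delay = 0.1, angular_noise_sd = 0.15),
                    seed = 21)
problem <- run_policy("problematic_up",
                      subject_profile(reaction_delay = 0.1, angular_noise_sd = 0.15,
                                      per_gesture_error_rate = c(up = 0.5)),
                      seed = 21)

write.csv(rbind(clean$hist, problem$hist),
          "results/deviation_histograms.csv", row.names = FALSE)
write.csv(rbind(clean$rates, problem$rates),
          "results/gesture_rates.csv", row.names = FALSE)
jsonlite::write_json(list(clean = clean$summary, problematic_up = problem$summary),
                     "results/game_summary.json", auto_unbox = TRUE, digits = NA,
                     dataframe = "rows")
cat("Wrote results/deviation_histograms.csv, results/gesture_rates.csv, results/game_summary.json\n")
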