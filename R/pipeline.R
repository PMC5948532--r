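#' Configuration of a synthetic cohort study
#'
#' Bundles every tunable of the end-to-end pipeline so a run is fully
#' determined by its config and seed. The defaults define a study scaled
#' to a laptop-class run: 20 subjects, 33 s calibration sequences per
#' recording, networks trained up to 3000 epochs, and 60 s game trials.
#'
#' @param n_subjects cohort size.
#' @param seed master integer seed; every stage seed derives from it.
#' @param factor_ranges latent-factor ranges, see
#'   [default_factor_ranges()].
#' @param window_ms,step_ms feature windowing, milliseconds.
#' @param max_epochs,patience,learning_rate network training controls.
#' @param game_duration seconds per simulated game trial.
#' @param game_gain displacement per control tick at full output.
#' @param d_th,prevalence_frac,bins decision-analysis thresholds.
#' @param noise_sd sensor-noise standard deviation.
#' @param seq_reps repetitions of each gesture in the calibration
#'   sequences (2).
#' @param rate sampling rate, Hz.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 20, seed = 1,
                         factor_ranges = default_factor_ranges(),
                         window_ms = 200, step_ms = 100,
                         max_epochs = 3000, patience = 100,
                         learning_rate = 2,
                         game_duration = 60, game_gain = 20,
                         d_th = 0.6, prevalence_frac = 0.2, bins = 36,
                         noise_sd = 0.25, seq_reps = 2, rate = 1000) {
  structure(as.list(environment()), class = "study_config")
}

# control law that emulates the deployed interface: the intended gesture
# is articulated as a random held-out feature frame of that gesture and
# classified by the trained network
.ann_control_law <- function(model, features) {
  pools <- split(seq_len(nrow(features$V)), features$labels)
  function(g) {
    idx <- pools[[g]]
    if (is.null(idx)) return(model$encoding[g, 1:4])
    f <- idx[sample.int(length(idx), 1)]
    predict_ann(model, features$V[f, ])[1:4]
  }
}

#' Run the full synthetic study
#'
#' Simulates a cohort, extracts features, trains the gesture network per
#' subject, measures the classifier error (E_MS) and its log-median index
#' (Re), the synergist-antagonist coefficient, the body-fat index, and a
#' pursuit-game score obtained with the subject's own trained network in
#' the control loop; then fits the three latent-factor regressions
#' (Re ~ SAC, Re ~ BF, Score ~ Re).
#'
#' @param config a [study_config()].
#' @param progress print per-stage progress messages.
#' @return Object of class `cohort_result`: `subjects` (per-subject
#'   data.frame with `subject, ems, re, sac, bf_index, score,
#'   co_activation, attenuation`), `e_m` (median E_MS), `regressions`
#'   (list `re_sac`, `re_bf`, `score_re` of [factor_regression()]
#'   results), `seeds`, `config`.
#' @export
run_synthetic_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (progress) message(sprintf(...))
  say("simulating cohort of %d subjects (seed %d)", config$n_subjects, config$seed)
  model <- muscle_model()
  sequence <- standard_sequence(rep(paste0("G", 1:8), config$seq_reps))
  cohort <- simulate_cohort(config$n_subjects,
                            factor_ranges = config$factor_ranges,
                            seed = config$seed, model = model,
                            sequence = sequence,
                            rate = config$rate, noise_sd = config$noise_sd)
  set.seed(config$seed + 1L)
  game_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  scenario_seed <- sample.int(.Machine$integer.max - 1L, 1)
  scenario <- random_scenario(seed = scenario_seed,
                              duration = config$game_duration)
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    subj <- cohort[[i]]
    ftr <- rms_windows(subj$train, config$window_ms, config$step_ms)
    fte <- rms_windows(subj$test, config$window_ms, config$step_ms)
    trained <- train_ann(ftr, fte, seed = subj$seed,
                         learning_rate = config$learning_rate,
                         max_epochs = config$max_epochs,
                         patience = config$patience)
    e_ms <- ems_ann(trained$model, fte)
    sac_val <- sac(mean_rms_per_gesture(fte, rest_correct = TRUE))$sac
    trace <- simulate_game_trace(scenario, subj$profile,
                                 control_law = .ann_control_law(trained$model, fte),
                                 seed = game_seeds[i], gain = config$game_gain)
    rows[[i]] <- data.frame(subject = i, ems = e_ms, sac = sac_val,
                            bf_index = subj$profile$bf_index,
                            score = game_score(trace),
                            co_activation = subj$profile$co_activation,
                            attenuation = subj$profile$attenuation,
                            epochs = trained$report$epochs_run)
    say("subject %d/%d: E_MS %.4f, SAC %.2f, score %d",
        i, config$n_subjects, e_ms, sac_val, game_score(trace))
  }
  subjects <- do.call(rbind, rows)
  subjects$re <- performance_index(subjects$ems)
  regressions <- list(
    re_sac = factor_regression(subjects$sac, subjects$re),
    re_bf = factor_regression(subjects$bf_index, subjects$re),
    score_re = factor_regression(subjects$re, subjects$score))
  structure(list(subjects = subjects,
                 e_m = stats::median(subjects$ems),
                 regressions = regressions,
                 seeds = list(master = config$seed, game = game_seeds,
                              scenario = scenario_seed),
                 config = config),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects, median E_MS = %.4f\n",
              nrow(x$subjects), x$e_m))
  for (nm in names(x$regressions)) {
    r <- x$regressions[[nm]]
    cat(sprintf("  %-9s slope %8.3f +/- %.3f  (p = %.3g)\n",
                nm, r$slope, r$slope_se, r$p_value))
  }
  invisible(x)
}

#' Write the study tables and a JSON summary to a directory
#'
#' Emits `subjects.csv` (per-subject metrics), `regressions.csv` and
#' `summary.json` (regression coefficients, median error, seeds used).
#'
#' @param result a `cohort_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(result, dir) {
  stopifnot(inherits(result, "cohort_result"))
  if (nrow(result$subjects) == 0) stop("empty cohort: nothing to report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  reg <- do.call(rbind, lapply(names(result$regressions), function(nm) {
    r <- result$regressions[[nm]]
    data.frame(regression = nm, slope = r$slope, slope_se = r$slope_se,
               intercept = r$intercept, intercept_se = r$intercept_se,
               p_value = r$p_value, n = r$n)
  }))
  utils::write.csv(reg, file.path(dir, "regressions.csv"), row.names = FALSE)
  jsonlite::write_json(list(e_m = result$e_m,
                            regressions = lapply(result$regressions, function(r)
                              r[c("slope", "intercept", "slope_se",
                                  "intercept_se", "p_value", "n")]),
                            seeds = result$seeds),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
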