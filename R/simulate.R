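#' Build a labelled gesture sequence
#'
#' @param gestures character vector of gesture ids.
#' @param durations_s per-gesture duration in seconds (recycled).
#' @return data.frame with columns `gesture`, `duration_s`.
#' @export
gesture_sequence <- function(gestures, durations_s) {
  stopifnot(length(gestures) >= 1, all(durations_s > 0))
  data.frame(gesture = as.character(gestures),
             duration_s = rep_len(as.numeric(durations_s), length(gestures)))
}

#' Standard calibration sequence: rest, then each gesture with rest gaps
#'
#' @param gestures gestures to include (default G1-G8).
#' @param gesture_s seconds per gesture segment.
#' @param rest_s seconds of rest between gestures.
#' @param lead_rest_s initial rest segment, seconds.
#' @return A [gesture_sequence()] data.frame.
#' @export
standard_sequence <- function(gestures = paste0("G", 1:8),
                              gesture_s = 1.5, rest_s = 0.5, lead_rest_s = 1) {
  g <- c("G0", as.vector(rbind(gestures, "G0")))
  d <- c(lead_rest_s, as.vector(rbind(rep(gesture_s, length(gestures)),
                                      rep(rest_s, length(gestures)))))
  gesture_sequence(g, d)
}

# zero-mean, unit-variance band-limited Gaussian noise (the sEMG carrier)
.bandlimited_noise <- function(n, rate, band = c(20, 450)) {
  hi <- min(band[2], 0.45 * rate)
  bf <- signal::butter(4, c(band[1], hi) / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2000))
  x <- x[1001:(1000 + n)]            # drop filter edge transients
  as.numeric(scale(x))
}

# slow (<= ~3 Hz) unit-variance Gaussian fluctuation of the drive to one
# muscle; models motor-unit force variability within a held gesture
.effort_fluctuation <- function(n, rate, cutoff_hz = 3) {
  bf <- signal::butter(2, cutoff_hz / (rate / 2), type = "low")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2000))
  x <- x[1001:(1000 + n)]
  as.numeric(scale(x))
}

# smooth a per-sample step profile with a centred moving average of
# `ramp` samples, yielding linear onset/offset ramps
.smooth_ramp <- function(x, ramp) {
  if (ramp <= 1) return(x)
  n <- length(x)
  xp <- c(rep(x[1], ramp), x, rep(x[n], ramp))
  y <- stats::filter(xp, rep(1 / ramp, ramp), sides = 2)
  as.numeric(y[(ramp + 1):(ramp + n)])
}

#' Simulate a labelled multichannel sEMG recording
#'
#' Each source emits band-limited (20-450 Hz) unit-variance Gaussian
#' carrier noise, amplitude-modulated by the gesture activation envelope
#' (template level with 100 ms linear onset/offset ramps, times an
#' independent slow effort fluctuation per muscle emulating motor-unit
#' drive variability within a held gesture). Sources are mixed onto
#' electrodes by the model loadings, scaled by the subject's attenuation,
#' and additive Gaussian sensor noise (not attenuated) is applied per
#' channel.
#'
#' @param model a [muscle_model()].
#' @param profile a [subject_profile()].
#' @param sequence a [gesture_sequence()] data.frame.
#' @param rate sampling rate in Hz (>= 200; default 1000).
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @param noise_sd sensor-noise standard deviation (arbitrary units).
#' @param ramp_ms onset/offset ramp length, milliseconds.
#' @param effort_cv coefficient of variation of the slow per-muscle
#'   effort fluctuation (0.5; 0 gives perfectly steady gestures).
#' @param segment_jitter_sd log-normal standard deviation of the
#'   per-segment, per-muscle drive level (0.35): successive repetitions of
#'   the same gesture are performed with slightly different effort, as
#'   real subjects do. 0 disables it.
#' @return Object of class `emg_recording`: `samples` (`[T x K]` matrix),
#'   `rate`, `labels` (per-sample gesture id), `envelopes` (`[T x m]`
#'   noise-free source activation envelopes, before attenuation), plus the
#'   generating `model`, `profile` and `seed`.
#' @export
simulate_recording <- function(model, profile, sequence,
                               rate = 1000, seed = 1,
                               noise_sd = 0.25, ramp_ms = 100,
                               effort_cv = 0.5, segment_jitter_sd = 0.35) {
  stopifnot(inherits(model, "muscle_model"),
            inherits(profile, "subject_profile"),
            is.data.frame(sequence), rate >= 200,
            all(sequence$duration_s > 0), noise_sd >= 0)
  unknown <- setdiff(sequence$gesture, gesture_ids())
  if (length(unknown)) {
    stop("unknown gesture id(s): ", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  act <- subject_activation(model, profile$co_activation)
  n_seg <- ceiling(sequence$duration_s * rate)
  total <- sum(n_seg)
  labels <- rep(sequence$gesture, n_seg)
  m <- model$n_sources
  K <- model$n_channels
  ramp <- max(1L, round(ramp_ms / 1000 * rate))
  # per-source activation envelope over time
  env <- matrix(0, nrow = total, ncol = m,
                dimnames = list(NULL, model$source_names))
  for (k in seq_len(m)) {
    seg_levels <- act[sequence$gesture, k]
    if (segment_jitter_sd > 0) {
      seg_levels <- seg_levels * exp(stats::rnorm(length(seg_levels), 0, segment_jitter_sd))
    }
    env[, k] <- .smooth_ramp(rep(seg_levels, n_seg), ramp)
    if (effort_cv > 0) {
      env[, k] <- env[, k] * pmax(0, 1 + effort_cv * .effort_fluctuation(total, rate))
    }
  }
  carriers <- vapply(seq_len(m), function(k) .bandlimited_noise(total, rate),
                     numeric(total))
  signal_part <- (env * carriers) %*% t(model$loadings)
  noise <- matrix(stats::rnorm(total * K, sd = noise_sd), nrow = total)
  samples <- profile$attenuation * signal_part + noise
  colnames(samples) <- rownames(model$loadings)
  structure(list(samples = samples, rate = rate, labels = labels,
                 envelopes = env, model = model, profile = profile,
                 seed = seed),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz (%.1f s), gestures: %s\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              nrow(x$samples) / x$rate,
              paste(unique(x$labels), collapse = " ")))
  invisible(x)
}

#' Default latent-factor ranges for a simulated cohort
#'
#' Ranges emulate the spread observed across untrained adult subjects:
#' attenuation in (0.1, 1] maps onto body-fat percentages of 4-40%,
#' matching the 4-44% range hand-to-hand fat monitors report.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
default_factor_ranges <- function() {
  list(co_activation = c(0.05, 0.45),
       attenuation = c(0.10, 1.00),
       reaction_delay = c(0.10, 0.40),
       angular_noise_sd = c(0.10, 0.40),
       error_rate = c(0.00, 0.15))
}

.draw_range <- function(rg, n) {
  stopifnot(length(rg) == 2)
  if (rg[1] > rg[2]) stop("degenerate range: min > max")
  if (rg[1] == rg[2]) rep(rg[1], n) else stats::runif(n, rg[1], rg[2])
}

#' Simulate a cohort of subjects with train and test recordings
#'
#' Subject profiles are drawn uniformly from the stated factor ranges;
#' each subject receives a train and a test recording covering rest and
#' all basic and compound gestures G1-G8.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param factor_ranges named list of `c(min, max)` ranges, see
#'   [default_factor_ranges()]. A degenerate range (min == max) is
#'   allowed; min > max is rejected.
#' @param seed integer seed.
#' @param model a [muscle_model()].
#' @param sequence gesture sequence for each recording.
#' @param rate sampling rate, Hz.
#' @param noise_sd sensor-noise standard deviation.
#' @return List of per-subject lists with elements `profile`, `train`,
#'   `test`, `seed`.
#' @export
simulate_cohort <- function(n_subjects, factor_ranges = default_factor_ranges(),
                            seed = 1, model = muscle_model(),
                            sequence = standard_sequence(),
                            rate = 1000, noise_sd = 0.25) {
  stopifnot(n_subjects >= 2)
  fr <- utils::modifyList(default_factor_ranges(), factor_ranges)
  set.seed(seed)
  ca <- .draw_range(fr$co_activation, n_subjects)
  # log-uniform: body fat (linear in log-attenuation) is uniform across
  # the cohort
  at <- exp(.draw_range(log(fr$attenuation), n_subjects))
  rd <- .draw_range(fr$reaction_delay, n_subjects)
  an <- .draw_range(fr$angular_noise_sd, n_subjects)
  er <- matrix(.draw_range(fr$error_rate, n_subjects * 8), nrow = n_subjects,
               dimnames = list(NULL, paste0("G", 1:8)))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, 2 * n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    prof <- subject_profile(co_activation = ca[i], attenuation = at[i],
                            reaction_delay = rd[i], angular_noise_sd = an[i],
                            per_gesture_error_rate = er[i, ])
    list(profile = prof,
         train = simulate_recording(model, prof, sequence, rate = rate,
                                    seed = subject_seeds[2 * i - 1],
                                    noise_sd = noise_sd),
         test = simulate_recording(model, prof, sequence, rate = rate,
                                   seed = subject_seeds[2 * i],
                                   noise_sd = noise_sd),
         seed = subject_seeds[2 * i - 1])
  })
}
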