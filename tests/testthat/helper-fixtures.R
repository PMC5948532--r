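# Shared fixtures. Recordings are generated in code (no stored data) and
# cached per test run because simulation is the slowest step.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, make) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- make()
  .fixture_env[[key]]
}

quick_profile <- function(...) subject_profile(...)

# short 4-gesture recording for feature/classifier unit tests
quick_recording <- function(seed = 1, ca = 0.2, att = 0.9, ...) {
  simulate_recording(muscle_model(), subject_profile(co_activation = ca, attenuation = att),
                     standard_sequence(paste0("G", 1:4), gesture_s = 1),
                     seed = seed, ...)
}

# a "clean subject": high SNR, minimal co-activation, steady repeatable
# effort -- the regime for classifier benchmarks
clean_pair <- function(seed) {
  m <- muscle_model()
  p <- subject_profile(co_activation = 0.05, attenuation = 1)
  sq <- standard_sequence(rep(paste0("G", 1:8), 2))
  list(train = simulate_recording(m, p, sq, seed = seed,
                                  effort_cv = 0.25, segment_jitter_sd = 0.15),
       test = simulate_recording(m, p, sq, seed = seed + 5000,
                                 effort_cv = 0.25, segment_jitter_sd = 0.15))
}

# mean per-window source envelope, the ground truth for ICA activation
# recovery
true_source_frames <- function(rec, fs) {
  N <- fs$window_samples
  ends <- round(fs$frame_times * rec$rate)
  t(vapply(ends, function(e) colMeans(rec$envelopes[(e - N + 1):e, ]),
           numeric(ncol(rec$envelopes))))
}

# brute-force best permutation matching of |correlations|; the oracle for
# source-recovery checks (5! = 120 permutations, enumerated)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(r) c(v[i], r))
  }))
}

matched_min_cor <- function(S, E) {
  cc <- abs(stats::cor(S, E))
  k <- ncol(cc)
  max(vapply(all_perms(seq_len(k)),
             function(pp) min(cc[cbind(seq_len(k), pp)]), numeric(1)))
}
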