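#' Windowed RMS features and mean power of an sEMG recording
#'
#' The raw flow is divided into trailing (causal) windows of `window_ms`
#' with step `step_ms`; per channel, the root mean square over each window
#' is the feature value, and the mean power pools the mean absolute value
#' over window samples and all channels. Frame timestamps are the right
#' edge of each window; partial leading windows are dropped.
#'
#' @param rec an `emg_recording` (see [simulate_recording()]), or a plain
#'   numeric matrix `[T x K]` with `rate` and `labels` supplied via
#'   attributes-free arguments below.
#' @param window_ms window length in milliseconds (default 200).
#' @param step_ms step between consecutive windows, milliseconds (100).
#' @param drop_transitions if `TRUE`, frames whose window spans a gesture
#'   transition are discarded.
#' @return Object of class `feature_stream`: `V` (`[frames x K]` RMS
#'   matrix), `P` (`[frames]` mean power), `frame_times` (s, right edge),
#'   `labels` (majority gesture per window), `window_samples`,
#'   `step_samples`, `rate`.
#' @export
rms_windows <- function(rec, window_ms = 200, step_ms = 100,
                        drop_transitions = FALSE) {
  stopifnot(inherits(rec, "emg_recording"), window_ms >= step_ms,
            window_ms > 0, step_ms > 0)
  x <- rec$samples
  rate <- rec$rate
  N <- round(window_ms / 1000 * rate)
  M <- round(step_ms / 1000 * rate)
  Tn <- nrow(x)
  K <- ncol(x)
  if (Tn < N) stop("recording shorter than one window")
  ends <- seq(N, Tn, by = M)
  # cumulative sums give O(T) windowed means
  cs2 <- rbind(0, apply(x^2, 2, cumsum))
  cs1 <- rbind(0, apply(abs(x), 2, cumsum))
  V <- sqrt((cs2[ends + 1, , drop = FALSE] - cs2[ends - N + 1, , drop = FALSE]) / N)
  P <- rowSums(cs1[ends + 1, , drop = FALSE] - cs1[ends - N + 1, , drop = FALSE]) / (N * K)
  colnames(V) <- colnames(x)
  labels <- NULL
  keep <- rep(TRUE, length(ends))
  if (!is.null(rec$labels)) {
    labels <- vapply(ends, function(e) {
      w <- rec$labels[(e - N + 1):e]
      names(which.max(table(w)))
    }, character(1))
    if (drop_transitions) {
      keep <- vapply(ends, function(e) {
        length(unique(rec$labels[(e - N + 1):e])) == 1L
      }, logical(1))
    }
  }
  structure(list(V = V[keep, , drop = FALSE],
                 P = P[keep],
                 frame_times = ends[keep] / rate,
                 labels = if (is.null(labels)) NULL else labels[keep],
                 window_samples = N, step_samples = M, rate = rate),
            class = "feature_stream")
}

#' @rdname rms_windows
#' @return `mean_power()` returns just the mean-power vector `P`.
#' @export
mean_power <- function(rec, window_ms = 200, step_ms = 100) {
  rms_windows(rec, window_ms = window_ms, step_ms = step_ms)$P
}

#' @export
print.feature_stream <- function(x, ...) {
  cat(sprintf("<feature_stream> %d frames x %d channels (window %d, step %d samples)\n",
              nrow(x$V), ncol(x$V), x$window_samples, x$step_samples))
  invisible(x)
}

#' Subset a feature stream by frame index or gesture label
#'
#' @param fs a `feature_stream`.
#' @param idx logical or integer frame index.
#' @return A `feature_stream` with the selected frames.
#' @export
subset_frames <- function(fs, idx) {
  stopifnot(inherits(fs, "feature_stream"))
  structure(list(V = fs$V[idx, , drop = FALSE], P = fs$P[idx],
                 frame_times = fs$frame_times[idx],
                 labels = if (is.null(fs$labels)) NULL else fs$labels[idx],
                 window_samples = fs$window_samples,
                 step_samples = fs$step_samples, rate = fs$rate),
            class = "feature_stream")
}
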