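#' Calibrate the proportional-control state
#'
#' Estimates the rest-state drift baseline and the maximal mean power from
#' calibration segments: the per-channel rest RMS trend, the reference
#' maximal mean power `p_max` over a maximal-effort segment, and the drift
#' threshold `p_th` (95th percentile of the relative rest-state mean
#' power), which suppresses involuntary cursor drift at rest.
#'
#' @param rest_features `feature_stream` recorded at rest.
#' @param max_effort_features `feature_stream` at maximal effort.
#' @param gain displacement scale in screen units (20).
#' @return Object of class `control_state` with fields `p_max`, `p_th`,
#'   `gain`, `rest_baseline`.
#' @export
calibrate_control <- function(rest_features, max_effort_features, gain = 20) {
  stopifnot(inherits(rest_features, "feature_stream"),
            inherits(max_effort_features, "feature_stream"),
            length(rest_features$P) > 0, length(max_effort_features$P) > 0,
            gain > 0)
  p_max <- max(max_effort_features$P)
  if (p_max <= 0) stop("p_max is zero: maximal-effort segment has no signal")
  p_th <- unname(stats::quantile(rest_features$P / p_max, 0.95, type = 7))
  structure(list(p_max = p_max,
                 p_th = min(p_th, 1 - 1e-12),
                 gain = gain,
                 rest_baseline = colMeans(rest_features$V)),
            class = "control_state")
}

#' Cursor speed from the mean power
#'
#' `v = max(0, P/p_max - p_th)`: the relative mean power above the rest
#' drift threshold, rectified.
#'
#' @param P_frame mean power of the current frame (scalar or vector).
#' @param state a `control_state`.
#' @return Non-negative speed value(s).
#' @export
control_velocity <- function(P_frame, state) {
  stopifnot(inherits(state, "control_state"), all(P_frame >= 0))
  pmax(0, P_frame / state$p_max - state$p_th)
}

#' Proportional cursor displacement from the directional outputs
#'
#' `delta = gain * v * (qr - ql, qu - qd)` in screen units (x rightward,
#' y upward).
#'
#' @param q directional output vector `(ql, qr, qu, qd)` (extra outputs
#'   are ignored), components in `[0, 1]`.
#' @param v speed from [control_velocity()].
#' @param state a `control_state`.
#' @return Numeric `c(dx, dy)`.
#' @export
cursor_displacement <- function(q, v, state) {
  stopifnot(inherits(state, "control_state"), length(q) >= 4,
            all(q[1:4] >= 0), all(q[1:4] <= 1), v >= 0)
  state$gain * v * c(q[[2]] - q[[1]], q[[3]] - q[[4]])
}
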