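#' Pursuit-game scenario
#'
#' The target ("cherry") moves along a piecewise-linear path at constant
#' speed per segment inside a rectangular arena; the cursor starts at a
#' fixed point.
#'
#' @param target_path `[n x 2]` matrix of waypoints (screen units).
#' @param speeds target speed per segment, units/s (recycled).
#' @param cursor_start length-2 start position.
#' @param arena `c(width, height)`.
#' @param duration seconds.
#' @return Object of class `game_scenario`.
#' @export
game_scenario <- function(target_path, speeds, cursor_start = c(400, 300),
                          arena = c(800, 600), duration = 60) {
  target_path <- as.matrix(target_path)
  stopifnot(ncol(target_path) == 2, nrow(target_path) >= 2,
            all(is.finite(speeds)), all(speeds > 0), duration > 0,
            all(target_path[, 1] >= 0), all(target_path[, 1] <= arena[1]),
            all(target_path[, 2] >= 0), all(target_path[, 2] <= arena[2]))
  structure(list(target_path = target_path,
                 speeds = rep_len(speeds, nrow(target_path) - 1),
                 cursor_start = cursor_start,
                 arena = arena, duration = duration),
            class = "game_scenario")
}

#' Random pursuit scenario with waypoints drawn inside the arena
#'
#' @param seed integer seed.
#' @param n_waypoints number of path vertices.
#' @param speed_range target speed range, units/s.
#' @inheritParams game_scenario
#' @return A [game_scenario()].
#' @export
random_scenario <- function(seed = 1, n_waypoints = 12,
                            speed_range = c(40, 80),
                            arena = c(800, 600), duration = 60) {
  set.seed(seed)
  margin <- 0.1
  path <- cbind(stats::runif(n_waypoints, margin * arena[1], (1 - margin) * arena[1]),
                stats::runif(n_waypoints, margin * arena[2], (1 - margin) * arena[2]))
  game_scenario(path, stats::runif(n_waypoints - 1, speed_range[1], speed_range[2]),
                cursor_start = arena / 2, arena = arena, duration = duration)
}

# target position and velocity along the piecewise-linear path at time t
# (the path is traversed cyclically)
.target_state <- function(scenario, t) {
  path <- scenario$target_path
  seg_vec <- diff(path)
  seg_len <- sqrt(rowSums(seg_vec^2))
  seg_dur <- seg_len / scenario$speeds
  total <- sum(seg_dur)
  tt <- t %% total
  cum <- c(0, cumsum(seg_dur))
  i <- findInterval(tt, cum, rightmost.closed = TRUE)
  i <- min(i, length(seg_dur))
  frac <- (tt - cum[i]) / seg_dur[i]
  pos <- path[i, ] + frac * seg_vec[i, ]
  vel <- seg_vec[i, ] / seg_dur[i]
  list(pos = pos, vel = vel)
}

#' Best interception direction for a constant-speed pursuer
#'
#' Solves `||omega_p|| t* = ||d + omega_c t*||` with `d = rho_c - rho_p`
#' for the interception time `t* > 0` (a quadratic in `t*`), and returns
#' the unit vector towards the interception point,
#' `n = (d + omega_c t*) / ||.||`. When no positive root exists (e.g. the
#' pursuer is too slow or stationary), the fallback aims at the target's
#' position one time step ahead: `n = normalise(d + omega_c * dt_next)`.
#'
#' @param rho_p,rho_c cursor and target positions (length-2).
#' @param omega_p,omega_c cursor and target velocity vectors.
#' @param dt_next duration of the next time step (s), used by the
#'   fallback.
#' @return List with `n` (unit vector), `t_star` (interception time, `NA`
#'   when the fallback was used) and `fallback` (logical).
#' @export
best_direction <- function(rho_p, omega_p, rho_c, omega_c, dt_next) {
  d <- rho_c - rho_p
  d2 <- sum(d^2)
  if (d2 == 0) stop("cursor and target coincide: direction undefined")
  sp2 <- sum(omega_p^2)
  a <- sum(omega_c^2) - sp2
  b <- 2 * sum(d * omega_c)
  t_star <- NA_real_
  if (abs(a) < 1e-12) {
    if (b < 0) t_star <- -d2 / b
  } else {
    disc <- b^2 - 4 * a * d2
    if (disc >= 0) {
      roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      pos <- roots[roots > 0]
      if (length(pos)) t_star <- min(pos)
    }
  }
  if (is.finite(t_star) && sp2 > 0) {
    v <- d + omega_c * t_star
    return(list(n = v / sqrt(sum(v^2)), t_star = t_star, fallback = FALSE))
  }
  v <- d + omega_c * dt_next
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate fallback geometry: zero direction vector")
  list(n = v / nv, t_star = NA_real_, fallback = TRUE)
}

#' Finite-difference velocities of a sampled trajectory
#'
#' Forward difference `omega(t_i) = (rho(t_{i+1}) - rho(t_i)) /
#' (t_{i+1} - t_i)`; the last point has no velocity.
#'
#' @param positions `[n x 2]` matrix.
#' @param times strictly increasing numeric vector of length n.
#' @return `[n-1 x 2]` matrix.
#' @export
trace_velocities <- function(positions, times) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 2, length(times) == nrow(positions))
  dt <- diff(times)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  diff(positions) / dt
}

#' Downsample a game trace for decision analysis
#'
#' Uniform decimation to at most `max_points` points (about 50 ms
#' spacing for game-trial-scale traces), preserving the first and last
#' point exactly. Already-sparse traces are returned unchanged.
#'
#' @param trace a `game_trace` (see [simulate_game_trace()]) or its
#'   data.frame.
#' @param max_points maximal number of retained points (100).
#' @param min_spacing_s target spacing between points, seconds (0.05).
#' @return The trace with a subset of rows.
#' @export
downsample_trace <- function(trace, max_points = 100, min_spacing_s = 0.05) {
  df <- as.data.frame(trace)
  n <- nrow(df)
  if (n < 2) stop("trace needs at least two points")
  span <- df$time_s[n] - df$time_s[1]
  n_out <- min(max_points, max(2, floor(span / min_spacing_s) + 1), n)
  idx <- unique(round(seq(1, n, length.out = n_out)))
  out <- df[idx, , drop = FALSE]
  rownames(out) <- NULL
  if (inherits(trace, "game_trace")) {
    attr(out, "score") <- attr(trace, "score")
    class(out) <- c("game_trace", class(out))
  }
  out
}

# best directions and cursor velocities along a (downsampled) trace;
# returns per-usable-point indices, n matrix, omega_p matrix
.trace_geometry <- function(df) {
  n_pts <- nrow(df)
  stopifnot(n_pts >= 3)
  times <- df$time_s
  wp <- trace_velocities(df[, c("px", "py")], times)
  wc <- trace_velocities(df[, c("cx", "cy")], times)
  dt <- diff(times)
  res <- lapply(seq_len(n_pts - 1), function(i) {
    p <- c(df$px[i], df$py[i]); cc <- c(df$cx[i], df$cy[i])
    if (all(p == cc)) return(NULL)
    bd <- best_direction(p, wp[i, ], cc, wc[i, ], dt[i])
    list(i = i, n = bd$n, wp = wp[i, ])
  })
  res <- Filter(Negate(is.null), res)
  list(idx = vapply(res, `[[`, integer(1) + 0, "i"),
       n = do.call(rbind, lapply(res, `[[`, "n")),
       wp = do.call(rbind, lapply(res, `[[`, "wp")))
}

#' Angular deviation of the cursor from the best direction
#'
#' The signed angle (counter-clockwise positive) from the best direction
#' `n(t_i)` to the actual movement direction `omega_p(t_i)`, in
#' `(-pi, pi]`. Points with zero cursor velocity are skipped.
#'
#' @param trace a `game_trace` (downsample first for trial-scale
#'   statistics).
#' @return data.frame with columns `time_s`, `alpha` (radians).
#' @export
angular_deviation <- function(trace) {
  df <- as.data.frame(trace)
  geom <- .trace_geometry(df)
  speed <- sqrt(rowSums(geom$wp^2))
  keep <- speed > 0
  if (!all(keep)) {
    message(sum(!keep), " zero-velocity frame(s) skipped")
  }
  n <- geom$n[keep, , drop = FALSE]
  wp <- geom$wp[keep, , drop = FALSE]
  alpha <- atan2(n[, 1] * wp[, 2] - n[, 2] * wp[, 1],
                 rowSums(n * wp))
  data.frame(time_s = df$time_s[geom$idx[keep]], alpha = alpha)
}

#' Circular summary of an angular-deviation series
#'
#' Histogram over `(-pi, pi]` with bins centred on zero, the location of
#' the modal bin, and the circular standard deviation
#' `sqrt(-2 ln Rbar)` where `Rbar` is the mean resultant length.
#'
#' @param alpha numeric vector of angles in radians (>= 10 values).
#' @param bins number of histogram bins (36, i.e. 10 degrees each).
#' @return List with `histogram` (data.frame `center`, `count`),
#'   `peak_location` (radians), `spread` (radians) and `uniform_flag`
#'   (`TRUE` when the distribution is too flat for a stable peak).
#' @export
decision_stats <- function(alpha, bins = 36) {
  if (length(alpha) < 10) stop("need at least 10 angles")
  w <- 2 * pi / bins
  k <- round(alpha / w)
  k[k == bins / 2] <- -bins / 2        # pi and -pi are the same bin
  k <- factor(k, levels = seq(-bins / 2, bins / 2 - 1))
  counts <- as.integer(table(k))
  centers <- seq(-bins / 2, bins / 2 - 1) * w
  rbar <- sqrt(mean(cos(alpha))^2 + mean(sin(alpha))^2)
  peak_bin <- which.max(counts)
  list(histogram = data.frame(center = centers, count = counts),
       peak_location = centers[peak_bin],
       spread = sqrt(-2 * log(max(rbar, .Machine$double.eps))),
       uniform_flag = rbar < 0.1)
}

#' Optimal and incorrect gesture rates along a game trace
#'
#' The emitted direction vector is `delta(t_i) = (qr - ql, qu - qd)`;
#' a gesture is *optimal* when its cosine with the best direction exceeds
#' `d_th` (a cone of half-angle `acos(d_th)` around `n`), otherwise
#' *incorrect*. Gestures are then assigned to the left/right/up/down
#' groups by the dominant delta component when it exceeds
#' `prevalence_frac` times that component's standard deviation (gestures
#' below threshold on both axes fall in no group, so the eight group
#' rates sum to at most 1).
#'
#' @param trace a `game_trace` with output-vector columns `ql,qr,qu,qd`.
#' @param d_th cosine threshold (0.6, a 0.93 rad cone).
#' @param prevalence_frac prevalence threshold as a fraction of the
#'   component standard deviation (0.2).
#' @return List with `rates` (data.frame `direction`, `optimal`,
#'   `incorrect`), `L` (total gesture count) and `optimal_fraction`.
#' @export
gesture_fidelity <- function(trace, d_th = 0.6, prevalence_frac = 0.2) {
  df <- as.data.frame(trace)
  stopifnot(all(c("ql", "qr", "qu", "qd") %in% names(df)))
  geom <- .trace_geometry(df)
  delta <- cbind(df$qr - df$ql, df$qu - df$qd)[geom$idx, , drop = FALSE]
  nd <- sqrt(rowSums(delta^2))
  if (all(nd == 0)) stop("all-zero output vectors: no gestures to analyse")
  sig <- c(stats::sd(delta[, 1]), stats::sd(delta[, 2]))
  if (any(sig == 0)) sig[sig == 0] <- .Machine$double.eps
  usable <- nd > 0
  cosang <- rep(NA_real_, length(nd))
  cosang[usable] <- rowSums(delta[usable, , drop = FALSE] *
                              geom$n[usable, , drop = FALSE]) / nd[usable]
  optimal <- usable & cosang > d_th
  # dominant-axis prevalence: pick the component larger relative to its sd
  rel <- sweep(abs(delta), 2, sig, "/")
  axis <- ifelse(rel[, 1] >= rel[, 2], 1L, 2L)
  over <- abs(delta[cbind(seq_along(axis), axis)]) >
    prevalence_frac * sig[axis]
  dir <- rep(NA_character_, length(axis))
  dir[axis == 1L & delta[, 1] < 0 & over] <- "left"
  dir[axis == 1L & delta[, 1] > 0 & over] <- "right"
  dir[axis == 2L & delta[, 2] > 0 & over] <- "up"
  dir[axis == 2L & delta[, 2] < 0 & over] <- "down"
  L <- length(geom$idx)
  dirs <- c("left", "right", "up", "down")
  rates <- data.frame(
    direction = dirs,
    optimal = vapply(dirs, function(d)
      sum(dir == d & optimal & usable, na.rm = TRUE) / L, numeric(1)),
    incorrect = vapply(dirs, function(d)
      sum(dir == d & !optimal & usable, na.rm = TRUE) / L, numeric(1)))
  rownames(rates) <- NULL
  list(rates = rates, L = L,
       optimal_fraction = sum(optimal, na.rm = TRUE) / L)
}

#' Simulate a pursuit-game trace under a user policy
#'
#' At each control tick the simulated user intends the best interception
#' direction, but acts with a reaction delay and angular noise; the
#' intended direction is quantised to the nearest of the eight gesture
#' directions and the emitted output vector `q` comes from the control
#' law (by default the ideal target encoding of the emitted gesture; a
#' trained network closure can be passed instead).
#'
#' A per-gesture articulation error rate models "problematic" gestures
#' by slow switching: whenever the intent changes into or out of gesture
#' `g`, the switch is delayed by 0.3-0.8 s with probability
#' `per_gesture_error_rate[g]` (the previously emitted gesture
#' perseverates meanwhile) -- so a problematic gesture is evoked late
#' when needed and lingers when no longer appropriate.
#'
#' The cursor moves by the proportional-control displacement and scores
#' a point whenever it comes within `capture_radius` of the target
#' (which then escapes along its path).
#'
#' @param scenario a [game_scenario()].
#' @param profile a [subject_profile()].
#' @param control_law function `(gesture_id) -> q` returning the
#'   4-component output vector; `NULL` uses the ideal encoding.
#' @param seed integer seed.
#' @param tick_s control tick, seconds (0.1, the feature step).
#' @param gain displacement per tick at full output (screen units).
#' @param capture_radius capture distance (screen units).
#' @return Object of class `game_trace`: a data.frame with columns
#'   `time_s, px, py, cx, cy, ql, qr, qu, qd` plus attributes `score` and
#'   `seed`.
#' @export
simulate_game_trace <- function(scenario, profile, control_law = NULL,
                                seed = 1, tick_s = 0.1, gain = 20,
                                capture_radius = 20) {
  stopifnot(inherits(scenario, "game_scenario"),
            inherits(profile, "subject_profile"), tick_s > 0)
  set.seed(seed)
  enc <- gesture_encoding(4)
  if (is.null(control_law)) control_law <- function(g) enc[g, ]
  steps <- max(2L, ceiling(scenario$duration / tick_s))
  delay_steps <- round(profile$reaction_delay / tick_s)
  gest_dirs <- c(basic_gestures(), compound_gestures())
  dir_mat <- t(vapply(gest_dirs, gesture_direction, numeric(2)))
  dir_angles <- atan2(dir_mat[, 2], dir_mat[, 1])
  pos <- scenario$cursor_start
  vel <- c(0, 0)
  target_offset <- 0        # advanced on captures
  score <- 0L
  n_buffer <- vector("list", steps)
  last_g <- NA_character_   # previously emitted gesture
  prev_intent <- NA_character_
  lag_remaining <- 0L       # sticky-switch ticks left
  out <- matrix(NA_real_, nrow = steps, ncol = 9,
                dimnames = list(NULL, c("time_s", "px", "py", "cx", "cy",
                                        "ql", "qr", "qu", "qd")))
  for (i in seq_len(steps)) {
    t_now <- (i - 1) * tick_s
    tgt <- .target_state(scenario, t_now + target_offset)
    # intended best direction now (stored; acted on after the delay)
    bd <- tryCatch(best_direction(pos, vel, tgt$pos, tgt$vel, tick_s),
                   error = function(e) NULL)
    n_buffer[[i]] <- if (is.null(bd)) NULL else bd$n
    acted <- n_buffer[[max(1L, i - delay_steps)]]
    if (is.null(acted)) acted <- c(0, 0)
    g <- NA_character_
    if (any(acted != 0)) {
      ang <- atan2(acted[2], acted[1]) +
        stats::rnorm(1, 0, profile$angular_noise_sd)
      diffs <- abs(((dir_angles - ang + pi) %% (2 * pi)) - pi)
      g <- gest_dirs[which.min(diffs)]
    }
    if (!identical(g, prev_intent)) {
      # switching into or out of a problematic gesture may be slow
      err <- max(profile$per_gesture_error_rate[[g %||% "G1"]] * !is.na(g),
                 profile$per_gesture_error_rate[[prev_intent %||% "G1"]] *
                   !is.na(prev_intent))
      if (err > 0 && stats::runif(1) < err) {
        lag_remaining <- sample(round(0.3 / tick_s):round(0.8 / tick_s), 1)
      }
      prev_intent <- g
    }
    if (lag_remaining > 0L) {
      g <- last_g
      lag_remaining <- lag_remaining - 1L
    }
    last_g <- g
    q <- c(ql = 0, qr = 0, qu = 0, qd = 0)
    if (!is.na(g)) q <- control_law(g)[1:4]
    delta <- gain * c(q[[2]] - q[[1]], q[[3]] - q[[4]])
    new_pos <- pmin(pmax(pos + delta, c(0, 0)), scenario$arena)
    vel <- (new_pos - pos) / tick_s
    pos <- new_pos
    out[i, ] <- c(t_now, pos, tgt$pos, q)
    if (sqrt(sum((pos - tgt$pos)^2)) < capture_radius) {
      score <- score + 1L
      # target escapes to the next waypoint region
      target_offset <- target_offset + stats::runif(1, 5, 15)
    }
  }
  df <- as.data.frame(out)
  attr(df, "score") <- score
  attr(df, "seed") <- seed
  class(df) <- c("game_trace", class(df))
  df
}

#' @export
print.game_trace <- function(x, ...) {
  cat(sprintf("<game_trace> %d points over %.1f s, score %d\n",
              nrow(x), x$time_s[nrow(x)], attr(x, "score")))
  invisible(x)
}

#' Game score of a trace
#'
#' @param trace a `game_trace`.
#' @return Integer number of captures.
#' @export
game_score <- function(trace) {
  s <- attr(trace, "score")
  if (is.null(s)) stop("trace carries no score attribute")
  s
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
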