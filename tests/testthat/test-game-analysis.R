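test_that("best direction has closed forms for stationary and head-on targets", {
  # stationary target: t* = |d| / speed, aim straight at it
  bd <- best_direction(c(0, 0), c(1, 0), c(10, 0), c(0, 0), 0.1)
  expect_equal(bd$t_star, 10)
  expect_equal(bd$n, c(1, 0))
  expect_false(bd$fallback)
  # head-on approach: d = (10, 0), target speed 1 toward the pursuer,
  # pursuer speed 1: closing speed 2, t* = 5, interception at (5, 0)
  bd2 <- best_direction(c(0, 0), c(0, 1), c(10, 0), c(-1, 0), 0.1)
  expect_equal(bd2$t_star, 5)
  expect_equal(bd2$n, c(1, 0))
})

test_that("a receding faster target triggers the one-step-lookahead fallback", {
  d <- c(10, 0)
  wc <- c(2, 0)            # receding at twice the pursuer speed
  # discriminant analysis: a = 3, b = 40, c = 100 -> both roots negative
  a <- sum(wc^2) - 1; b <- 2 * sum(d * wc); cc <- sum(d^2)
  roots <- (-b + c(-1, 1) * sqrt(b^2 - 4 * a * cc)) / (2 * a)
  expect_true(all(roots < 0))
  bd <- best_direction(c(0, 0), c(0, 1), d, wc, dt_next = 0.5)
  expect_true(bd$fallback)
  expect_true(is.na(bd$t_star))
  v <- d + wc * 0.5
  expect_equal(bd$n, v / sqrt(sum(v^2)))
  # zero pursuer velocity also falls back
  expect_true(best_direction(c(0, 0), c(0, 0), d, c(0, 0), 0.5)$fallback)
  expect_error(best_direction(c(1, 1), c(1, 0), c(1, 1), c(0, 0), 0.1), "coincide")
})

test_that("best direction is always a unit vector and t* verified by time stepping", {
  set.seed(12)
  for (i in 1:50) {
    rp <- runif(2, 0, 100); rc <- runif(2, 0, 100)
    if (all(rp == rc)) next
    sp <- runif(1, 5, 20)
    wp <- sp * (function(a) c(cos(a), sin(a)))(runif(1, 0, 2 * pi))
    wc <- runif(2, -10, 10)
    bd <- best_direction(rp, wp, rc, wc, 0.05)
    expect_equal(sqrt(sum(bd$n^2)), 1, tolerance = 1e-9)
    if (!bd$fallback) {
      # brute-force: walk along n at speed |wp| while the target drifts;
      # capture when within one relative-speed step
      dt <- bd$t_star / 2000
      rel <- sqrt(sum((sp * bd$n - wc)^2))
      pos <- rp; tgt <- rc; hit_t <- NA
      for (k in 1:2600) {
        pos <- pos + sp * bd$n * dt
        tgt <- tgt + wc * dt
        if (sqrt(sum((pos - tgt)^2)) <= rel * dt) { hit_t <- k * dt; break }
      }
      expect_false(is.na(hit_t))
      expect_lt(abs(hit_t - bd$t_star), bd$t_star / 100 + 2 * dt + 1e-9)
    }
  }
})

test_that("finite-difference velocities follow the forward-difference definition", {
  tms <- c(0, 0.5, 1.5, 2)
  pos <- cbind(c(0, 1, 3, 3), c(0, 0, 2, 2))
  w <- trace_velocities(pos, tms)
  expect_equal(nrow(w), 3)
  expect_equal(w[1, ], c(2, 0))
  expect_equal(w[2, ], c(2, 2))
  expect_equal(w[3, ], c(0, 0))
  # uniform linear motion gives a constant velocity
  tt <- seq(0, 5, by = 0.1)
  lin <- cbind(3 * tt, -2 * tt)
  wl <- trace_velocities(lin, tt)
  expect_true(all(abs(sweep(wl, 2, c(3, -2))) < 1e-9))
  expect_error(trace_velocities(pos, c(0, 0, 1, 2)), "strictly increasing")
})

test_that("downsampling bounds the point count and preserves endpoints", {
  sc <- random_scenario(seed = 2, duration = 100)
  p <- subject_profile()
  tr <- simulate_game_trace(sc, p, seed = 4, tick_s = 0.05)
  expect_equal(nrow(tr), 2000)
  ds <- downsample_trace(tr)
  expect_lte(nrow(ds), 100)
  expect_gte(nrow(ds), 60)
  expect_equal(ds[1, c("px", "py")], tr[1, c("px", "py")])
  expect_equal(unlist(ds[nrow(ds), c("time_s", "cx")]),
               unlist(tr[nrow(tr), c("time_s", "cx")]))
  # already-sparse traces are unchanged
  sparse <- tr[seq(1, 2000, by = 40), ]
  class(sparse) <- class(tr)
  expect_equal(nrow(downsample_trace(sparse)), nrow(sparse))
})

test_that("a perfect policy yields small angular deviation; reversal gives |alpha| = pi", {
  sc <- game_scenario(rbind(c(100, 300), c(700, 300)), speeds = 40,
                      cursor_start = c(400, 100), duration = 30)
  p0 <- subject_profile(reaction_delay = 0, angular_noise_sd = 0)
  tr <- simulate_game_trace(sc, p0, seed = 5)
  ad <- angular_deviation(downsample_trace(tr))
  # movement is quantised to eight gesture directions, so the deviation is
  # bounded by half the 45-degree sector plus discretisation effects
  expect_lt(median(abs(ad$alpha)), pi / 8)
  # cursor moving exactly opposite the best direction
  df <- data.frame(time_s = c(0, 1, 2), px = c(0, -10, -20), py = 0,
                   cx = c(50, 50, 50), cy = 0,
                   ql = 1, qr = 0, qu = 0, qd = 0)
  ad2 <- angular_deviation(df)
  expect_equal(abs(ad2$alpha), rep(pi, nrow(ad2)))
})

test_that("mirror-reflecting the scene about the x-axis negates the deviation", {
  sc <- random_scenario(seed = 6, duration = 40)
  tr <- simulate_game_trace(sc, subject_profile(), seed = 7)
  ds <- downsample_trace(tr)
  ad <- angular_deviation(ds)
  mirrored <- ds
  mirrored$py <- -mirrored$py
  mirrored$cy <- -mirrored$cy
  ad_m <- angular_deviation(mirrored)
  expect_equal(ad_m$alpha, -ad$alpha, tolerance = 1e-9)
})

test_that("circular statistics have the expected degenerate behaviour", {
  st <- decision_stats(rep(0, 50))
  expect_equal(st$peak_location, 0)
  expect_equal(st$spread, 0, tolerance = 1e-6)
  expect_false(st$uniform_flag)
  set.seed(8)
  st_u <- decision_stats(runif(2000, -pi, pi))
  expect_true(st_u$uniform_flag)
  expect_gt(st_u$spread, 1.5)
  expect_error(decision_stats(rep(0, 5)), "at least 10")
  # histogram covers (-pi, pi] with bins centred on zero
  expect_equal(sum(st$histogram$count), 50)
  expect_equal(st$histogram$center[which.max(st$histogram$count)], 0)
})

test_that("tightening the angular noise shrinks the circular spread", {
  sc <- random_scenario(seed = 9, duration = 40)
  spreads <- sapply(c(0.05, 0.3, 0.8), function(sdn) {
    mean(sapply(1:3, function(s) {
      p <- subject_profile(angular_noise_sd = sdn, reaction_delay = 0.1)
      tr <- simulate_game_trace(sc, p, seed = 20 + s)
      decision_stats(angular_deviation(downsample_trace(tr))$alpha)$spread
    }))
  })
  expect_true(all(diff(spreads) > 0))
})

test_that("the optimality criterion accepts exactly the directions inside the cone", {
  # dense angular grid around a fixed best direction
  n <- c(1, 0)
  th <- acos(0.6)
  angles <- seq(-pi, pi, length.out = 721)
  inside <- vapply(angles, function(a) {
    delta <- c(cos(a), sin(a)) * 0.8
    sum(delta * n) / sqrt(sum(delta^2)) > 0.6
  }, logical(1))
  expect_equal(inside, abs(angles) < th)
})

test_that("gesture rates are disjoint, bounded, and respond to articulation errors", {
  rates_at <- function(err, s) {
    sc <- random_scenario(seed = 100 + s, duration = 60)
    p <- subject_profile(reaction_delay = 0.1, angular_noise_sd = 0.15,
                         per_gesture_error_rate = c(up = err))
    tr <- simulate_game_trace(sc, p, seed = 30 + s)
    gf <- gesture_fidelity(tr)
    expect_lte(sum(gf$rates$optimal) + sum(gf$rates$incorrect), 1 + 1e-9)
    expect_true(all(gf$rates$optimal >= 0 & gf$rates$optimal <= 1))
    gf$rates
  }
  up_rates <- lapply(c(0, 0.6), function(err) {
    rr <- lapply(1:8, function(s) rates_at(err, s))
    c(inc = mean(sapply(rr, function(r) r$incorrect[r$direction == "up"])),
      opt = mean(sapply(rr, function(r) r$optimal[r$direction == "up"])))
  })
  # a problematic "up" gesture fires late and lingers: more incorrect,
  # fewer optimal up gestures on average
  expect_gt(up_rates[[2]]["inc"], up_rates[[1]]["inc"])
  expect_lt(up_rates[[2]]["opt"], up_rates[[1]]["opt"])
})

test_that("all-zero output vectors are rejected", {
  df <- data.frame(time_s = 0:9, px = 0:9, py = 0, cx = 50, cy = 0,
                   ql = 0, qr = 0, qu = 0, qd = 0)
  expect_error(gesture_fidelity(df), "all-zero")
})
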