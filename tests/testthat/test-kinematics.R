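test_that("movement offset honors the 33.3 ms stationarity minimum", {
  # constant-velocity motion for 500 ms then frozen for 100 ms: offset at 500 ms
  tm <- seq(0, 500, by = 5)
  tf <- seq(505, 600, by = 5)
  tr <- make_traj(c(tm, tf), rep(0, length(tm) + length(tf)),
                  c(15 * tm / 500, rep(15, length(tf))))
  off <- detect_movement_offset(tr)
  expect_equal(off$offset_ms, 500)
  expect_false(off$no_offset)
  # onset: first sample farther than 0.5 cm from home
  r <- sqrt(tr$x_cm^2 + tr$y_cm^2)
  expect_equal(off$onset_ms, tr$t_ms[which(r > 0.5)[1]])

  # a 30 ms freeze (6 intervals) does not qualify; the 600 ms freeze does
  t1 <- seq(0, 300, by = 5)
  y1 <- 15 * (t1 / 600) # moving
  t2 <- seq(305, 330, by = 5)
  y2 <- rep(y1[length(y1)], length(t2)) # frozen exactly 30 ms
  t3 <- seq(335, 600, by = 5)
  y3 <- seq(y2[1] + 0.1, 15, length.out = length(t3)) # moving again
  t4 <- seq(605, 700, by = 5)
  y4 <- rep(15, length(t4)) # frozen from 600 ms on
  tr2 <- make_traj(c(t1, t2, t3, t4), rep(0, length(c(t1, t2, t3, t4))),
                   c(y1, y2, y3, y4))
  off2 <- detect_movement_offset(tr2)
  expect_equal(off2$offset_ms, 600)

  # independent oracle: explicit linear scan with the 33.3 ms rule
  scan_offset <- function(traj) {
    r <- sqrt(traj$x_cm^2 + traj$y_cm^2)
    onset <- which(r > 0.5)[1]
    d <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)
    for (i in (onset + 1):nrow(traj)) {
      ok <- TRUE
      dur <- 0
      j <- i
      while (j < nrow(traj) && dur < 100 / 3) {
        if (d[j] >= 0.01) {
          ok <- FALSE
          break
        }
        dur <- dur + (traj$t_ms[j + 1] - traj$t_ms[j])
        j <- j + 1
      }
      if (ok && dur >= 100 / 3) return(traj$t_ms[i])
    }
    NA_real_
  }
  expect_equal(off$offset_ms, scan_offset(tr))
  expect_equal(off2$offset_ms, scan_offset(tr2))
})

test_that("a trajectory that freezes right after leaving home gets an immediate offset", {
  tr <- make_traj(seq(0, 100, by = 5), rep(0, 21), c(0, rep(10, 20)))
  off <- detect_movement_offset(tr)
  expect_equal(off$onset_ms, 5)
  expect_equal(off$offset_ms, 10) # first post-onset sample
})

test_that("a trajectory with no stationary run is flagged no-offset", {
  t <- seq(0, 400, by = 5)
  tr <- make_traj(t, rep(0, length(t)), 15 * t / 400)
  off <- detect_movement_offset(tr)
  expect_true(off$no_offset)
  expect_equal(off$offset_ms, 400)
})

test_that("mean speed applies the strict 20 cm/s threshold", {
  lin <- function(ms) {
    t <- seq(0, ms, by = 5)
    make_traj(t, rep(0, length(t)), 15 * t / ms)
  }
  fast <- mean_speed(lin(500), 0, 500)
  expect_equal(fast$mean_speed_cm_s, 30)
  expect_false(fast$slow_flag)

  slow <- mean_speed(lin(1000), 0, 1000)
  expect_equal(slow$mean_speed_cm_s, 15)
  expect_true(slow$slow_flag)

  # exactly 20.0 cm/s: 15 cm in 750 ms, strict < means not slow
  boundary <- mean_speed(lin(750), 0, 750)
  expect_equal(boundary$mean_speed_cm_s, 20)
  expect_false(boundary$slow_flag)

  expect_error(mean_speed(lin(500), 500, 500), "offset")
})

test_that("endpoint metrics follow the clockwise-positive angle convention", {
  on_target <- endpoint_metrics(15 * sin(-30 * pi / 180), 15 * cos(-30 * pi / 180), -30)
  expect_equal(on_target$direction_deg, 0)
  expect_equal(on_target$extent_cm, 15)

  overshoot <- endpoint_metrics(0, 17.25, 0)
  expect_equal(overshoot$direction_deg, 0)
  expect_equal(overshoot$extent_cm, 17.25)

  cw <- endpoint_metrics(15 * sin(8.53 * pi / 180), 15 * cos(8.53 * pi / 180), 0)
  expect_equal(cw$direction_deg, 8.53)
  expect_equal(cw$extent_cm, 15)

  expect_error(endpoint_metrics(0, 0, 0), "home position")
})

test_that("max path deviation matches geometric oracles", {
  t <- seq(0, 500, by = 5)
  straight <- make_traj(t, rep(0, length(t)), 15 * t / 500)
  expect_equal(max_path_deviation(straight, 0, 500), 0)

  # sinusoidal detour of amplitude 2 on a 15 cm reach
  s <- t / 500
  arc <- make_traj(t, 2 * sin(pi * s), 15 * s)
  expect_equal(max_path_deviation(arc, 0, 500), 2, tolerance = 1e-3)

  # single mid-path sample displaced 3 cm laterally
  spike <- straight
  spike$x_cm[50] <- 3
  expect_equal(max_path_deviation(spike, 0, 500), 3)

  # oracle: brute-force point-to-segment distance
  seg_dist <- function(px, py, ex, ey) {
    tt <- pmin(pmax((px * ex + py * ey) / (ex^2 + ey^2), 0), 1)
    sqrt((px - tt * ex)^2 + (py - tt * ey)^2)
  }
  expect_equal(max_path_deviation(arc, 0, 500),
               max(seg_dist(arc$x_cm, arc$y_cm, 0, 15)))
})

test_that("Savitzky-Golay differentiation is exact on quadratic signals", {
  t <- seq(0, 1000, by = 5)
  a <- 2e-5
  b <- 0.01
  cxy <- 1.5e-5
  tr <- make_traj(t, a * t^2 + b * t, cxy * t^2)
  sp <- reachprime:::sg_speed(tr)
  # analytic speed of the quadratic path (t in ms, positions in cm -> cm/s)
  vx <- (2 * a * t + b) * 1000
  vy <- (2 * cxy * t) * 1000
  expected <- sqrt(vx^2 + vy^2)
  interior <- !is.na(sp)
  expect_equal(sum(!interior), 30) # 15 samples lost at each edge
  expect_equal(sp[interior], expected[interior], tolerance = 1e-9)
})

test_that("peak-velocity direction is on target for a straight minimum-jerk reach", {
  tr <- straight_reach_traj(move_ms = 500, tail_ms = 100)
  off <- detect_movement_offset(tr)
  pk <- direction_at_peak_velocity(tr, 0, off$onset_ms, off$offset_ms)
  expect_equal(pk$peakvel_direction_deg, 0, tolerance = 1e-6)
  # minimum-jerk peak speed = 1.875 * d / T at the movement midpoint
  expect_equal(pk$peak_speed_cm_s, 1.875 * 15 / 0.5, tolerance = 0.05)
  expect_equal(pk$peak_time_ms, 250, tolerance = 15)
})

test_that("an initially deviated path has larger peak-velocity than endpoint direction", {
  # fast first segment along a 5 deg clockwise bearing, slow correction to target
  dt <- 5
  t1 <- seq(0, 300, by = dt)
  tau1 <- t1 / 300
  s1 <- 10 * tau1^3 - 15 * tau1^4 + 6 * tau1^5
  mid <- c(10 * sin(5 * pi / 180), 10 * cos(5 * pi / 180))
  x1 <- mid[1] * s1
  y1 <- mid[2] * s1
  t2 <- seq(305, 700, by = dt)
  tau2 <- (t2 - 300) / 400
  s2 <- 10 * tau2^3 - 15 * tau2^4 + 6 * tau2^5
  x2 <- mid[1] + (0 - mid[1]) * s2
  y2 <- mid[2] + (15 - mid[2]) * s2
  t3 <- seq(705, 800, by = dt)
  tr <- make_traj(c(t1, t2, t3), c(x1, x2, rep(0, length(t3))),
                  c(y1, y2, rep(15, length(t3))))
  off <- detect_movement_offset(tr)
  pk <- direction_at_peak_velocity(tr, 0, off$onset_ms, off$offset_ms)
  ep <- endpoint_metrics(0, 15, 0)
  expect_gt(pk$peakvel_direction_deg, ep$direction_deg)
  expect_gt(pk$peakvel_direction_deg, 3)
})

test_that("rotation changes direction only and gain changes extent only", {
  set.seed(31)
  for (i in 1:10) {
    x <- runif(1, -8, 8)
    y <- runif(1, 8, 18)
    base <- endpoint_metrics(x, y, 0)
    rot <- apply_perturbation(x, y, "rotation", 5.71)
    mrot <- endpoint_metrics(rot$x, rot$y, 0)
    expect_equal(mrot$extent_cm, base$extent_cm, tolerance = 1e-9)
    expect_equal(mrot$direction_deg - base$direction_deg, 5.71, tolerance = 1e-9)
    gn <- apply_perturbation(x, y, "gain", -0.1)
    mgn <- endpoint_metrics(gn$x, gn$y, 0)
    expect_equal(mgn$direction_deg, base$direction_deg, tolerance = 1e-9)
    expect_equal(mgn$extent_cm / base$extent_cm, 0.9, tolerance = 1e-9)
  }
})

test_that("kinematics recovered from simulated trajectories match trial records", {
  sc <- session_schedule("arc", seed = 19)
  p <- agent_params(p_slow = 0.1, p_curved = 0.1, p_outlier = 0)
  out <- simulate_session(sc, p, seed = 20, phases = "test", trajectories = TRUE)
  sub <- out$trials[1:40, ]
  traj <- out$trajectories[out$trajectories$trial_id %in% sub$trial_id, ]
  kin <- compute_kinematics(traj, sub)
  # detected endpoint within a millimetre of the generative endpoint
  expect_lt(max(abs(kin$endpoint_x_cm - sub$endpoint_x_cm)), 0.1)
  expect_lt(max(abs(kin$endpoint_y_cm - sub$endpoint_y_cm)), 0.1)
  # injected curved trials recovered, clean trials essentially straight
  expect_equal(kin$max_dev_cm > 2, sub$injected_curved)
  # slow flags match the injected artifacts
  expect_equal(kin$slow_flag, sub$injected_slow)
})
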