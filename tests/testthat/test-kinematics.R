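test_that("body centroid is the head/abdomen midpoint", {
  d <- data.frame(frame = 0, head_x = 0, head_y = 0,
                  abdomen_x = 0.014, abdomen_y = 0,
                  ftj_x = 0.005, ftj_y = -0.002,
                  tarsus_x = 0.006, tarsus_y = -0.004)
  traj <- track_trajectory(d, 2000)
  expect_equal(unname(body_centroid(traj, 0)), c(0.007, 0))
  d2 <- d
  d2$abdomen_x <- 0; d2$abdomen_y <- 0
  expect_equal(unname(body_centroid(track_trajectory(d2, 2000), 0)), c(0, 0))
})

test_that("body angle handles quadrants, unwrapping and degeneracy", {
  mk <- function(hx, hy) {
    d <- data.frame(frame = 0, head_x = hx, head_y = hy,
                    abdomen_x = 0, abdomen_y = 0,
                    ftj_x = 0.001, ftj_y = 0, tarsus_x = 0.002, tarsus_y = 0)
    track_trajectory(d, 2000)
  }
  expect_equal(body_angle(mk(1, 1), 0), pi / 4)
  expect_equal(body_angle(mk(-1, 0), 0), pi)
  expect_error(body_angle(mk(0, 0), 0), "degenerate body axis")

  # several turns at 0.05 rad/frame: unwrapped series is strictly
  # increasing with the generative slope, wrapped diffs stay in (-pi, pi)
  n <- 300
  traj <- rod_traj(n, av = 0.05 * 2000, theta0 = 0.3)
  th <- body_angle(traj)
  expect_true(all(diff(th) > 0))
  expect_equal(max(abs(diff(th) - 0.05)), 0, tolerance = 1e-9)
  expect_gt(max(th) - min(th), 2 * pi)  # the series really wraps
})

test_that("secant velocities match hand computations and generative truth", {
  # centroid displacement (0.03, 0.04) m over 50 frames at 2000 Hz
  traj <- rod_traj(51, vx = 0.03 / 0.025, vy = 0.04 / 0.025)
  expect_equal(secant_linear_velocity(traj, 0, 50), 2.0, tolerance = 1e-12)
  still <- rod_traj(10)
  expect_equal(secant_linear_velocity(still, 0, 9), 0)
  expect_error(secant_linear_velocity(traj, 5, 5), "smaller")

  # noise-free constant motion reproduces the printed 50-mm means exactly
  cv <- rod_traj(80, vx = 0, vy = 1.40, av = 47.36)
  expect_equal(secant_linear_velocity(cv, 0, 79), 1.40, tolerance = 1e-12)
  expect_equal(secant_angular_velocity(cv, 0, 79), 47.36, tolerance = 1e-12)

  # half-turn over 66.3 ms
  fps <- 1 / 0.0663 * 100
  half <- rod_traj(101, fps = fps, av = pi / 0.0663)
  expect_equal(secant_angular_velocity(half, 0, 100), pi / 0.0663,
               tolerance = 1e-9)
  expect_equal(pi / 0.0663, 47.36, tolerance = 1e-3)
})

test_that("local velocity agrees with secant on constant motion and is
           within the truncation bound on ballistic flight", {
  cv <- rod_traj(60, vx = 0.4, vy = 1.2, av = 31.80)
  lw <- local_velocity(cv, 30, window = 5)
  expect_equal(lw[["lv"]], secant_linear_velocity(cv, 0, 59),
               tolerance = 1e-9)
  expect_equal(lw[["av"]], 31.80, tolerance = 1e-9)

  g <- 9.81
  bal <- rod_traj(80, vy = 1.79, gravity = g, cy0 = 0.03)
  lw2 <- local_velocity(bal, 40, window = 2)
  v_true <- 1.79 - g * (40 / 2000)
  expect_lt(abs(lw2[["lv"]] - v_true), g / 2000)
  expect_error(local_velocity(bal, 0, window = 5), "window extends past")
})

test_that("FTJ angle is correct, bounded and rigid-motion invariant", {
  mk <- function(prox, ftj, tar) {
    d <- data.frame(frame = 0, head_x = prox[1] + 0.02, head_y = prox[2],
                    abdomen_x = prox[1], abdomen_y = prox[2],
                    ftj_x = ftj[1], ftj_y = ftj[2],
                    tarsus_x = tar[1], tarsus_y = tar[2])
    track_trajectory(d, 2000)
  }
  expect_equal(ftj_angle(mk(c(-1, 0), c(0, 0), c(1, 0)), 0), 180)
  expect_equal(ftj_angle(mk(c(0, 1), c(0, 0), c(1, 0)), 0), 90)
  expect_error(ftj_angle(mk(c(0, 1), c(0, 0), c(0, 0)), 0),
               "degenerate joint")

  set.seed(42)
  for (i in 1:20) {
    prox <- runif(2); ftj <- runif(2); tar <- runif(2)
    a0 <- ftj_angle(mk(prox, ftj, tar), 0)
    phi <- runif(1, 0, 2 * pi); shift <- runif(2, -1, 1)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    tf <- function(p) as.vector(R %*% p + shift)
    a1 <- ftj_angle(mk(tf(prox), tf(ftj), tf(tar)), 0)
    expect_equal(a1, a0, tolerance = 1e-9)
  }

  # generator posture built with a 144-degree take-off FTJ angle
  cfg <- exact_config(ftj_takeoff_mean = c(144, 144, 144))
  st <- simulate_study(cfg)
  tr <- st$trajectories[[5L]]   # a 100-mm jump
  expect_equal(ftj_angle(tr, st$truth$takeoff_frame[5L]), 144,
               tolerance = 0.01)
})

test_that("event detection matches generator truth and fails cleanly", {
  st <- simulate_study(small_config())
  for (i in c(1L, 6L, 12L)) {
    tr <- st$trajectories[[i]]
    truth <- st$truth[i, ]
    expect_lte(abs(detect_takeoff(tr) - truth$takeoff_frame), 1)
    # contact can only fire early (within the tolerance band below the
    # target), never late; a tighter tolerance fires no earlier
    c1 <- detect_contact(tr, truth$target_height)
    c2 <- detect_contact(tr, truth$target_height, tolerance = 5e-4)
    expect_lte(c1, truth$contact_frame + 1)
    expect_gte(c2, c1)
    expect_lte(abs(c2 - truth$contact_frame), 2)
    r <- match(c1, tr$data$frame)
    expect_gte(tr$data$head_y[r], truth$target_height - 1e-3)
  }
  grounded <- rod_traj(30, tarsus_y = 0)
  expect_error(detect_takeoff(grounded), "no take-off detected")
  airborne <- rod_traj(30, tarsus_y = 0.002)
  expect_error(detect_takeoff(airborne, clearance = 0.05),
               "no take-off detected")
  low <- rod_traj(30, cy0 = 0.02)
  expect_error(detect_contact(low, target_y = 0.5), "no contact detected")
  expect_error(detect_contact(low, target_y = 0.001), "no contact detected")
  expect_equal(detect_contact(low, target_y = 0.5, tolerance = 10), 0)
})

test_that("total rotation of a constructed half-turn flight is pi", {
  av <- 47.36
  n_fl <- round(pi / av * 2000)
  traj <- rod_traj(n_fl + 1, av = av, theta0 = 0.2)
  ev <- jump_events(-1, 0, n_fl)
  expect_equal(total_rotation(traj, ev), n_fl / 2000 * av, tolerance = 1e-9)
  expect_lt(abs(total_rotation(traj, ev) - pi), av / 2000)
  expect_equal(total_rotation(rod_traj(50, av = 0), jump_events(0, 1, 49)), 0)
  expect_error(jump_events(5, 5, 10), "stationary < takeoff < contact")
})

test_that("analyze_jump recovers noise-free generative truth", {
  st <- simulate_study(exact_config())
  res <- analyze_study(st)
  truth <- st$truth
  fps <- st$config$frame_rate
  g <- st$config$g
  # discretization bounds: one g*dt for speeds, one frame for events
  expect_lt(max(abs(res$lv - truth$lv)), 3 * g / fps)
  expect_lt(max(abs(res$av - truth$av)), 1e-6)
  expect_lt(max(abs(res$av_secant - truth$av)), 1e-6)
  expect_lt(max(abs(res$ftj_takeoff - truth$ftj_takeoff)), 0.02)
  expect_lt(max(abs(res$ftj_rest - truth$ftj_rest)), 0.02)
  expect_lte(max(abs(res$takeoff_frame - truth$takeoff_frame)), 1)
  expect_lte(max(abs(res$air_time - truth$air_time)), 2.5 / fps)

  # a trajectory cut before the flight phase cannot reach the target
  tr <- st$trajectories[[1L]]
  cut <- track_trajectory(tr$data[seq_len(truth$takeoff_frame[1] + 2), ],
                          fps, jump_id = "cut",
                          target_height = tr$target_height)
  m <- st$morphometrics[1, ]
  expect_error(analyze_jump(cut, m), "cut.*no contact detected")
})

test_that("estimates converge to truth as tracking noise shrinks", {
  rmse_at <- function(noise_sd) {
    st <- simulate_study(small_config(tracking_noise_sd = noise_sd))
    res <- analyze_study(st)
    sqrt(mean((res$av_secant - st$truth$av)^2))
  }
  r <- vapply(c(2e-4, 5e-5, 0), rmse_at, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_lt(r[3], 1e-6)
})
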