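# Shared fixtures: all built in code at test time.

# rigid-rod trajectory with prescribed centroid motion and rotation;
# gravity > 0 gives ballistic vertical motion
rod_traj <- function(n, fps = 2000, cx0 = 0, cy0 = 0.02, vx = 0, vy = 0,
                     gravity = 0, theta0 = 0, av = 0, L = 0.0146,
                     tarsus_y = NULL, jump_id = "fix",
                     target_height = NA_real_) {
  t <- (0:(n - 1)) / fps
  cx <- cx0 + vx * t
  cy <- cy0 + vy * t - gravity * t^2 / 2
  th <- theta0 + av * t
  frames <- data.frame(
    frame = 0:(n - 1),
    head_x = cx + L / 2 * cos(th), head_y = cy + L / 2 * sin(th),
    abdomen_x = cx - L / 2 * cos(th), abdomen_y = cy - L / 2 * sin(th),
    ftj_x = cx + 0.002, ftj_y = cy - 0.004,
    tarsus_x = cx + 0.005,
    tarsus_y = if (is.null(tarsus_y)) cy - 0.008 else tarsus_y)
  track_trajectory(frames, fps, jump_id = jump_id,
                   target_height = target_height)
}

# reduced synthetic study for fast unit tests
small_config <- function(seed = 11L, ...) {
  study_config(jumps_per_height = c(4L, 4L, 4L), seed = seed, ...)
}

# zero-variance, noise-free configuration: every draw equals its mean
exact_config <- function(...) {
  study_config(lv_se = rep(0, 3), av_se = rep(0, 3),
               ftj_takeoff_se = rep(0, 3), ftj_rest_se = rep(0, 3),
               animal_sd_fraction = 0, tracking_noise_sd = 0,
               body_length_sd = 0, jumps_per_height = c(2L, 2L, 2L),
               seed = 5L, ...)
}

# the full default study is expensive enough to share across test files
.fixtures <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.fixtures$results)) {
    st <- simulate_study(study_config(seed = 1L))
    .fixtures$study <- st
    .fixtures$results <- analyze_study(st)
  }
  list(study = .fixtures$study, results = .fixtures$results)
}

# printed per-height study values used as generative defaults
printed <- list(
  heights = c(0.050, 0.075, 0.100),
  n = c(47L, 53L, 51L),
  lv = c(1.40, 1.55, 1.79), lv_se = c(0.07, 0.08, 0.12),
  av = c(47.36, 38.10, 31.80), av_se = c(3.51, 2.43, 3.18),
  ftj_100 = 144, ftj_100_se = 2.65)
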