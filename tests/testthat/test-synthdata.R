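test_that("default roster reproduces the study structure exactly", {
  roster <- sample_study(study_config())
  asg <- roster$assignments
  expect_equal(nrow(asg), 151L)
  expect_equal(as.vector(table(asg$target_height)), c(47L, 53L, 51L))
  expect_equal(nrow(roster$morphometrics), 7L)
  expect_equal(sum(roster$morphometrics$sex == "M"), 5L)
  expect_equal(sum(roster$morphometrics$sex == "F"), 2L)
  m <- roster$morphometrics
  expect_true(all(m$mass >= 6.78e-5 & m$mass <= 8.22e-5))
  # hind leg is exactly 1.37 body lengths for every animal
  expect_equal((m$femur_length + m$tibia_length) / m$body_length,
               rep(1.37, 7), tolerance = 1e-12)
  # every animal jumps at every height (needed by the stratified test)
  expect_true(all(table(asg$animal_id, asg$target_height) > 0))
})

test_that("sampling is deterministic given the seed", {
  r1 <- sample_study(study_config(seed = 33L))
  r2 <- sample_study(study_config(seed = 33L))
  expect_identical(r1, r2)
  s1 <- simulate_study(small_config())
  s2 <- simulate_study(small_config())
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$trajectories[[3]]$data, s2$trajectories[[3]]$data)
  s3 <- simulate_study(small_config(seed = 12L))
  expect_false(identical(s1$trajectories[[3]]$data,
                         s3$trajectories[[3]]$data))
  expect_identical(dim(s1$truth), dim(s3$truth))
})

test_that("zero-variance configuration hits the fixed-effect means exactly", {
  cfg <- exact_config()
  st <- simulate_study(cfg)
  t50 <- st$truth[st$truth$target_height == 0.050, ]
  expect_equal(t50$lv, rep(1.40, 2))
  expect_equal(t50$av, rep(47.36, 2))
  t100 <- st$truth[st$truth$target_height == 0.100, ]
  expect_equal(t100$ftj_takeoff, rep(144, 2))
})

test_that("mean-preserving truncation keeps the configured means", {
  cfg <- study_config()
  a0 <- setNames(rep(0, 4), c("lv", "av", "ftj_rest", "ftj_takeoff"))
  set.seed(99)
  draws <- replicate(4000, unlist(sample_jump_parameters(cfg, a0, 0.100)))
  lv <- draws["lv", ]
  # reachability floor holds, yet the mean stays at the configured value
  expect_true(all(lv >= sqrt(2 * 9.81 * (0.100 + 0.0146 / 2 - 0.024))))
  expect_lt(abs(mean(lv) - 1.79), 3 * sd(lv) / sqrt(length(lv)))
  av <- draws["av", ]
  expect_true(all(av > 0))
  expect_lt(abs(mean(av) - 31.80), 3 * sd(av) / sqrt(length(av)))
})

test_that("synthesized bodies are rigid rods with consistent placement", {
  st <- simulate_study(exact_config())
  tr <- st$trajectories[[1L]]
  L <- st$morphometrics$body_length[
    st$morphometrics$animal_id == tr$animal_id]
  seg <- sqrt((tr$data$head_x - tr$data$abdomen_x)^2 +
                (tr$data$head_y - tr$data$abdomen_y)^2)
  expect_equal(seg, rep(L, nrow(tr$data)), tolerance = 1e-12)
  # grounded until take-off, airborne after
  truth <- st$truth[1, ]
  grounded <- tr$data$frame < truth$takeoff_frame
  expect_true(all(abs(tr$data$tarsus_y[grounded]) < 1e-9))
  expect_true(all(tr$data$tarsus_y[!grounded] > 5e-4))
})

test_that("truth covers every estimated quantity", {
  st <- simulate_study(small_config())
  res <- analyze_study(st)
  estimated <- c("lv", "av", "ftj_rest", "ftj_takeoff", "air_time",
                 "total_rotation", "takeoff_frame", "contact_frame",
                 "body_angle_takeoff")
  expect_true(all(estimated %in% names(st$truth)))
  expect_setequal(res$jump_id, st$truth$jump_id)
})

test_that("generated study trees are parseable and byte-reproducible", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  st <- generate_study(cfg, d1)
  generate_study(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_length(files, 12 + 4)   # 12 trajectories + 3 tables + manifest
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  back <- load_study(d1)
  expect_equal(length(back$trajectories), 12L)
  for (i in c(1L, 7L)) {
    a <- st$trajectories[[i]]$data
    b <- back$trajectories[[i]]$data
    for (col in setdiff(names(a), c("frame", "t")))
      expect_lt(max(abs(a[[col]] - b[[col]])), 1e-9)
  }
  # loaded studies analyze identically
  res1 <- analyze_study(st)
  res2 <- analyze_study(back)
  expect_equal(res1$av_secant, res2$av_secant, tolerance = 1e-6)
})

test_that("invalid configurations are rejected with every fault listed", {
  expect_error(study_config(jumps_per_height = c(10, 10)),
               "one per height")
  expect_error(study_config(rest_frames = 4), "rest_frames")
  err <- tryCatch(study_config(n_animals = 0, g = -1), error = identity)
  expect_match(conditionMessage(err), "n_animals")
  expect_match(conditionMessage(err), "g must be positive")
})
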