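test_that("wide-layout files convert units and match pre-converted data", {
  d_mm <- data.frame(frame = 0:2,
                     head_x = c(10, 11, 12), head_y = c(20, 21, 22),
                     abdomen_x = c(0, 1, 2), abdomen_y = c(18, 19, 20),
                     ftj_x = c(5, 6, 7), ftj_y = c(15, 16, 17),
                     tarsus_x = c(6, 7, 8), tarsus_y = c(0.1, 0.2, 0.3))
  f_mm <- withr::local_tempfile(fileext = ".csv")
  write.csv(cbind(d_mm[1], t = d_mm$frame / 2000, d_mm[-1]), f_mm,
            row.names = FALSE, quote = FALSE)
  traj <- read_trajectory(f_mm, scale = 0.001, frame_rate = 2000)
  expect_equal(nrow(traj$data), 3L)
  expect_equal(traj$data$head_x, c(0.010, 0.011, 0.012))
  expect_equal(traj$data$tarsus_y, c(0.0001, 0.0002, 0.0003))

  d_m <- d_mm
  d_m[-1] <- d_m[-1] / 1000
  f_m <- withr::local_tempfile(fileext = ".csv")
  write.csv(cbind(d_m[1], t = d_m$frame / 2000, d_m[-1]), f_m,
            row.names = FALSE, quote = FALSE)
  traj_m <- read_trajectory(f_m, scale = 1, frame_rate = 2000)
  expect_equal(traj$data, traj_m$data, tolerance = 1e-12)
})

test_that("long-layout files are pivoted and validated", {
  pts <- c("head", "abdomen_tip", "ftj", "tarsus")
  long <- expand.grid(point = pts, frame = 0:2, stringsAsFactors = FALSE)
  long$t <- long$frame / 2000
  long$x <- seq_len(nrow(long)) * 0.001
  long$y <- seq_len(nrow(long)) * 0.002
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(long[, c("frame", "t", "point", "x", "y")], f,
            row.names = FALSE, quote = FALSE)
  traj <- read_trajectory(f, frame_rate = 2000)
  expect_equal(nrow(traj$data), 3L)
  expect_equal(traj$data$head_x[1], long$x[long$frame == 0 &
                                             long$point == "head"])
  expect_equal(traj$data$ftj_y[3], long$y[long$frame == 2 &
                                            long$point == "ftj"])

  # frame blocks out of order
  scrambled <- long[long$frame != 1, ]
  scrambled <- rbind(scrambled, long[long$frame == 1, ])
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(scrambled[, c("frame", "t", "point", "x", "y")], f2,
            row.names = FALSE, quote = FALSE)
  expect_error(read_trajectory(f2, frame_rate = 2000),
               "non-monotonic frame index")

  # one point label missing from one frame
  dropped <- long[!(long$frame == 1 & long$point == "tarsus"), ]
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(dropped[, c("frame", "t", "point", "x", "y")], f3,
            row.names = FALSE, quote = FALSE)
  expect_error(read_trajectory(f3, frame_rate = 2000),
               "frame 1: missing point label 'tarsus'")

  # corrupted numeric reports its file line (line 1 is the header)
  txt <- readLines(f)
  cells <- strsplit(txt[5], ",")[[1]]
  cells[4] <- "not-a-number"
  txt[5] <- paste(cells, collapse = ",")
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, f4)
  expect_error(read_trajectory(f4, frame_rate = 2000),
               "line 5")
})

test_that("write/read round trip is the identity on trajectories", {
  st <- simulate_study(small_config())
  traj <- st$trajectories[[1L]]
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f, scale = 1, frame_rate = traj$frame_rate,
                          jump_id = traj$jump_id,
                          animal_id = traj$animal_id, sex = traj$sex,
                          target_height = traj$target_height)
  for (col in setdiff(names(traj$data), c("frame", "t")))
    expect_lt(max(abs(back$data[[col]] - traj$data[[col]])), 1e-9)
  expect_identical(back$data$frame, traj$data$frame)

  # empty and single-frame trajectories
  empty <- track_trajectory(traj$data[0, ], traj$frame_rate)
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(empty, f0)
  expect_length(readLines(f0), 1L)
  one <- track_trajectory(traj$data[1, ], traj$frame_rate)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(one, f1)
  lines <- readLines(f1)
  expect_length(lines, 2L)
  expect_length(strsplit(lines[2], ",")[[1]], 10L)
})

test_that("y_flip negates the vertical axis", {
  st <- simulate_study(small_config())
  traj <- st$trajectories[[2L]]
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  flipped <- read_trajectory(f, frame_rate = traj$frame_rate, y_flip = TRUE)
  expect_equal(flipped$data$head_y, -traj$data$head_y, tolerance = 1e-9)
  expect_equal(flipped$data$head_x, traj$data$head_x, tolerance = 1e-9)
})

test_that("results tables round trip and reject heterogeneous records", {
  res <- analyze_study(simulate_study(small_config()))
  f <- withr::local_tempfile(fileext = ".csv")
  write_results_table(res, f)
  back <- read_results_table(f)
  expect_equal(nrow(back), nrow(res))
  for (col in names(res)[vapply(res, is.numeric, TRUE)])
    expect_lt(max(abs(back[[col]] - res[[col]])), 1e-9)

  f0 <- withr::local_tempfile(fileext = ".csv")
  write_results_table(list(), f0)
  expect_length(readLines(f0), 1L)

  bad <- list(list(jump_id = "a", lv = 1), list(jump_id = "b", av = 2))
  expect_error(write_results_table(bad, f0), "heterogeneous.*record 2")
})
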