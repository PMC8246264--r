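make_traj <- function(x, y = NULL, fps = 10) {
  if (is.null(y)) y <- rep(9, length(x))
  trajectory(seq_along(x) - 1L, x, y, fps = fps)
}

test_that("between-frame speeds scale displacement by the frame rate", {
  tr <- make_traj(seq(0, 4, by = 0.4))
  expect_equal(frame_speeds(tr), rep(4.0, 10))
  still <- make_traj(rep(3, 20))
  expect_true(all(frame_speeds(still) == 0))
  expect_error(frame_speeds(make_traj(1)), "2 frames")

  # rigid translation leaves speeds unchanged
  tr2 <- make_traj(seq(0, 4, by = 0.4) + 7)
  expect_equal(frame_speeds(tr2), frame_speeds(tr))

  # gap intervals yield undefined speeds
  trg <- trajectory(c(0:5, 7:10), rep(1, 10), rep(9, 10), fps = 10)
  expect_true(is.na(frame_speeds(trg)[6L]))
})

test_that("pause rule: >=20 consecutive frames, strict >1.5 cm/s breaks", {
  sp <- c(rep(4, 10), rep(0, 50), rep(4, 10))
  p <- detect_pauses(sp)
  expect_equal(nrow(p), 1L)
  expect_equal(p$n_frames, 50L)

  # 19 sub-threshold frames between fast frames: no pause
  expect_equal(nrow(detect_pauses(c(rep(4, 5), rep(0, 19), rep(4, 5)))), 0L)

  # a speed of exactly 1.5 does not break a slow run
  run <- c(rep(4, 5), rep(0.5, 10), 1.5, rep(0.5, 10), rep(4, 5))
  expect_equal(detect_pauses(run)$n_frames, 21L)

  # an NA (tracking gap) terminates a run
  gappy <- c(rep(0, 15), NA, rep(0, 15))
  expect_equal(nrow(detect_pauses(gappy)), 0L)
})

test_that("activity percentage and active speed exclude pauses", {
  sp_all_active <- rep(4, 100)
  tr <- make_traj(cumsum(c(0, sp_all_active)) / 10)
  expect_equal(percent_time_active(tr), 100)
  expect_equal(active_speed(tr), 4.0)

  still <- make_traj(rep(1, 101))
  expect_equal(percent_time_active(still), 0)
  expect_error(active_speed(still), "no active frames")

  # 4 cm/s bursts interleaved with true pauses still average 4
  seg <- data.frame(duration_s = rep(c(5, 5), 6),
                    mode = rep(c("active", "pause"), 6),
                    speed_cm_s = rep(c(4, 0), 6))
  st <- simulate_trajectory(trajectory_sim_spec(seg, seed = 40))
  expect_equal(active_speed(st$traj), 4.0, tolerance = 1e-8)
  # removing pauses never decreases the mean speed
  expect_gte(active_speed(st$traj), mean(frame_speeds(st$traj)))
})

test_that("fastest-window speed matches a brute-force scan and is monotone in window", {
  expect_equal(fastest_window_speed(rep(3, 200), 100), 3.0)
  burst <- c(rep(1, 80), rep(8, 100), rep(1, 80))
  expect_equal(fastest_window_speed(burst, 100), 8.0)
  set.seed(41)
  for (i in 1:30) {
    sp <- runif(sample(120:300, 1L), 0, 10)
    w <- sample(c(30, 50, 100), 1L)
    expect_equal(fastest_window_speed(sp, w), bf_fastest_window(sp, w))
    expect_gte(fastest_window_speed(sp, 30), fastest_window_speed(sp, 100))
  }
  expect_error(fastest_window_speed(rep(1, 50), 100), "shorter")

  # top-n-seconds mode averages the n best non-overlapping 1-s bins
  sp <- rep(c(2, 6), each = 50)
  expect_equal(fastest_window_speed(sp, mode = "top-n-seconds", n_top = 5,
                                    fps = 10), 6.0)
})

test_that("vertical position index maps bottom/mid/top to 0/50/100", {
  bottom <- make_traj(rep(1, 10), y = rep(0, 10))
  expect_equal(vertical_position_index(bottom), 0)
  mid <- make_traj(rep(1, 10), y = rep(9, 10))
  expect_equal(vertical_position_index(mid), 50)
  top <- make_traj(rep(1, 10), y = rep(18, 10))
  expect_equal(vertical_position_index(top), 100)
  expect_error(vertical_position_index(make_traj(rep(1, 3), y = rep(25, 3))),
               "calibration")
})

test_that("total distance sums segment lengths, excluding gaps", {
  expect_equal(total_distance(make_traj(rep(2, 50))), 0)
  # 3-4-5 triangle path
  tr <- trajectory(0:3, c(0, 3, 3, 0), c(0, 0, 4, 0), fps = 10)
  expect_equal(total_distance(tr), 3 + 4 + 5)
  trg <- trajectory(c(0, 1, 3), c(0, 1, 2), c(0, 0, 0), fps = 10)
  expect_equal(total_distance(trg), 1)  # distance across the gap excluded
})

test_that("pause segmentation reproduces planted modes on jitter-free data", {
  seg <- data.frame(duration_s = c(10, 4, 8, 1.5, 6),
                    mode = c("active", "pause", "active", "pause", "active"),
                    speed_cm_s = c(4, 0.3, 2.5, 0.2, 5))
  st <- simulate_trajectory(trajectory_sim_spec(seg, fps = 10, seed = 42))
  p <- detect_pauses(frame_speeds(st$traj))
  truth <- st$truth[st$truth$detectable_pause, ]
  expect_equal(nrow(p), nrow(truth))
  expect_equal(p$start_frame, truth$start_interval)
  expect_equal(p$end_frame, truth$end_interval)
})

test_that("kinematics summary bundles the five statistics coherently", {
  seg <- data.frame(duration_s = c(120, 60, 120),
                    mode = c("active", "pause", "active"),
                    speed_cm_s = c(4, 0.3, 4))
  st <- simulate_trajectory(trajectory_sim_spec(seg, seed = 43))
  ks <- kinematics_summary(st$traj)
  expect_equal(ks$percent_time_active, 80, tolerance = 0.02)
  expect_equal(ks$active_speed_cm_s, 4.0, tolerance = 1e-8)
  expect_gte(ks$fastest_speed_cm_s, ks$active_speed_cm_s - 1e-8)
  expect_true(ks$vertical_position_index >= 0 &&
                ks$vertical_position_index <= 100)
  expect_equal(ks$total_distance_cm,
               sum(seg$duration_s * seg$speed_cm_s), tolerance = 0.01)
})
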