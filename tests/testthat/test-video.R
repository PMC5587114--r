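# Synthetic video rendering and motion analytics.

# scripted ground truth: one animal walking, rearing over [t1, t2)
scripted_gt <- function(x, rear_from, rear_to, duration, x2 = NULL) {
  n <- as.integer(duration / 0.1)
  tt <- (seq_len(n) - 1L) * 0.1
  posture <- ifelse(tt >= rear_from & tt < rear_to, "rearing", "walking")
  spec <- list(list(x = x, y = 19, posture = posture))
  if (!is.null(x2)) spec <- c(spec, list(list(x = x2, y = 19)))
  make_gt(spec, duration)
}

test_that("renderer is deterministic and an empty cage is pure background", {
  gt <- scripted_gt(25, 2, 4, 6)
  cam <- camera_config(noise_sd = 2)
  a <- render_frames(gt, cam, seed = 3, n_frames = 50)
  b <- render_frames(gt, cam, seed = 3, n_frames = 50)
  expect_identical(a$frames, b$frames)
  empty <- render_frames(make_gt(list(), 10), camera_config(noise_sd = 0),
                         n_frames = 10)
  expect_equal(dim(empty$frames)[3], 10)
  for (i in 2:10)
    expect_identical(empty$frames[, , i], empty$frames[, , 1])
})

test_that("a rearing blob rises above the 8 cm line, walking stays below", {
  cam <- camera_config(noise_sd = 0)
  lr <- line_row(cam)
  gt_walk <- scripted_gt(25, 1e9, 1e9, 2)
  f1 <- render_frames(gt_walk, cam, n_frames = 1)$frames[, , 1]
  body_rows <- which(apply(f1 == cam$rat_intensity, 1, any))
  expect_true(min(body_rows) >= lr)  # below the line (larger row index)
  gt_rear <- scripted_gt(25, 0, 10, 2)
  f2 <- render_frames(gt_rear, cam, n_frames = 1)$frames[, , 1]
  body_rows2 <- which(apply(f2 == cam$rat_intensity, 1, any))
  expect_true(min(body_rows2) < lr)  # blob top above the line
})

test_that("pixel motion counts differenced pixels with set arithmetic", {
  bg <- matrix(0L, 50, 80)
  blob <- function(r0, c0) {
    m <- bg; m[r0:(r0 + 4), c0:(c0 + 4)] <- 200L; m
  }
  frames <- array(0L, dim = c(50, 80, 3))
  frames[, , 1] <- blob(10, 10)
  frames[, , 2] <- blob(10, 40)   # translated, disjoint support
  frames[, , 3] <- blob(10, 40)
  pm <- pixel_motion(frames, diff_threshold = 10)
  expect_equal(pm, c(2L * 25L, 0L))
  # adding a second moving blob never decreases the count
  frames2 <- frames
  frames2[40:44, 10:14, 2] <- 200L
  pm2 <- pixel_motion(frames2, diff_threshold = 10)
  expect_true(all(pm2 >= pm))
  # single frame -> empty series; reversal symmetry
  expect_length(pixel_motion(frames[, , 1, drop = FALSE]), 0)
  expect_equal(rev(pm), pixel_motion(frames[, , 3:1], diff_threshold = 10))
})

test_that("vertical activity segments episodes above the line only", {
  cam <- camera_config(noise_sd = 0)
  lr <- line_row(cam)
  # all motion below the line: walking animal moving along x
  n <- 100
  tt <- (seq_len(n * 4) - 1L) * 0.1
  gt_move <- make_gt(list(list(x = 15 + 5 * sin(tt / 3), y = 19)), n * 4 * 0.1)
  fs <- render_frames(gt_move, cam, n_frames = n)
  expect_equal(nrow(vertical_activity(fs, lr)), 0)
  # one rearing bout of 50 frames -> exactly one episode spanning it
  gt_rear <- scripted_gt(25, 1.0, 3.0, 5)
  fs2 <- render_frames(gt_rear, cam, n_frames = 120)
  ep <- vertical_activity(fs2, lr)
  expect_equal(nrow(ep), 1)
  expect_lte(ep$start_frame, 27)   # bout starts at frame 26
  expect_gte(ep$end_frame, 74)     # and ends at frame 76
  # two bouts separated by quiet frames -> two episodes
  gt2 <- scripted_gt(25, 1.0, 2.0, 6)
  gt2$posture[gt2$t >= 4 & gt2$t < 5] <- "rearing"
  fs3 <- render_frames(gt2, cam, n_frames = 149)
  expect_equal(nrow(vertical_activity(fs3, lr)), 2)
})

test_that("episode identity goes to the nearest track, ties unassigned", {
  arr <- antenna_array()
  cam <- camera_config(noise_sd = 0)
  mk_track <- function(id, x) data.table::data.table(
    t = seq(0, 10, by = 1.08), animal_id = id, antenna = 1L, x = x, y = 19,
    source = "read")
  ep <- data.table::data.table(start_frame = 10L, end_frame = 60L,
                               peak_row = 100L,
                               centroid_col = cam$x_origin_px + 25 / cam$cm_per_px,
                               animal_id = NA_character_)
  times <- (0:199) / cam$fps
  one <- assign_episode_identity(ep, mk_track("r1", 20), cam, times)
  expect_equal(one$animal_id, "r1")
  two <- assign_episode_identity(ep, rbind(mk_track("r1", 20),
                                           mk_track("r2", 30)), cam, times)
  expect_true(is.na(two$animal_id))  # equidistant -> unassigned
  near <- assign_episode_identity(ep, rbind(mk_track("r1", 24),
                                            mk_track("r2", 40)), cam, times)
  expect_equal(near$animal_id, "r1")
})

test_that("three separated rearing animals are all assigned correctly", {
  cam <- camera_config(noise_sd = 0)
  lr <- line_row(cam)
  # animals at x = 8, 25, 42; each rears in its own window
  n <- as.integer(9 / 0.1)
  tt <- (seq_len(n) - 1L) * 0.1
  posture_for <- function(a, b) ifelse(tt >= a & tt < b, "rearing", "walking")
  gt <- make_gt(list(
    list(x = 8, y = 19, posture = posture_for(1, 2)),
    list(x = 25, y = 19, posture = posture_for(4, 5)),
    list(x = 42, y = 19, posture = posture_for(7, 8))), 9)
  fs <- render_frames(gt, cam, n_frames = 220)
  ep <- vertical_activity(fs, lr)
  expect_equal(nrow(ep), 3)
  track <- data.table::rbindlist(lapply(
    list(c("rat01", 8), c("rat02", 25), c("rat03", 42)),
    function(z) data.table::data.table(t = seq(0, 9, by = 1.08),
                                       animal_id = z[1], antenna = 1L,
                                       x = as.numeric(z[2]), y = 19,
                                       source = "read")))
  got <- assign_episode_identity(ep, track, cam, fs$times)
  expect_equal(got$animal_id, c("rat01", "rat02", "rat03"))
})

test_that("frame accuracy is percent agreement", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(frame_accuracy(a, a), 100)
  expect_equal(frame_accuracy(a, !a), 0)
  expect_equal(frame_accuracy(a, c(TRUE, TRUE, TRUE, TRUE)), 50)
  expect_error(frame_accuracy(a, a[1:3]), "equal length")
})
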