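test_that("routine generation respects probabilities and determinism", {
  cfg0 <- synthetic_config(n_stimuli = 20, p_mistake = 0, p_miss = 0)
  r <- generate_routine(cfg0, seed = 4)
  expect_equal(nrow(r), 20L)
  expect_true(all(r$outcome == "POSITIVE"))
  expect_true(all(r$expected_target %in% c(1:4, 6:9)))
  expect_true(all(r$actual_target == r$expected_target))

  cfg <- synthetic_config()
  expect_identical(generate_routine(cfg, seed = 9),
                   generate_routine(cfg, seed = 9))
  # mistaken plays land in a different peripheral region
  r2 <- generate_routine(synthetic_config(n_stimuli = 200, p_mistake = 0.5),
                         seed = 5)
  mis <- r2[r2$outcome == "MISTAKEN", ]
  expect_gt(nrow(mis), 0)
  expect_true(all(mis$actual_target != mis$expected_target))
  expect_true(all(mis$actual_target %in% c(1:4, 6:9)))
  expect_error(synthetic_config(p_mistake = 0.7, p_miss = 0.5), "probabilities")
})

test_that("nine routines of twenty stimuli script 180 events", {
  total <- sum(vapply(1:9, function(s)
    nrow(generate_routine(synthetic_config(), seed = s)), integer(1)))
  expect_identical(total, 180L)
})

test_that("trajectories honour the scripted landings and contact windows", {
  cfg <- synthetic_config(n_stimuli = 12, p_mistake = 0.2, p_miss = 0.25,
                          seed = 31)
  routine <- generate_routine(cfg, seed = 31)
  gt <- generate_trajectory(routine, cfg)
  pm <- build_platform()
  expect_true(any(routine$outcome == "MISSED"))

  # scripted target landings fall inside their contact regions
  tev <- gt$events[!gt$events$is_center, ]
  expect_equal(nrow(tev), sum(routine$outcome != "MISSED"))
  for (i in seq_len(nrow(tev))) {
    d <- sqrt(sum((c(tev$X[i], tev$Y[i]) -
                     pm$centers[as.character(tev$target[i]), ])^2))
    expect_lt(d, 0.30)
  }
  # missed plays land 30-45 cm from the intended centre, touching no region
  for (i in which(routine$outcome == "MISSED")) {
    expect_false(any(gt$events$play == i & !gt$events$is_center))
  }
  # every scripted CONTACT run lasts 2-4 frames with a frozen position
  for (side in c("left", "right")) {
    ph <- gt$phase[[side]]
    runs <- rle(!is.na(ph) & ph == "CONTACT")
    lens <- runs$lengths[runs$values]
    expect_true(all(lens >= 2 & lens <= 4))
    idx <- which(!is.na(ph) & ph == "CONTACT")
    pos <- gt$foot[[side]][idx, 1:2, drop = FALSE]
    expect_true(all(gt$foot[[side]][idx, 3] == 0))
  }
  # all foot positions stay within the platform surroundings
  for (side in c("left", "right")) {
    xy <- gt$foot[[side]][, 1:2]
    xy <- xy[!is.na(xy[, 1]), ]
    expect_true(all(abs(xy) <= 2.8))
  }
  # one outcome per stimulus, chronological presentations
  expect_false(is.unsorted(gt$routine$presentation_frame))
})

test_that("feet on the ground plane render at their projected pixels", {
  cfg <- synthetic_config(n_stimuli = 1, seed = 8)
  gt <- generate_trajectory(generate_routine(cfg, seed = 8), cfg)
  fs <- frame_stream(gt, noise = FALSE)
  cam <- fs$camera
  # place the left foot exactly on the platform origin for one frame
  i <- cfg$warmup_frames + 2
  gt$foot$left[i + 1, ] <- c(0, 0, 0)
  fs2 <- frame_stream(gt, noise = FALSE)
  mask <- fs2$mask(i)
  p5 <- project_points(cam, c(0, 0, 0))
  # foreground present within one pixel of the projected contact point
  nb <- mask[round(p5[1, 2]) + 1 + (-1:1), round(p5[1, 1]) + 1 + (-1:1)]
  expect_true(any(nb))
  # the foot blob's bottom-centre agrees with the projection
  rows <- (round(p5[1, 2]) - 10):(round(p5[1, 2]) + 3)
  cols <- (round(p5[1, 1]) - 12):(round(p5[1, 1]) + 12)
  sub <- mask[rows + 1, cols + 1]
  bottom <- max(which(apply(sub, 1, any)))
  xc <- mean(range(which(sub[bottom, ])))
  expect_lt(abs((rows[1] + bottom - 1) - p5[1, 2]), 2)
  expect_lt(abs((cols[1] + xc - 1) - p5[1, 1]), 1.5)
})

test_that("rendering is deterministic and noise-free frames are clean", {
  cfg <- synthetic_config(n_stimuli = 1, seed = 13)
  gt <- generate_trajectory(generate_routine(cfg, seed = 13), cfg)
  a <- frame_stream(gt, noise = TRUE)
  b <- frame_stream(gt, noise = TRUE)
  i <- cfg$warmup_frames + 5
  expect_identical(a$frame(i), b$frame(i))
  expect_identical(a$frame(0), b$frame(0))

  # zero noise: frame differencing against the background recovers
  # exactly the ground-truth mask support
  fs <- frame_stream(gt, noise = FALSE)
  diffmask <- abs(fs$frame(i) - fs$background) > 1e-9
  expect_identical(unname(diffmask), unname(as.matrix(fs$mask(i))))
})

test_that("written sessions contain frames, truth, routine, calibration", {
  cfg <- synthetic_config(n_stimuli = 1, seed = 2)
  gt <- generate_trajectory(generate_routine(cfg, seed = 2), cfg)
  d <- withr::local_tempdir()
  write_synthetic_session(gt, d, noise = FALSE, frames = 0:3)
  expect_length(list.files(d, pattern = "frame_.*png"), 4L)
  expect_true(file.exists(file.path(d, "ground_truth.csv")))
  r2 <- read_routine(file.path(d, "routine.yaml"))
  expect_equal(r2$expected_target, gt$routine$expected_target)
  h <- calibrate_from_file(file.path(d, "calibration.csv"))
  expect_lt(h$residual, 1e-6)
  # frames read back as grayscale matrices usable by the detector
  fr <- png::readPNG(list.files(d, pattern = "png$", full.names = TRUE)[1])
  expect_equal(dim(fr), c(480, 640))
})

test_that("self-occlusion is flagged exactly when foot boxes overlap", {
  # crossing fixture: right foot slides horizontally across the left
  cfg <- synthetic_config(n_stimuli = 1, seed = 6)
  gt <- generate_trajectory(generate_routine(cfg, seed = 6), cfg)
  cam <- synthetic_camera(cfg)
  dc <- agility_config()
  overlap_frac <- function(xl, xr) {
    # foot ellipses approx 0.18 m wide on the ground
    w <- 0.18
    inter <- max(0, min(xl + w / 2, xr + w / 2) - max(xl - w / 2, xr - w / 2))
    inter / w
  }
  labels <- character(0); gt_occ <- logical(0)
  for (xr in seq(0.45, -0.05, by = -0.05)) {
    gt$foot$left[cfg$warmup_frames + 3, ] <- c(0, 0, 0)
    gt$foot$right[cfg$warmup_frames + 3, ] <- c(xr, 0, 0)
    gt$body[cfg$warmup_frames + 3, ] <- c(xr / 2, 0)
    fs <- frame_stream(gt, noise = FALSE)
    mask <- fs$mask(cfg$warmup_frames + 2)
    roi <- extract_feet_roi(mask, min_area = 50)
    obs <- discriminate_feet(mask, roi$feet, dc$min_foot_area)
    labels <- c(labels, obs$mode)
    gt_occ <- c(gt_occ, overlap_frac(0, xr) > 0.5)
  }
  expect_true(all(labels[gt_occ] == "OCCLUDED"))
  expect_true(all(labels[!gt_occ & abs(seq(0.45, -0.05, by = -0.05)) > 0.25]
                  == "SEPARATED"))
})
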