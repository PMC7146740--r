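# small frames keep the background-model tests fast
seg_cfg <- function(w = 160, h = 120) agility_config(w, h, 20)

test_that("a static scene yields an empty foreground mask", {
  set.seed(1)
  w <- 160; h <- 120
  frame <- matrix(runif(h * w, 0.3, 0.7), h, w)
  bg <- background_model(w, h, seg_cfg(), init_frame = frame)
  for (i in 1:50) m <- update_background(bg, frame)
  expect_equal(sum(m), 0L)
  expect_error(update_background(bg, matrix(0, 10, 10)), "dimensions")
  expect_error(update_background(bg, frame, learning_rate = 2), "learning")
})

test_that("an inserted blob is segmented with IoU >= 0.8", {
  set.seed(2)
  w <- 160; h <- 120
  base <- matrix(runif(h * w, 0.35, 0.6), h, w)
  bg <- background_model(w, h, seg_cfg(), init_frame = base)
  for (i in 1:50) update_background(bg, base + matrix(rnorm(h * w, 0, 0.01), h, w))
  gt <- matrix(FALSE, h, w)
  gt[30:109, 60:99] <- TRUE                    # 40 x 80 blob
  frame <- base
  frame[gt] <- 0.9
  m <- update_background(bg, frame)
  iou <- sum(m & gt) / sum(m | gt)
  expect_gte(iou, 0.8)
})

test_that("pixels outside the scenario mask are always background", {
  set.seed(3)
  w <- 160; h <- 120
  base <- matrix(0.5, h, w)
  bg <- background_model(w, h, seg_cfg(), init_frame = base)
  scen <- matrix(FALSE, h, w); scen[, 41:120] <- TRUE
  frame <- base
  frame[50:70, 10:30] <- 0.95                  # object outside the scenario
  frame[50:70, 60:80] <- 0.95                  # object inside
  m <- update_background(bg, frame, scenario_mask = scen)
  expect_true(all(!m[, 1:40]))
  expect_gt(sum(m[, 41:120]), 0)
})

test_that("feet box is the bottom 20% of the silhouette box", {
  m <- matrix(FALSE, 200, 100)
  m[41:140, 31:60] <- TRUE                     # silhouette 100 px tall
  roi <- extract_feet_roi(m, min_area = 10)
  expect_equal(unname(roi$silhouette), c(30, 40, 30, 100))
  expect_equal(unname(roi$feet), c(30, 120, 30, 20))  # bottom-aligned slab
  # area relation: feet box area <= 0.2 * silhouette area + one row
  expect_lte(roi$feet["w"] * roi$feet["h"],
             0.2 * roi$silhouette["w"] * roi$silhouette["h"] +
               roi$silhouette["w"])
  expect_equal(extract_feet_roi(matrix(FALSE, 50, 50)),
               list(silhouette = NULL, feet = NULL))
})

test_that("feet discrimination separates, merges and reports absence", {
  m <- matrix(FALSE, 400, 400)
  # two disjoint 10 x 15 blobs with x-centres 100 and 140
  m[301:315, 96:105] <- TRUE
  m[301:315, 136:145] <- TRUE
  fb <- c(x = 80, y = 295, w = 100, h = 25)
  obs <- discriminate_feet(m, fb, min_foot_area = 12)
  expect_equal(obs$mode, "SEPARATED")
  expect_equal(unname(obs$left["x"] + obs$left["w"] / 2), 100)
  expect_equal(unname(obs$right["x"] + obs$right["w"] / 2), 140)

  # one 30 x 15 blob: self-occlusion
  m2 <- matrix(FALSE, 400, 400)
  m2[301:315, 91:120] <- TRUE
  obs2 <- discriminate_feet(m2, fb, min_foot_area = 12)
  expect_equal(obs2$mode, "OCCLUDED")
  expect_equal(unname(obs2$merged), c(90, 300, 30, 15))

  expect_equal(discriminate_feet(matrix(FALSE, 400, 400), fb)$mode, "ABSENT")
})

test_that("measurements are box bottom-centres; occlusion splits in half", {
  obs <- list(mode = "SEPARATED",
              left = c(x = 95, y = 300, w = 10, h = 15),
              right = c(x = 136, y = 301, w = 10, h = 14))
  z <- measure_feet(obs)
  expect_equal(z$left, c(100, 315, 10, 15))
  expect_equal(z$right, c(141, 315, 10, 14))

  occ <- list(mode = "OCCLUDED", merged = c(x = 90, y = 300, w = 30, h = 15))
  z2 <- measure_feet(occ)
  expect_equal(z2$left, c(97.5, 315, 15, 15))
  expect_equal(z2$right, c(112.5, 315, 15, 15))

  expect_null(measure_feet(list(mode = "ABSENT")))
})

test_that("binary morphology matches a naive oracle on random masks", {
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(runif(40 * 30) < 0.4, 30, 40)
    expect_identical(bin_open(m, 3), naive_open(m, 3))
    expect_identical(bin_close(m, 5), naive_close(m, 5))
  }
})

test_that("connected components agree with an independent labeller", {
  set.seed(10)
  for (rep in 1:5) {
    m <- matrix(runif(60 * 50) < 0.3, 50, 60)
    res <- mask_components(m, 1)
    # oracle: EBImage connected-component labelling
    lab <- EBImage::bwlabel(m * 1)
    areas <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
    # EBImage labels 8-connected sets; compare against 4-connected by
    # checking on a mask without diagonal adjacencies
    m2 <- bin_open(m, 3)   # opened masks have no diagonal-only links
    res2 <- mask_components(m2, 1)
    lab2 <- EBImage::bwlabel(m2 * 1)
    areas2 <- sort(tabulate(lab2[lab2 > 0]), decreasing = TRUE)
    expect_equal(as.numeric(res2$stats[, "area"]),
                 as.numeric(areas2[areas2 >= 1]))
    expect_identical(res2$mask, m2)     # min_area 1 keeps every pixel
  }
})

test_that("scenario mask from the platform covers the player columns", {
  cam <- test_camera()
  h <- camera_homography(cam)
  pm <- build_platform()
  sm <- scenario_mask_from_platform(h, pm, cam$width, cam$height)
  # all nine target centre pixels lie inside the mask
  px <- project_points(cam, cbind(pm$centers, 0))
  for (i in 1:9)
    expect_true(sm[round(px[i, 2]) + 1, round(px[i, 1]) + 1])
  # image corners lie outside
  expect_false(sm[cam$height, 1])
  expect_false(sm[cam$height, cam$width])
})
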