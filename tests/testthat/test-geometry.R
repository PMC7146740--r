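test_that("platform grid geometry and numbering are correct", {
  pm <- build_platform(2.0, 0.30)
  expect_identical(unname(pm$centers["5", ]), c(0, 0))
  # adjacent centres two metres apart
  expect_equal(sqrt(sum((pm$centers["4", ] - pm$centers["5", ])^2)), 2.0)
  expect_equal(sqrt(sum((pm$centers["2", ] - pm$centers["5", ])^2)), 2.0)
  # numbering: 1-3 nearest the camera (+Y), 7-9 farthest
  expect_true(all(pm$centers[c("1", "2", "3"), "y"] == 2))
  expect_true(all(pm$centers[c("7", "8", "9"), "y"] == -2))
  expect_lt(pm$centers["1", "x"], pm$centers["3", "x"])
  # all 36 pairs at distance >= spacing, so 30 cm contact disks are disjoint
  d <- as.matrix(dist(pm$centers))
  expect_true(all(d[upper.tri(d)] >= 2.0))
  expect_true(all(d[upper.tri(d)] > 2 * pm$contact_radius))
})

test_that("invalid platform parameters are rejected", {
  expect_error(build_platform(0, 0.3), "spacing")
  expect_error(build_platform(2, -1), "contact_radius")
})

test_that("contact-region matching uses a strict 30 cm rule", {
  pm <- build_platform()
  expect_equal(match_target(pm, c(0, 0)), list(target = 5L, distance = 0))
  # 0.29 m from centre 3 (at (2, 2)): inside
  m <- match_target(pm, c(2, 2 - 0.29))
  expect_identical(m$target, 3L)
  expect_equal(m$distance, 0.29)
  # 0.31 m away from the nearest centre: no match, distance still reported
  m <- match_target(pm, c(2, 2 - 0.31))
  expect_true(is.na(m$target))
  expect_equal(m$distance, 0.31)
  # exactly at threshold: exclusive
  expect_true(is.na(match_target(pm, c(2, 2 - 0.30))$target))
  # midpoint between adjacent centres is 1 m from each, outside any disk
  expect_equal(match_target(pm, c(1, 2))$distance, 1)
})

test_that("homography estimation recovers exact maps", {
  # identity from 4 points with pixel == platform coordinates
  pts <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10), c(3, 7))
  h <- estimate_homography(pts, pts)
  expect_equal(h$H, diag(3), tolerance = 1e-9)
  expect_equal(unname(pixel_to_platform(h, c(3, 7))), c(3, 7),
               tolerance = 1e-9)

  # re-estimate the synthetic ground-plane homography from the 9 targets
  cam <- test_camera()
  pm <- build_platform()
  calib <- true_calibration(cam, pm)
  h2 <- estimate_homography(as.matrix(calib[, 1:2]), as.matrix(calib[, 3:4]))
  h_true <- camera_homography(cam)
  expect_lt(max(abs(h2$H - h_true$H)), 1e-6)
  expect_lt(h2$residual, 1e-6)

  # round trip of the 9 target centres through the estimated calibration
  px <- platform_to_pixel(h2, pm$centers)
  back <- pixel_to_platform(h2, px)
  expect_lt(max(abs(back - pm$centers)), 1e-6)
})

test_that("homography round trips and degenerate inputs error", {
  cam <- test_camera()
  h <- camera_homography(cam)
  set.seed(42)
  pts <- cbind(runif(100, 0, 639), runif(100, 0, 400))
  back <- platform_to_pixel(h, pixel_to_platform(h, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  # the exact pixel of target 5 maps to the platform origin
  p5 <- project_points(cam, c(0, 0, 0))
  expect_lt(max(abs(pixel_to_platform(h, p5[1, 1:2]))), 1e-6)

  expect_error(estimate_homography(matrix(1:6, 3, 2), matrix(1:6, 3, 2)),
               "at least 4")
  coll <- cbind(1:5, 2 * (1:5))          # all collinear
  expect_error(estimate_homography(coll, coll), "degenerate")
})

test_that("homography estimation is scale-equivariant in the inputs", {
  cam <- test_camera()
  pm <- build_platform()
  calib <- true_calibration(cam, pm)
  px <- as.matrix(calib[, 1:2]); pl <- as.matrix(calib[, 3:4])
  h1 <- estimate_homography(px, pl)
  h2 <- estimate_homography(px * 3, pl)
  # mapping scaled pixels through h2 equals mapping originals through h1
  expect_equal(pixel_to_platform(h2, px[4, ] * 3),
               pixel_to_platform(h1, px[4, ]), tolerance = 1e-8)
})

test_that("target-region pixel polygons gate the contact disks", {
  pm <- build_platform()
  hid <- homography(diag(3))
  polys <- target_regions_pixels(hid, pm, n_vertices = 16)
  expect_length(polys, 9)
  # under identity, target 5's polygon is the metric circle itself
  p5 <- polys[["5"]]
  expect_equal(max(p5[, 1]) - min(p5[, 1]), 2 * pm$contact_radius,
               tolerance = 1e-9)
  expect_lt(max(abs(sqrt(rowSums(p5^2)) - pm$contact_radius)), 1e-9)

  # through the camera: every vertex maps back onto its own circle,
  # and polygons of different targets stay disjoint
  h <- camera_homography(test_camera())
  polys <- target_regions_pixels(h, pm, n_vertices = 24)
  for (t in names(polys)) {
    back <- pixel_to_platform(h, polys[[t]])
    d <- sqrt(rowSums(sweep(back, 2, pm$centers[t, ])^2))
    expect_lt(max(abs(d - pm$contact_radius)), 1e-6)
  }
  for (t1 in 1:8) for (t2 in (t1 + 1):9) {
    b1 <- pixel_to_platform(h, polys[[as.character(t1)]])
    ctr2 <- pm$centers[as.character(t2), ]
    expect_true(all(sqrt(rowSums(sweep(b1, 2, ctr2)^2)) > pm$contact_radius))
  }
})

test_that("platform and calibration files round trip", {
  pm <- build_platform(2.0, 0.25)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_platform(pm, f)
  pm2 <- read_platform(f)
  expect_equal(pm2$centers, pm$centers)
  expect_equal(pm2$contact_radius, 0.25)

  cam <- test_camera()
  calib <- true_calibration(cam)
  g <- withr::local_tempfile(fileext = ".csv")
  write_calibration(calib, g)
  h <- calibrate_from_file(g)
  expect_lt(max(abs(h$H - camera_homography(cam)$H)), 1e-6)
})
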