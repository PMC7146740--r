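mk_routine <- function(expected, pres) {
  data.frame(index = seq_along(expected),
             role = rep("DEFENSIVE", length(expected)),
             expected_target = as.integer(expected),
             presentation_frame = as.integer(pres),
             stringsAsFactors = FALSE)
}
mk_events <- function(frame, target, dist = 0.1, foot = "right", fps = 20) {
  data.frame(foot = foot, frame = as.integer(frame), time = frame / fps,
             px = 0, py = 0, X = 0, Y = 0,
             target = as.integer(target), distance = dist,
             stringsAsFactors = FALSE)
}

test_that("event classification follows the matching taxonomy", {
  expect_equal(classify_event(3, 3), "POSITIVE")
  expect_equal(classify_event(6, 2), "MISTAKEN")
  expect_equal(classify_event(7, NA), "IGNORED")
  expect_equal(classify_event(7, 5), "IGNORED")
  expect_error(classify_event(5, 3))
})

test_that("a correct response resolves with its response time", {
  # stimulus at frame 200 (t = 10 s), correct step at frame 247 (12.35 s)
  routine <- mk_routine(3, 200)
  ev <- mk_events(247, 3)
  s <- score_session(routine, ev, fps = 20)
  expect_equal(s$plays$kind, "POSITIVE")
  expect_equal(s$plays$response_time, 2.35)
  expect_true(s$plays$correct)
})

test_that("a near-miss registers MISSED at the centre return", {
  # expected 7; a step 0.40 m from it (no match), then back to centre
  routine <- mk_routine(7, 100)
  ev <- rbind(mk_events(130, NA, dist = 0.40),
              mk_events(170, 5, dist = 0.05))
  s <- score_session(routine, ev, fps = 20)
  expect_equal(s$plays$kind, "MISSED")
  expect_false(s$plays$correct)
  expect_equal(s$plays$resolve_frame, 170L)
})

test_that("a centre match before the player moves does not resolve", {
  routine <- mk_routine(c(4, 6), c(100, 260))
  ev <- rbind(
    mk_events(104, 5),            # still standing when stimulus appears
    mk_events(140, NA, 0.8),      # sprint footstep
    mk_events(160, 4),            # reaches the target: positive
    mk_events(205, 5),            # centre return (play already resolved)
    mk_events(262, 5),            # standing again at next presentation
    mk_events(300, NA, 0.9),
    mk_events(320, 5))            # back at centre with no target: missed
  s <- score_session(routine, ev, fps = 20)
  expect_equal(s$plays$kind, c("POSITIVE", "MISSED"))
  expect_equal(s$plays$resolve_frame, c(160L, 320L))
})

test_that("wrong-target steps resolve as mistaken; counts partition plays", {
  routine <- mk_routine(c(6, 2, 8), c(10, 100, 200))
  ev <- rbind(mk_events(40, 2),             # mistaken (expected 6)
              mk_events(120, NA, 0.5),
              mk_events(130, 2),            # positive
              mk_events(230, NA, 0.6),
              mk_events(250, 5))            # missed
  s <- score_session(routine, ev, fps = 20)
  expect_equal(s$plays$kind, c("MISTAKEN", "POSITIVE", "MISSED"))
  k <- table(factor(s$plays$kind,
                    c("POSITIVE", "MISTAKEN", "MISSED", "PENDING")))
  expect_equal(sum(k), nrow(routine))
  expect_true(all(s$plays$response_time >= 0, na.rm = TRUE))
})

test_that("simultaneous events resolve toward the smaller distance", {
  routine <- mk_routine(4, 10)
  ev <- rbind(mk_events(40, 6, dist = 0.2, foot = "left"),
              mk_events(40, 4, dist = 0.1, foot = "right"))
  s <- score_session(routine, ev, fps = 20)
  expect_equal(s$plays$kind, "POSITIVE")   # nearer match wins the frame
})

test_that("scoring ground-truth events reproduces the script exactly", {
  # feed the generator's own event log through the session logic
  for (sd in c(21, 22)) {
    cfg <- synthetic_config(n_stimuli = 20, seed = sd)
    routine <- generate_routine(cfg, seed = sd)
    gt <- generate_trajectory(routine, cfg)
    pm <- build_platform()
    ev <- gt$events
    mt <- t(vapply(seq_len(nrow(ev)),
                   function(i) {
                     m <- match_target(pm, c(ev$X[i], ev$Y[i]))
                     c(m$target, m$distance)
                   }, numeric(2)))
    events <- data.frame(foot = ev$foot, frame = ev$frame,
                         time = ev$frame / cfg$fps, px = NA, py = NA,
                         X = ev$X, Y = ev$Y, target = mt[, 1],
                         distance = mt[, 2], stringsAsFactors = FALSE)
    # the ground-truth log keeps only contact-region events; a real step
    # stream also carries the sprint footsteps, which engage the play —
    # add one out-of-region footstep after each presentation
    sprint <- data.frame(foot = "left",
                         frame = gt$routine$presentation_frame + 12L,
                         time = (gt$routine$presentation_frame + 12) / cfg$fps,
                         px = NA, py = NA, X = 1.0, Y = 1.0,
                         target = NA_integer_, distance = 0.6,
                         stringsAsFactors = FALSE)
    s <- score_session(gt$routine, rbind(events, sprint), fps = cfg$fps)
    expect_equal(s$plays$kind, gt$routine$outcome)
    pos <- s$plays$kind == "POSITIVE"
    expect_true(all(s$plays$response_time[pos] > 0))
  }
})

test_that("routine files round trip and invalid routines are rejected", {
  routine <- mk_routine(c(3, 7, 2), c(50, 150, 260))
  routine$role <- c("DEFENSIVE", "OFFENSIVE", "DEFENSIVE")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_routine(routine, f)
  expect_equal(read_routine(f), routine)
  bad <- routine; bad$expected_target[2] <- 5L
  expect_error(write_routine(bad, f), "peripheral")
  bad2 <- routine; bad2$presentation_frame <- c(260L, 150L, 50L)
  expect_error(write_routine(bad2, f), "chronological")
})
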