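#' Configuration of the synthetic session generator
#'
#' Describes the simulated recording conditions: a single player on the
#' 3 x 3 platform (2 m spacing), sprinting centre -> target -> centre in
#' response to each stimulus, footsteps static for a few frames at every
#' ground contact, viewed by a fixed camera in front of the platform.  The
#' defaults reproduce the reference recording conditions: 20 fps, 640 x 480,
#' 20 stimuli per routine, camera 6.5 m in front of the central target and
#' 3.5 m high.
#'
#' @param fps Frames per second (default 20).
#' @param frame_size `c(width, height)` in pixels (default 640 x 480).
#' @param n_stimuli Stimuli (plays) per routine (default 20).
#' @param p_mistake Probability a play is scripted as reaching a wrong
#'   target (default 0.1).
#' @param p_miss Probability a play is scripted as a near-target overshoot
#'   that reaches no target (default 0.08, so negative plays stay below
#'   roughly 8% of events).
#' @param noise List: `illumination_drift_amp` (relative amplitude of the
#'   slow sinusoidal global gain, default 0.10), `drift_period_s` (default
#'   30), `n_shadow_blobs` (drifting soft shadows, default 2),
#'   `shadow_depth` (peak relative darkening, default 0.10),
#'   `salt_pepper_rate` (default 0.001), `sensor_sd` (additive Gaussian
#'   noise, default 0.015).
#' @param camera List: `distance` (m in front of target 5, default 6.5),
#'   `height` (m, default 3.5), `focal_px` (pinhole focal length in pixels,
#'   default 600).
#' @param contact_frames Frames a foot stays frozen at a ground contact
#'   (2--4, default 3).
#' @param warmup_frames Background-only frames before the player walks in
#'   (default 50).
#' @param seed Base seed for reproducibility.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(fps = 20, frame_size = c(640, 480),
                             n_stimuli = 20, p_mistake = 0.1, p_miss = 0.08,
                             noise = list(), camera = list(),
                             contact_frames = 3, warmup_frames = 50,
                             seed = 1) {
  stopifnot(fps > 0, length(frame_size) == 2, all(frame_size >= 64),
            n_stimuli >= 1, contact_frames %in% 2:4, warmup_frames >= 0)
  if (p_mistake < 0 || p_miss < 0 || p_mistake + p_miss > 1)
    stop("outcome probabilities must be in [0,1] with p_mistake + p_miss <= 1")
  ndef <- list(illumination_drift_amp = 0.10, drift_period_s = 30,
               n_shadow_blobs = 2, shadow_depth = 0.10,
               salt_pepper_rate = 0.001, sensor_sd = 0.015)
  for (nm in names(noise)) ndef[[nm]] <- noise[[nm]]
  cdef <- list(distance = 6.5, height = 3.5, focal_px = 600)
  for (nm in names(camera)) cdef[[nm]] <- camera[[nm]]
  structure(
    list(fps = fps, frame_size = as.integer(frame_size),
         n_stimuli = as.integer(n_stimuli),
         p_mistake = p_mistake, p_miss = p_miss,
         noise = ndef, camera = cdef,
         contact_frames = as.integer(contact_frames),
         warmup_frames = as.integer(warmup_frames), seed = seed),
    class = "synthetic_config"
  )
}

# run code under a temporary RNG state (restores the caller's stream)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Pinhole camera viewing the platform
#'
#' Builds the projection of a camera placed `distance` metres in front of
#' the central target (along +Y) at the given height, aimed at the platform
#' origin.  Platform +X appears toward increasing pixel column and points
#' nearer the camera toward increasing row.
#'
#' @param cfg A `synthetic_config` (or a list with `camera` and
#'   `frame_size` fields).
#' @return List of class `synthetic_camera`: `P` (3 x 4 projection from
#'   platform `(X, Y, Z)`), `C` (camera position), `focal`, `width`,
#'   `height`.
#' @export
synthetic_camera <- function(cfg = synthetic_config()) {
  d <- cfg$camera$distance; hc <- cfg$camera$height
  focal <- cfg$camera$focal_px
  w <- cfg$frame_size[1]; h <- cfg$frame_size[2]
  C <- c(0, d, hc)
  fwd <- -C / sqrt(sum(C^2))             # camera looks at the origin
  right <- c(1, 0, 0)                    # platform +X -> image right
  down <- c(0, hc, -d) / sqrt(hc^2 + d^2)
  R <- rbind(right, down, fwd)
  K <- matrix(c(focal, 0, (w - 1) / 2,
                0, focal, (h - 1) / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  P <- K %*% cbind(R, -R %*% C)
  structure(list(P = P, C = C, focal = focal, width = w, height = h),
            class = "synthetic_camera")
}

#' Project platform-frame 3D points to pixels
#'
#' @param cam A `synthetic_camera`.
#' @param pts n x 3 matrix of `(X, Y, Z)` platform points (metres; Z up).
#' @return n x 3 matrix: pixel `x` (column), `y` (row), `depth` (metres
#'   along the optical axis; pixel scale is `focal / depth` px per metre).
#' @export
project_points <- function(cam, pts) {
  pts <- if (is.null(dim(pts))) matrix(pts, ncol = 3) else as.matrix(pts)
  ph <- cbind(pts, 1) %*% t(cam$P)
  cbind(x = ph[, 1] / ph[, 3], y = ph[, 2] / ph[, 3], depth = ph[, 3])
}

#' Ground-plane homography of a synthetic camera
#'
#' Restriction of the camera projection to the floor plane `Z = 0`,
#' inverted to give the pixel-to-platform calibration homography the
#' detector needs.
#'
#' @param cam A `synthetic_camera`.
#' @return A `homography` (pixel to platform).
#' @export
camera_homography <- function(cam) {
  Hpp <- cam$P[, c(1, 2, 4)]          # platform (X, Y, 1) -> pixel
  homography(solve(Hpp))
}

#' True calibration correspondences for a synthetic camera
#'
#' The nine target centres with their exact pixel projections: the
#' calibration file a synthetic session ships with.
#'
#' @param cam A `synthetic_camera`.
#' @param pm A `platform_model`.
#' @return Data frame with `pixel_x`, `pixel_y`, `platform_x`, `platform_y`.
#' @export
true_calibration <- function(cam, pm = build_platform()) {
  px <- project_points(cam, cbind(pm$centers, 0))
  data.frame(pixel_x = px[, 1], pixel_y = px[, 2],
             platform_x = pm$centers[, 1], platform_y = pm$centers[, 2])
}

#' Generate a random stimulus routine with scripted outcomes
#'
#' Draws `n_stimuli` stimuli with uniformly distributed peripheral expected
#' targets and random roles, and scripts each play's outcome: `POSITIVE`
#' (the player will land inside the expected target's contact region),
#' `MISTAKEN` (lands inside a wrong peripheral target's region) or `MISSED`
#' (overshoots the intended target by 30--45 cm, reaching no region), with
#' probabilities `1 - p_mistake - p_miss`, `p_mistake`, `p_miss`.
#'
#' @param cfg A `synthetic_config`.
#' @param seed Seed (defaults to `cfg$seed`); identical seeds give
#'   identical routines.
#' @return Data frame: `index`, `role`, `expected_target`, `outcome`,
#'   `actual_target` (the target region actually landed in, `NA` for
#'   `MISSED`), `presentation_frame` (`NA` until the trajectory is
#'   generated).  The seed is stored as attribute `"seed"`.
#' @export
generate_routine <- function(cfg = synthetic_config(), seed = cfg$seed) {
  periph <- c(1:4, 6:9)
  with_seed(seed, {
    n <- cfg$n_stimuli
    expected <- sample(periph, n, replace = TRUE)
    role <- sample(c("DEFENSIVE", "OFFENSIVE"), n, replace = TRUE)
    outcome <- sample(c("POSITIVE", "MISTAKEN", "MISSED"), n, replace = TRUE,
                      prob = c(1 - cfg$p_mistake - cfg$p_miss,
                               cfg$p_mistake, cfg$p_miss))
    actual <- expected
    for (i in which(outcome == "MISTAKEN"))
      actual[i] <- sample(setdiff(periph, expected[i]), 1)
    actual[outcome == "MISSED"] <- NA_integer_
    routine <- data.frame(
      index = seq_len(n), role = role,
      expected_target = as.integer(expected), outcome = outcome,
      actual_target = as.integer(actual),
      presentation_frame = NA_integer_, stringsAsFactors = FALSE)
    attr(routine, "seed") <- seed
    routine
  })
}

# arc distance covered at each frame of a trapezoidal speed profile
# (accelerate at `a`, cruise at `vmax`, decelerate), last frame lands on D
trapezoid_profile <- function(D, fps, a = 6, vmax = 4) {
  stopifnot(D > 0)
  if (D > vmax^2 / a) {
    t_acc <- vmax / a
    t_tot <- 2 * t_acc + (D - vmax^2 / a) / vmax
  } else {
    t_acc <- sqrt(D / a)
    t_tot <- 2 * t_acc
    vmax <- a * t_acc
  }
  n <- max(2L, as.integer(ceiling(t_tot * fps)))
  t <- seq_len(n) / n * t_tot
  s <- ifelse(t <= t_acc, 0.5 * a * t^2,
              ifelse(t <= t_tot - t_acc,
                     0.5 * a * t_acc^2 + vmax * (t - t_acc),
                     D - 0.5 * a * (t_tot - t)^2))
  pmin(s, D)
}

# keep a mid-sprint plant point at least `clear` metres from every target
# centre by sliding it along the path; NULL when no admissible point exists
clear_plant <- function(p, dir, centers, clear = 0.50, max_shift = 0.35) {
  for (shift in seq(0, max_shift, by = 0.05)) {
    for (sgn in if (shift == 0) 1 else c(1, -1)) {
      q <- p + sgn * shift * dir
      if (min(sqrt(rowSums(sweep(centers, 2, q)^2))) >= clear) return(q)
    }
  }
  NULL
}

#' Generate the ground-truth trajectory of a routine
#'
#' Turns a scripted routine into per-frame motion: the player's body
#' follows straight centre -> landing -> centre paths with trapezoidal
#' speed profiles (6 m/s^2, 4 m/s); the feet alternate between ground
#' plants (frozen 2--4 frames) and smooth swings with a small parabolic
#' lift; the scripted landing is planted exactly for `contact_frames`
#' frames, and the centre-return plant triggers the next stimulus after a
#' short latency.  Mid-sprint plants are kept clear of every contact region
#' so the only contact-region footsteps are the scripted ones.  Feet cross
#' in the camera view during the change of direction at the target, so
#' self-occlusion frames occur naturally.
#'
#' @param routine Routine from [generate_routine()].
#' @param cfg A `synthetic_config`.
#' @param seed Seed for the trajectory randomness (reaction times, landing
#'   jitter); defaults to the routine seed offset by a constant.
#' @param pm A `platform_model`.
#' @return Object of class `agility_ground_truth`: `routine` (with
#'   `presentation_frame` filled in), `foot` (list `left`/`right`, each an
#'   `n_frames` x 3 matrix `X, Y, lift`, `NA` before the player enters),
#'   `body` (`n_frames` x 2), `phase` (list `left`/`right`, per-frame
#'   `"SPRINT"/"CONTACT"/"STAND"` labels, `NA` pre-entry), `events` (data
#'   frame: `play`, `frame`, `foot`, `target`, `X`, `Y`, `is_center`),
#'   `n_frames`, `cfg`.
#' @export
generate_trajectory <- function(routine, cfg = synthetic_config(),
                                seed = (attr(routine, "seed") %||% cfg$seed) + 424243,
                                pm = build_platform()) {
  fps <- cfg$fps
  centers <- pm$centers
  cfr <- cfg$contact_frames
  with_seed(seed, {
    nmax <- 400 + nrow(routine) * 120
    foot <- list(left = matrix(NA_real_, nmax, 3),
                 right = matrix(NA_real_, nmax, 3))
    phase <- list(left = rep(NA_character_, nmax),
                  right = rep(NA_character_, nmax))
    body <- matrix(NA_real_, nmax, 2)
    holds <- list(left = list(), right = list())
    events <- list()

    add_hold <- function(side, a, b, p, contact = FALSE) {
      hl <- holds[[side]]
      if (length(hl) && a <= hl[[length(hl)]]$b)
        a <- hl[[length(hl)]]$b + 1
      if (b < a) b <- a
      holds[[side]][[length(holds[[side]]) + 1]] <<-
        list(a = a, b = b, p = p, contact = contact)
      invisible(NULL)
    }

    entry <- cfg$warmup_frames                   # first frame with a player
    stand_l <- c(-0.15, 0.04)
    stand_r <- c(0.15, -0.04)
    add_hold("left", entry, entry, stand_l)      # ends grow as plays begin
    add_hold("right", entry, entry, stand_r)
    body[(entry + 1):nmax, ] <- rep(c(0, 0), each = nmax - entry)
    pres <- entry + 12
    alt <- TRUE

    for (i in seq_len(nrow(routine))) {
      routine$presentation_frame[i] <- pres
      reaction <- sample(8:14, 1)
      onset <- pres + reaction
      # close the standing holds at movement onset
      for (s in c("left", "right")) {
        last <- length(holds[[s]])
        holds[[s]][[last]]$b <- max(holds[[s]][[last]]$b, onset)
      }
      out <- routine$outcome[i]
      tgt <- if (out == "MISTAKEN") routine$actual_target[i]
             else routine$expected_target[i]
      ctr <- centers[as.character(tgt), ]
      land <- if (out == "MISSED") {
        th <- stats::runif(1, 0, 2 * pi)
        ctr + stats::runif(1, 0.31, 0.45) * c(cos(th), sin(th))
      } else {
        th <- stats::runif(1, 0, 2 * pi)
        ctr + 0.30 * stats::runif(1, 0, 0.6) * c(cos(th), sin(th))
      }
      D <- sqrt(sum(land^2))
      dir <- land / D
      prof <- trapezoid_profile(D, fps)
      arrival <- onset + length(prof)
      # frame f maps to row f + 1; body moves over frames onset+1 .. arrival
      body[onset + 1 + seq_along(prof), ] <- outer(prof, dir)
      foot_a <- if (land[1] < -0.1) "left" else if (land[1] > 0.1) "right"
                else if (alt) "left" else "right"
      alt <- !alt
      foot_b <- setdiff(c("left", "right"), foot_a)
      # mid-sprint plant of the trailing foot, clear of all contact regions
      if (D > 1.4) {
        dmid <- 0.55 * D
        q <- clear_plant(dir * dmid +
                           0.15 * c(-dir[2], dir[1]) *
                           (if (foot_b == "left") 1 else -1),
                         dir, centers)
        if (!is.null(q)) {
          tmid <- onset + which.min(abs(prof - dmid))
          if (tmid >= onset + 2 && tmid <= arrival - 3)
            add_hold(foot_b, tmid - 1, tmid + 1, q)
        }
      }
      # scripted landing: frozen contact_frames frames
      add_hold(foot_a, arrival, arrival + cfr - 1, land, contact = TRUE)
      if (!is.na(routine$actual_target[i]))
        events[[length(events) + 1]] <- data.frame(
          play = i, frame = arrival, foot = foot_a,
          target = as.integer(routine$actual_target[i]),
          X = land[1], Y = land[2], is_center = FALSE,
          stringsAsFactors = FALSE)
      # trailing foot brakes behind the landing on its own natural side
      # (deceleration stance: feet uncrossed, shoulder-width apart, so the
      # single frontal camera sees two separate foot columns)
      nat <- if (foot_b == "right") 1 else -1
      support <- land - 0.42 * dir + c(nat * 0.28, 0)
      sup_ok <- clear_plant(support, dir, centers)
      if (!is.null(sup_ok)) support <- sup_ok
      add_hold(foot_b, arrival + 1, arrival + 2, support)
      # body dwells on the landing during the contact
      if (cfr > 1)
        body[(arrival + 2):(arrival + cfr), ] <- rep(land, each = cfr - 1)
      # change of direction: sprint back to centre
      onset_b <- arrival + cfr
      Db <- sqrt(sum(land^2))
      prof_b <- trapezoid_profile(Db, fps)
      arr_b <- onset_b + length(prof_b)
      body[onset_b + 1 + seq_along(prof_b), ] <-
        rep(land, each = length(prof_b)) - outer(prof_b, dir)
      if (arr_b + 2 <= nmax)
        body[(arr_b + 2):nmax, ] <- rep(c(0, 0), each = nmax - arr_b - 1)
      if (Db > 1.4) {
        dmid <- 0.5 * Db
        q <- clear_plant(land - dir * dmid +
                           0.15 * c(-dir[2], dir[1]) *
                           (if (foot_a == "left") 1 else -1),
                         dir, centers)
        if (!is.null(q)) {
          tmid <- onset_b + which.min(abs(prof_b - dmid))
          if (tmid >= onset_b + 2 && tmid <= arr_b - 3)
            add_hold(foot_a, tmid - 1, tmid + 1, q)
        }
      }
      ctr_land <- c(stats::runif(1, -0.10, 0.10), stats::runif(1, -0.10, 0.10))
      add_hold(foot_b, arr_b, arr_b + cfr - 1, ctr_land, contact = TRUE)
      # the foot then keeps standing on the same spot (separate hold so the
      # scripted contact window keeps its 2-4 frame length)
      add_hold(foot_b, arr_b + cfr, arr_b + cfr, ctr_land)
      events[[length(events) + 1]] <- data.frame(
        play = i, frame = arr_b, foot = foot_b, target = 5L,
        X = ctr_land[1], Y = ctr_land[2], is_center = TRUE,
        stringsAsFactors = FALSE)
      # other foot settles beside for the stand (position jittered per
      # play: a player never stands on exactly the same pixels twice)
      side_p <- (if (foot_a == "left") stand_l else stand_r) +
        stats::runif(2, -0.06, 0.06)
      add_hold(foot_a, arr_b + 3, arr_b + 3, side_p)
      pres <- arr_b + 3
    }

    n_frames <- pres + 12
    stopifnot(n_frames <= nmax)
    for (s in c("left", "right")) {
      last <- length(holds[[s]])
      holds[[s]][[last]]$b <- n_frames - 1
    }

    # rasterise holds + smoothstep swings with parabolic lift
    for (s in c("left", "right")) {
      hl <- holds[[s]]
      for (k in seq_along(hl)) {
        h <- hl[[k]]
        rows <- (h$a:min(h$b, n_frames - 1)) + 1
        foot[[s]][rows, 1] <- h$p[1]
        foot[[s]][rows, 2] <- h$p[2]
        foot[[s]][rows, 3] <- 0
        phase[[s]][rows] <- if (h$contact) "CONTACT" else "STAND"
        if (k > 1) {
          g <- hl[[k - 1]]
          if (h$a - g$b >= 2) {
            tt <- (g$b + 1):(h$a - 1)
            u <- (tt - g$b) / (h$a - g$b)
            sm <- 3 * u^2 - 2 * u^3
            foot[[s]][tt + 1, 1] <- g$p[1] + sm * (h$p[1] - g$p[1])
            foot[[s]][tt + 1, 2] <- g$p[2] + sm * (h$p[2] - g$p[2])
            foot[[s]][tt + 1, 3] <- 0.12 * 4 * u * (1 - u)
            phase[[s]][tt + 1] <- "SPRINT"
          }
        }
      }
      # mid-sprint plants are part of the sprint, not scripted contacts
      phase[[s]][is.na(foot[[s]][seq_len(n_frames), 1])] <- NA
    }
    # standing labels outside contact: reuse STAND for non-swing holds

    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(play = integer(), frame = integer(), foot = character(),
                 target = integer(), X = numeric(), Y = numeric(),
                 is_center = logical(), stringsAsFactors = FALSE)
    structure(
      list(routine = routine,
           foot = list(left = foot$left[seq_len(n_frames), , drop = FALSE],
                       right = foot$right[seq_len(n_frames), , drop = FALSE]),
           phase = list(left = phase$left[seq_len(n_frames)],
                        right = phase$right[seq_len(n_frames)]),
           body = body[seq_len(n_frames), , drop = FALSE],
           events = ev, n_frames = n_frames, cfg = cfg, seed = seed),
      class = "agility_ground_truth")
  })
}

#' @export
print.agility_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic session ground truth: %d frames (%.1f s at %d fps)\n",
              x$n_frames, x$n_frames / x$cfg$fps, x$cfg$fps))
  cat(sprintf("  %d plays, %d target events, %d centre returns\n",
              nrow(x$routine), sum(!x$events$is_center),
              sum(x$events$is_center)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- rendering -------------------------------------------------------------

# filled axis-aligned ellipse, 0-based pixel centre coordinates
draw_ellipse <- function(img, cx, cy, rx, ry, value) {
  nr <- nrow(img); nc <- ncol(img)
  c0 <- max(1, floor(cx - rx) + 1); c1 <- min(nc, ceiling(cx + rx) + 1)
  r0 <- max(1, floor(cy - ry) + 1); r1 <- min(nr, ceiling(cy + ry) + 1)
  if (c0 > c1 || r0 > r1 || rx <= 0 || ry <= 0) return(img)
  cols <- c0:c1; rows <- r0:r1
  m <- outer(((rows - 1) - cy)^2 / ry^2, ((cols - 1) - cx)^2 / rx^2, "+") <= 1
  sub <- img[rows, cols, drop = FALSE]
  sub[m] <- value
  img[rows, cols] <- sub
  img
}

# thick 2D segment: capsule fill (distance to segment <= r) on the
# bounding subgrid, one vectorised pass
draw_limb <- function(img, p0, p1, r, value) {
  nr <- nrow(img); nc <- ncol(img)
  c0 <- max(1, floor(min(p0[1], p1[1]) - r) + 1)
  c1 <- min(nc, ceiling(max(p0[1], p1[1]) + r) + 1)
  r0 <- max(1, floor(min(p0[2], p1[2]) - r) + 1)
  r1 <- min(nr, ceiling(max(p0[2], p1[2]) + r) + 1)
  if (c0 > c1 || r0 > r1 || r <= 0) return(img)
  xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
  X <- matrix(rep(xs, each = length(ys)), length(ys))
  Y <- matrix(rep(ys, times = length(xs)), length(ys))
  d <- p1 - p0; L2 <- sum(d^2)
  tt <- if (L2 > 0)
    pmin(pmax(((X - p0[1]) * d[1] + (Y - p0[2]) * d[2]) / L2, 0), 1)
  else 0
  m <- (X - (p0[1] + tt * d[1]))^2 + (Y - (p0[2] + tt * d[2]))^2 <= r^2
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  sub[m] <- value
  img[r0:r1, c0:c1] <- sub
  img
}

# smooth static background texture in [0.35, 0.65]
synth_background <- function(width, height, seed) {
  with_seed(seed, {
    cc <- matrix(rep(0:(width - 1), each = height), height, width)
    rr <- matrix(rep(0:(height - 1), times = width), height, width)
    coarse <- matrix(stats::runif(ceiling(height / 16) * ceiling(width / 16),
                                  -1, 1),
                     ceiling(height / 16), ceiling(width / 16))
    up <- coarse[pmin(nrow(coarse), (0:(height - 1)) %/% 16 + 1),
                 pmin(ncol(coarse), (0:(width - 1)) %/% 16 + 1)]
    0.5 + 0.05 * sin(2 * pi * cc / 97) + 0.04 * sin(2 * pi * rr / 71) +
      0.05 * up
  })
}

# draw the player into img (intensities) and mask (logical); returns both
render_player <- function(img, mask, cam, bx, by, fl, fr) {
  pj <- function(p3) project_points(cam, p3)
  # torso + head as one tall ellipse
  tc <- pj(c(bx, by, 1.32))
  tb <- pj(c(bx, by, 0.82)); tt <- pj(c(bx, by, 1.85))
  sc <- cam$focal / tc[3]
  img <- draw_ellipse(img, tc[1], tc[2], 0.24 * sc, abs(tb[2] - tt[2]) / 2, 0.85)
  mask <- draw_ellipse(mask, tc[1], tc[2], 0.24 * sc, abs(tb[2] - tt[2]) / 2, TRUE)
  for (side in 1:2) {
    f <- if (side == 1) fl else fr
    hip <- pj(c(bx + if (side == 1) -0.09 else 0.09, by, 0.92))
    ftop <- pj(c(f[1], f[2], f[3] + 0.10))
    fsc <- cam$focal / ftop[3]
    img <- draw_limb(img, hip[1:2], ftop[1:2], 0.05 * fsc, 0.80)
    mask <- draw_limb(mask, hip[1:2], ftop[1:2], 0.05 * fsc, TRUE)
    f0 <- pj(c(f[1], f[2], f[3]))
    fmid <- pj(c(f[1], f[2], f[3] + 0.07))
    ry <- max(abs(f0[2] - fmid[2]), 2.5)
    # bottom-anchored at the projected ground-contact row, so the blob's
    # lowest pixels sit exactly at the foot's floor position
    img <- draw_ellipse(img, fmid[1], f0[2] - ry, 0.09 * fsc, ry, 0.92)
    mask <- draw_ellipse(mask, fmid[1], f0[2] - ry, 0.09 * fsc, ry, TRUE)
  }
  list(img = img, mask = mask)
}

#' Frame stream of a synthetic session
#'
#' Renders the ground-truth trajectory into grayscale frames through the
#' synthetic camera: static textured background, player as torso + legs +
#' foot ellipses (feet on the ground plane, so the published ground-plane
#' homography is exact for them), sinusoidal illumination drift, drifting
#' soft shadow blobs, additive sensor noise and salt-and-pepper noise.  All
#' noise is seed-reproducible per frame, so the stream supports random
#' access and identical seeds give identical frames.
#'
#' @param gt An `agility_ground_truth`.
#' @param noise If `FALSE`, render noise-free (still with the player).
#' @return List of class `frame_stream`: `frame(i)` returns the 0-based
#'   frame `i` as a height x width matrix in [0,1]; `mask(i)` the noise-free
#'   ground-truth player mask; plus `n_frames`, `camera`, `homography`,
#'   `background`.
#' @export
frame_stream <- function(gt, noise = TRUE) {
  cfg <- gt$cfg
  w <- cfg$frame_size[1]; h <- cfg$frame_size[2]
  cam <- synthetic_camera(cfg)
  bg <- synth_background(w, h, seed = gt$seed + 7)
  nz <- cfg$noise
  shadows <- with_seed(gt$seed + 17, {
    lapply(seq_len(nz$n_shadow_blobs), function(j)
      list(p0 = c(stats::runif(1, 0, w), stats::runif(1, 0, h)),
           v = stats::runif(2, -0.9, 0.9)))
  })
  # sensor noise drawn from a pre-generated pool of fields, applied with a
  # per-frame seeded circular shift: temporally varying per pixel, but far
  # cheaper than a fresh Gaussian field every frame
  noise_pool <- if (noise && nz$sensor_sd > 0)
    with_seed(gt$seed + 29, lapply(1:6, function(j)
      matrix(stats::rnorm(h * w, 0, nz$sensor_sd), h, w)))
  else NULL
  frame_fun <- function(i) {
    img <- bg
    fl <- gt$foot$left[i + 1, ]; fr <- gt$foot$right[i + 1, ]
    if (!is.na(fl[1])) {
      drawn <- render_player(img, matrix(FALSE, h, w), cam,
                             gt$body[i + 1, 1], gt$body[i + 1, 2], fl, fr)
      img <- drawn$img
    }
    if (noise) {
      gain <- 1 + nz$illumination_drift_amp *
        sin(2 * pi * i / (nz$drift_period_s * cfg$fps))
      img <- img * gain
      for (s in shadows) {
        p <- s$p0 + s$v * i
        p[1] <- p[1] %% (w + 120) - 60
        p[2] <- p[2] %% (h + 120) - 60
        c0 <- max(1, floor(p[1] - 60)); c1 <- min(w, ceiling(p[1] + 60))
        r0 <- max(1, floor(p[2] - 60)); r1 <- min(h, ceiling(p[2] + 60))
        if (c0 <= c1 && r0 <= r1) {
          dd <- outer((((r0:r1) - 1) - p[2])^2, (((c0:c1) - 1) - p[1])^2, "+")
          img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] *
            (1 - nz$shadow_depth * exp(-dd / (2 * 20^2)))
        }
      }
      img <- with_seed((gt$seed * 131 + i) %% 2147483647, {
        if (!is.null(noise_pool)) {
          dr <- sample.int(h, 1); dc <- sample.int(w, 1)
          nf <- noise_pool[[sample.int(length(noise_pool), 1)]]
          img <- img + nf[c(dr:h, seq_len(dr - 1)),
                          c(dc:w, seq_len(dc - 1)), drop = FALSE]
        }
        nsp <- round(nz$salt_pepper_rate * h * w)
        if (nsp > 0) {
          idx <- sample.int(h * w, nsp)
          img[idx] <- rep(c(0, 1), length.out = nsp)
        }
        img
      })
    }
    pmin(pmax(img, 0), 1)
  }
  mask_fun <- function(i) {
    m <- matrix(FALSE, h, w)
    fl <- gt$foot$left[i + 1, ]; fr <- gt$foot$right[i + 1, ]
    if (is.na(fl[1])) return(m)
    render_player(matrix(0, h, w), m, cam,
                  gt$body[i + 1, 1], gt$body[i + 1, 2], fl, fr)$mask
  }
  structure(list(frame = frame_fun, mask = mask_fun, n_frames = gt$n_frames,
                 camera = cam, homography = camera_homography(cam),
                 background = bg),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("Synthetic frame stream: %d frames of %dx%d\n",
              x$n_frames, x$camera$width, x$camera$height))
  invisible(x)
}

#' Write a synthetic session to disk
#'
#' Emits a numbered PNG frame sequence, the ground-truth event log
#' (`ground_truth.csv`), the routine (`routine.yaml`) and the true
#' calibration file (`calibration.csv`) into a directory.
#'
#' @param gt An `agility_ground_truth`.
#' @param dir Output directory (created if needed).
#' @param noise Render noise (default `TRUE`).
#' @param frames Which 0-based frames to write (default all).
#' @return The directory, invisibly.
#' @export
write_synthetic_session <- function(gt, dir, noise = TRUE,
                                    frames = seq_len(gt$n_frames) - 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- frame_stream(gt, noise = noise)
  for (i in frames)
    png::writePNG(fs$frame(i),
                  file.path(dir, sprintf("frame_%05d.png", i)))
  utils::write.csv(gt$events, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  write_routine(gt$routine, file.path(dir, "routine.yaml"))
  write_calibration(true_calibration(fs$camera),
                    file.path(dir, "calibration.csv"))
  invisible(dir)
}
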