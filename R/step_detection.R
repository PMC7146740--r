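#' Per-frame, per-foot step decision
#'
#' Implements the two-threshold decision applied every frame to each foot:
#' the filter first predicts, then the Euclidean distance `d` between the
#' predicted and measured box position is evaluated.
#'
#' * `d > theta_move` — the foot is most likely moving, so no step: the
#'   filter is reset from the measurement (zero velocity, initial
#'   covariance) and the decision is `MOVING`.  The reset re-anchors the
#'   filter at the most recent measurement, so on the next frame `d` is the
#'   true one-frame displacement: a contact as short as two frames
#'   (foot-down to toe-off spans 2--4 frames) still yields a near-zero `d`
#'   on its second frame and can fire the step threshold.
#' * `d <= theta_move` — the foot is decelerating or still: the filter is
#'   updated with the current measurement.  A second, tighter threshold is
#'   then checked on the post-update distance between the filtered position
#'   and the measurement; within `theta_step` the frame is classified as a
#'   `STEP`, otherwise `UPDATED`.
#'
#' A ground contact lasts 2--4 frames, during which the foot position is
#' essentially static, so the prediction locks onto the measurement and the
#' step threshold fires within the contact window.
#'
#' @param track A `foot_track` (posterior state of the previous frame).
#' @param z Current measurement `[x, y, w, h]`, or `NULL` when the foot has
#'   no measurement this frame (the track coasts on one predict).
#' @param theta_move Reset threshold, pixels (`theta_step <= theta_move`).
#' @param theta_step Step threshold, pixels.
#' @param model A `transition_model()`.
#' @param frame Frame index recorded on the decision.
#' @return List with `track` (advanced) and `decision`: `kind` one of
#'   `"MOVING"`, `"UPDATED"`, `"STEP"`, `"COAST"`, plus `foot`, `frame`,
#'   `dist` (pre-update prediction-measurement distance) and the measured
#'   `x`, `y`.
#' @export
step_decide <- function(track, z, theta_move = 15, theta_step = 4,
                        model = transition_model(), frame = NA_integer_) {
  stopifnot(inherits(track, "foot_track"))
  if (!(theta_step > 0 && theta_move > 0 && theta_step <= theta_move))
    stop("need 0 < theta_step <= theta_move")
  if (is.null(z)) {
    track <- kf_predict(track, model)
    return(list(track = track,
                decision = list(kind = "COAST", foot = track$foot,
                                frame = frame, dist = NA_real_,
                                x = NA_real_, y = NA_real_)))
  }
  stopifnot(is.numeric(z), length(z) == 4, all(is.finite(z)))
  track <- kf_predict(track, model)
  d <- sqrt(sum((track$x[1:2] - z[1:2])^2))
  if (d > theta_move) {
    track <- kf_reset(track, z)
    kind <- "MOVING"
  } else {
    track <- kf_update(track, z, model)
    d2 <- sqrt(sum((track$x[1:2] - z[1:2])^2))
    kind <- if (d2 <= theta_step) "STEP" else "UPDATED"
  }
  track$last_z <- z
  list(track = track,
       decision = list(kind = kind, foot = track$foot, frame = frame,
                       dist = d, x = z[1], y = z[2]))
}

#' Debounce step decisions into step events
#'
#' A single ground contact produces a run of consecutive `STEP` decisions
#' (the foot stays static for several frames).  Runs of `STEP` decisions of
#' the same foot whose frames are less than `min_gap` apart collapse to one
#' step event, timed at the first `STEP` frame of the run and located at the
#' measured foot position of that frame.  A contact happens at one place:
#' when the measured position drifts more than `break_px` pixels from the
#' run's anchor (its first `STEP`), a new event starts even without a frame
#' gap — otherwise slow approaches toward a distant target, whose per-frame
#' displacement stays under the step threshold, would chain successive
#' footsteps into one event.
#'
#' @param decisions Data frame of per-frame decisions with columns
#'   `kind`, `foot`, `frame`, `x`, `y` (as accumulated from [step_decide()]).
#' @param min_gap Minimum frame gap between distinct events of one foot
#'   (default 6, above the 2--4-frame contact duration at 20 fps).
#' @param fps Frames per second, used to stamp event times.
#' @param break_px Spatial run-break distance in pixels (default 10).
#' @param min_run Minimum number of `STEP` decisions a run needs to emit an
#'   event (default 1: every run emits).  A ground contact spans 2--4
#'   frames and yields several `STEP` decisions, so the detector pipeline
#'   sets 2: a single isolated `STEP` — e.g. a swinging foot momentarily
#'   stationary at the reversal point of a change of direction, off the
#'   ground — is then discarded.
#' @return Data frame of step events: `foot`, `frame`, `time`, `px`, `py`.
#' @export
debounce_steps <- function(decisions, min_gap = 6, fps = 20, break_px = 10,
                           min_run = 1) {
  stopifnot(min_gap >= 1, fps > 0, break_px > 0, min_run >= 1)
  steps <- decisions[decisions$kind == "STEP", , drop = FALSE]
  if (nrow(steps) == 0)
    return(data.frame(foot = character(), frame = integer(),
                      time = numeric(), px = numeric(), py = numeric(),
                      stringsAsFactors = FALSE))
  out <- lapply(split(steps, steps$foot), function(s) {
    s <- s[order(s$frame), , drop = FALSE]
    run_id <- integer(nrow(s))
    run_id[1] <- 1L
    ax <- s$x[1]; ay <- s$y[1]; af <- s$frame[1]
    for (i in seq_len(nrow(s))[-1]) {
      run_id[i] <- run_id[i - 1]
      if (s$frame[i] - af >= min_gap ||
          sqrt((s$x[i] - ax)^2 + (s$y[i] - ay)^2) > break_px) {
        run_id[i] <- run_id[i] + 1L
        ax <- s$x[i]; ay <- s$y[i]
      }
      af <- s$frame[i]
    }
    keep <- as.integer(names(which(table(run_id) >= min_run)))
    first <- !duplicated(run_id) & run_id %in% keep
    res <- s[first, , drop = FALSE]
    # the event is timed at the run's first STEP but located at the run's
    # median measured position: the first frame carries the settling
    # transient, while the median is the stable contact locus
    res$x <- vapply(run_id[first], function(id)
      stats::median(s$x[run_id == id]), numeric(1))
    res$y <- vapply(run_id[first], function(id)
      stats::median(s$y[run_id == id]), numeric(1))
    res
  })
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$frame, ev$foot), , drop = FALSE]
  data.frame(
    foot = ev$foot,
    frame = as.integer(ev$frame),
    time = ev$frame / fps,
    px = ev$x,
    py = ev$y,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Default detector configuration
#'
#' Collects every tunable parameter of the pipeline.  Pixel thresholds are
#' calibrated for 640-wide frames and scale linearly with frame width.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param fps Frames per second of the video.
#' @return Named list of parameters:
#' \describe{
#'   \item{theta_move, theta_step}{step-decision thresholds, pixels.}
#'   \item{min_gap}{debounce gap, frames.}
#'   \item{seg_threshold}{background-model match threshold on the squared
#'     Mahalanobis distance (the "segmentation threshold").}
#'   \item{seg_alpha, seg_alpha_w, seg_components, seg_var_init,
#'     seg_var_min, seg_cf, seg_shadow}{Gaussian-mixture background
#'     parameters: `seg_alpha` is the mean/variance learning rate (fast, to
#'     track slow illumination drift), `seg_alpha_w` the weight learning
#'     rate (slow, so a frequently-occupied pixel is not absorbed into the
#'     background), `seg_cf` the cumulative-weight fraction defining the
#'     background component set.}
#'   \item{morph_open, morph_close}{box structuring-element sizes.}
#'   \item{min_blob_frac}{minimum silhouette blob area, fraction of frame.}
#'   \item{min_foot_area}{minimum component area inside the feet box, px.}
#'   \item{feet_frac}{fraction of the silhouette height taken as feet box.}
#'   \item{kalman_P0, kalman_Q, kalman_R}{filter covariance diagonals.}
#' }
#' @export
agility_config <- function(frame_width = 640, frame_height = 480, fps = 20) {
  s <- frame_width / 640
  list(
    frame_width = frame_width,
    frame_height = frame_height,
    fps = fps,
    theta_move = 3 * s,
    theta_step = 1.5 * s,
    min_gap = 6L,
    debounce_break = 10 * s,
    min_run = 2L,
    seg_threshold = 16,
    seg_alpha = 0.025,
    seg_alpha_w = 0.001,
    seg_components = 3L,
    seg_var_init = 4e-4,
    seg_var_min = 2e-4,
    seg_var_max = 9e-4,
    seg_cf = 0.6,
    seg_shadow = c(0.5, 0.95),
    morph_open = 3L,
    morph_close = 5L,
    min_blob_frac = 0.001,
    min_foot_area = max(8, round(12 * s^2)),
    feet_frac = 0.2,
    kalman_P0 = c(10, 10, 25, 25, 10, 10) * s^2,
    kalman_Q = c(1, 1, 1, 1, 0.5, 0.5) * s^2,
    kalman_R = c(4, 4, 4, 4) * s^2
  )
}

#' Read / write a detector configuration file (YAML)
#'
#' Values present in the file override [agility_config()] defaults.
#'
#' @param path File path.
#' @param frame_width,frame_height,fps Base geometry for defaults.
#' @return `read_config` returns a full configuration list.
#' @export
read_config <- function(path, frame_width = 640, frame_height = 480, fps = 20) {
  cfg <- agility_config(frame_width, frame_height, fps)
  usr <- yaml::read_yaml(path)
  for (nm in names(usr)) cfg[[nm]] <- usr[[nm]]
  cfg
}

#' @param cfg Configuration list.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
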