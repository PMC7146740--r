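#' Run the footstep detector over a video session
#'
#' Executes the full per-frame pipeline: Gaussian-mixture background
#' subtraction with scenario masking and morphological cleanup, feet-ROI
#' extraction (bottom 20% of the player silhouette), separated/occluded
#' discrimination, per-foot Kalman tracking with the two-threshold step
#' decision, debouncing into step events, pixel-to-platform mapping,
#' 30 cm contact-region matching, and session scoring against the stimulus
#' routine.
#'
#' @param frames Input video: a `frame_stream`, a list of height x width
#'   matrices in [0,1], or a directory containing a numbered PNG sequence.
#' @param h Calibration `homography` (pixel to platform).
#' @param routine Stimulus routine data frame (see [read_routine()]).
#' @param pm A `platform_model`.
#' @param cfg Configuration from [agility_config()].
#' @param scenario_mask Optional logical mask; by default built from the
#'   calibrated platform footprint via [scenario_mask_from_platform()].
#' @return Object of class `agility_detection`: `session`
#'   (an `agility_session`), `events` (annotated debounced step events),
#'   `decisions` (per-frame decision log), `n_frames`, `cfg`.
#' @export
detect_session <- function(frames, h, routine, pm = build_platform(),
                           cfg = agility_config(), scenario_mask = NULL) {
  src <- as_frame_source(frames)
  n <- src$n
  w <- cfg$frame_width; ht <- cfg$frame_height
  if (is.null(scenario_mask))
    scenario_mask <- scenario_mask_from_platform(h, pm, w, ht)
  bg <- background_model(w, ht, cfg, init_frame = src$get(0))
  model <- transition_model(1)
  tracks <- list(left = NULL, right = NULL)

  cap <- 2L * n + 2L
  d_kind <- character(cap); d_foot <- character(cap)
  d_frame <- integer(cap); d_x <- numeric(cap); d_y <- numeric(cap)
  d_dist <- numeric(cap)
  nd <- 0L
  push <- function(dec) {
    nd <<- nd + 1L
    d_kind[nd] <<- dec$kind; d_foot[nd] <<- dec$foot
    d_frame[nd] <<- dec$frame
    d_x[nd] <<- dec$x; d_y[nd] <<- dec$y; d_dist[nd] <<- dec$dist
  }

  for (i in 0:(n - 1)) {
    f <- src$get(i)
    seg <- update_background(bg, f, scenario_mask, details = TRUE)
    mask <- seg$mask
    roi <- extract_feet_roi(mask, min_area = cfg$min_blob_frac * w * ht,
                            feet_frac = cfg$feet_frac, stats = seg$stats)
    z <- NULL
    if (!is.null(roi$feet)) {
      obs <- discriminate_feet(mask, roi$feet,
                               min_foot_area = cfg$min_foot_area)
      z <- measure_feet(obs, mask = mask)
    }
    for (side in c("left", "right")) {
      if (is.null(z)) {
        if (!is.null(tracks[[side]])) {
          res <- step_decide(tracks[[side]], NULL, cfg$theta_move,
                             cfg$theta_step, model, frame = i)
          tracks[[side]] <- res$track
          push(res$decision)
        }
      } else if (is.null(tracks[[side]])) {
        # filters initialise from the first observation (player standing
        # on the central target at session start)
        tracks[[side]] <- foot_track(z[[side]], side,
                                     P0 = cfg$kalman_P0, Q = cfg$kalman_Q,
                                     R = cfg$kalman_R)
      } else {
        res <- step_decide(tracks[[side]], z[[side]], cfg$theta_move,
                           cfg$theta_step, model, frame = i)
        tracks[[side]] <- res$track
        push(res$decision)
      }
    }
  }
  decisions <- data.frame(kind = d_kind[seq_len(nd)],
                          foot = d_foot[seq_len(nd)],
                          frame = d_frame[seq_len(nd)],
                          x = d_x[seq_len(nd)], y = d_y[seq_len(nd)],
                          dist = d_dist[seq_len(nd)],
                          stringsAsFactors = FALSE)
  events <- debounce_steps(decisions, cfg$min_gap, cfg$fps,
                           break_px = cfg$debounce_break %||% 10,
                           min_run = cfg$min_run %||% 2)
  events <- annotate_events(events, h, pm)
  session <- score_session(routine, events, cfg$fps)
  structure(list(session = session, events = session$events,
                 decisions = decisions, n_frames = n, cfg = cfg),
            class = "agility_detection")
}

#' @export
print.agility_detection <- function(x, ...) {
  cat(sprintf("Footstep detection over %d frames: %d step events\n",
              x$n_frames, nrow(x$events)))
  print(x$session)
  invisible(x)
}

as_frame_source <- function(frames) {
  if (inherits(frames, "frame_stream"))
    return(list(get = frames$frame, n = frames$n_frames))
  if (is.list(frames))
    return(list(get = function(i) frames[[i + 1]], n = length(frames)))
  if (is.character(frames) && length(frames) == 1 && dir.exists(frames)) {
    files <- sort(list.files(frames, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", frames)
    return(list(get = function(i) {
      a <- png::readPNG(files[i + 1])
      if (length(dim(a)) == 3) a <- a[, , 1] * 0.299 + a[, , 2] * 0.587 +
          a[, , 3] * 0.114
      a
    }, n = length(files)))
  }
  stop("unsupported frame source")
}

#' Detected contact-region events in evaluation form
#'
#' Extracts the registered footstep-in-contact-region events (peripheral
#' targets only; centre-return registrations steer the session but are not
#' scored events) and assigns each to the play whose presentation interval
#' contains it.  A contact region can only be stepped once within the
#' debounce gap, so same-target registrations closer than `min_gap` frames
#' (e.g. both feet read the same contact during a self-occlusion) collapse
#' to the first.
#'
#' @param det An `agility_detection`.
#' @param min_gap Region-level debounce gap in frames (default 1.5 s: a
#'   region cannot be genuinely re-stepped without a full sprint away and
#'   back, which takes well over a second).
#' @return Data frame `play`, `frame`, `target`.
#' @export
detected_event_table <- function(det, min_gap = round(1.5 * det$cfg$fps)) {
  ev <- det$events
  keep <- !is.na(ev$target) & ev$target != 5
  ev <- ev[keep, , drop = FALSE]
  ev <- ev[order(ev$frame), , drop = FALSE]
  if (nrow(ev) > 1) {
    drop <- logical(nrow(ev))
    last_frame <- rep(-Inf, 9)
    for (i in seq_len(nrow(ev))) {
      t <- ev$target[i]
      if (ev$frame[i] - last_frame[t] < min_gap) drop[i] <- TRUE
      else last_frame[t] <- ev$frame[i]
    }
    ev <- ev[!drop, , drop = FALSE]
  }
  pres <- det$session$plays$presentation_frame
  play <- findInterval(ev$frame, pres)
  play[play < 1] <- 1L
  data.frame(play = play, frame = ev$frame, target = ev$target)
}

#' Ground-truth contact-region events in evaluation form
#'
#' @param gt An `agility_ground_truth`.
#' @return Data frame `play`, `frame`, `target` (centre returns excluded).
#' @export
gt_event_table <- function(gt) {
  ev <- gt$events[!gt$events$is_center, , drop = FALSE]
  data.frame(play = ev$play, frame = ev$frame, target = ev$target)
}

#' Run a synthetic training campaign and score it
#'
#' Generates `n_routines` synthetic sessions (routine, trajectory, rendered
#' frames), runs the full detector on each with the calibration estimated
#' from the true correspondences, and scores all routines together against
#' ground truth with the 250 ms tolerance protocol.  The default campaign
#' mirrors the reference evaluation: 9 routines (3 simulated players x 3
#' routines) of 20 stimuli each, 180 scripted events in total.
#'
#' @param n_routines Number of routines (default 9).
#' @param base_seed Campaign seed; routine `r` uses seed
#'   `(base_seed - 1) * n_routines + r`, so the default campaign uses seeds
#'   1..9.
#' @param cfg A `synthetic_config` (shared by all routines up to the seed).
#' @param det_cfg Detector configuration (defaults to [agility_config()]
#'   at the campaign frame geometry).
#' @param noise Render noise (default `TRUE`).
#' @param verbose Print one line per routine.
#' @return Object of class `agility_campaign`: `report` (an `eval_report`
#'   over all routines), `detections`/`ground_truth` (pooled event tables
#'   with campaign-unique play ids), `sessions` (per-routine
#'   `agility_session`s), `scripted` (per-routine scripted outcomes),
#'   `n_frames` (total frames processed).
#' @export
run_campaign <- function(n_routines = 9, base_seed = 1,
                         cfg = synthetic_config(),
                         det_cfg = agility_config(cfg$frame_size[1],
                                                  cfg$frame_size[2], cfg$fps),
                         noise = TRUE, verbose = FALSE) {
  pm <- build_platform()
  det_all <- list(); gt_all <- list()
  sessions <- list(); scripted <- list()
  plays_all <- integer(0)
  total_frames <- 0L
  for (r in seq_len(n_routines)) {
    seed_r <- (base_seed - 1) * n_routines + r
    routine <- generate_routine(cfg, seed = seed_r)
    gt <- generate_trajectory(routine, cfg, pm = pm)
    fs <- frame_stream(gt, noise = noise)
    calib <- true_calibration(fs$camera, pm)
    h <- estimate_homography(as.matrix(calib[, 1:2]), as.matrix(calib[, 3:4]))
    det <- detect_session(fs, h, gt$routine, pm, det_cfg)
    dt <- detected_event_table(det)
    gtt <- gt_event_table(gt)
    off <- (r - 1L) * 1000L
    dt$play <- dt$play + off
    gtt$play <- gtt$play + off
    det_all[[r]] <- dt
    gt_all[[r]] <- gtt
    plays_all <- c(plays_all, off + seq_len(nrow(routine)))
    sessions[[r]] <- det$session
    scripted[[r]] <- gt$routine
    total_frames <- total_frames + gt$n_frames
    if (verbose)
      cat(sprintf("routine %d (seed %d): %d frames, %d GT events, %d detections\n",
                  r, seed_r, gt$n_frames, nrow(gtt), nrow(dt)))
  }
  detections <- do.call(rbind, det_all)
  ground_truth <- do.call(rbind, gt_all)
  m <- match_events(detections, ground_truth,
                    tolerance_frames(cfg$fps), plays = plays_all)
  report <- eval_metrics(m$counts)
  report$per_target <- timing_error_stats(m$pairs, cfg$fps)
  report$pairs <- m$pairs
  structure(list(report = report, detections = detections,
                 ground_truth = ground_truth, sessions = sessions,
                 scripted = scripted, n_frames = total_frames,
                 n_routines = n_routines, base_seed = base_seed),
            class = "agility_campaign")
}

#' @export
print.agility_campaign <- function(x, ...) {
  cat(sprintf("Synthetic campaign: %d routines, %d frames, %d GT events\n",
              x$n_routines, x$n_frames, nrow(x$ground_truth)))
  print(x$report)
  invisible(x)
}

#' Sweep the segmentation threshold and recompute the metrics
#'
#' Re-runs a campaign at several background-model match thresholds (the
#' squared-Mahalanobis segmentation threshold), reproducing the robustness
#' experiment: precision stays stable across thresholds while sensitivity
#' varies with them.
#'
#' @param thresholds Numeric vector of segmentation thresholds (>= 5 values
#'   for the qualitative shape).
#' @param n_routines,base_seed,cfg,noise As in [run_campaign()].
#' @return Data frame: `threshold`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, and the raw counts.
#' @export
sweep_seg_threshold <- function(thresholds, n_routines = 2, base_seed = 1,
                                cfg = synthetic_config(n_stimuli = 10),
                                noise = TRUE) {
  rows <- lapply(thresholds, function(th) {
    dc <- agility_config(cfg$frame_size[1], cfg$frame_size[2], cfg$fps)
    dc$seg_threshold <- th
    camp <- run_campaign(n_routines, base_seed, cfg, det_cfg = dc,
                         noise = noise)
    r <- camp$report
    data.frame(threshold = th, precision = r$precision,
               sensitivity = r$sensitivity, specificity = r$specificity,
               f1 = r$f1, TP = r$counts["TP"], FP = r$counts["FP"],
               FN = r$counts["FN"], TN = r$counts["TN"], row.names = NULL)
  })
  do.call(rbind, rows)
}
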