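#' Classify a matched footstep against the active stimulus
#'
#' A play resolves positively when the player's footstep reaches the target
#' the stimulus calls for, and as mistaken when it reaches a different
#' peripheral target.  A footstep that matches no target, or that matches
#' the central target (target 5, the start/return position), does not
#' resolve the play and is ignored here; the session logic treats a central
#' match while a play is unresolved as a missed play (the player came back
#' to the centre without reaching any target).
#'
#' @param expected_target Target id (1..9, not 5) the stimulus calls for.
#' @param matched Matched target id for the footstep, or `NA` for none.
#' @return `"POSITIVE"`, `"MISTAKEN"` or `"IGNORED"`.
#' @export
classify_event <- function(expected_target, matched) {
  stopifnot(expected_target %in% c(1:4, 6:9))
  if (is.na(matched) || matched == 5) return("IGNORED")
  if (matched == expected_target) "POSITIVE" else "MISTAKEN"
}

#' Score a training session from step events
#'
#' Runs the training-session state machine over the chronological step
#' events.  One stimulus (play) is active at a time, from its presentation
#' frame.  A footstep matching the expected target resolves the play
#' `POSITIVE`; a footstep matching a different peripheral target resolves it
#' `MISTAKEN`; a footstep matching the central target while the play is
#' unresolved registers `MISSED` (no target reached before the centre
#' return).  A centre match only counts as a *return* once the play is
#' engaged — at least one non-centre footstep has occurred since the
#' stimulus was presented — so the player still standing on the central
#' target when the stimulus appears cannot spuriously resolve the play.
#' The response time of a resolved play is the elapsed time from stimulus
#' presentation to the resolving footstep.  Events before the active
#' play's presentation (e.g. the centre-return footsteps that triggered
#' it) are ignored.
#'
#' @param routine Data frame of stimuli with columns `index`, `role`,
#'   `expected_target`, `presentation_frame` (see [read_routine()]).
#' @param events Data frame of annotated step events, time-ordered, with
#'   columns `frame`, `time`, `foot`, `target` (matched target id or `NA`)
#'   and `distance`.  Ties within a frame are resolved toward the smaller
#'   centre distance, then the left foot.
#' @param fps Frames per second.
#' @return List of class `agility_session`: `plays` (one row per stimulus:
#'   `stimulus_index`, `expected_target`, `kind`, `reached_target`,
#'   `response_time`, `correct`, `resolve_frame`) and `events` (the input
#'   events with a `stimulus_index` column and a `consumed` flag).
#' @export
score_session <- function(routine, events, fps = 20) {
  stopifnot(is.data.frame(routine), is.data.frame(events))
  np <- nrow(routine)
  plays <- data.frame(
    stimulus_index = routine$index,
    role = routine$role,
    expected_target = routine$expected_target,
    presentation_frame = routine$presentation_frame,
    kind = rep("PENDING", np),
    reached_target = rep(NA_integer_, np),
    response_time = rep(NA_real_, np),
    correct = rep(NA, np),
    resolve_frame = rep(NA_integer_, np),
    stringsAsFactors = FALSE
  )
  ev <- events[order(events$frame, events$distance,
                     match(events$foot, c("left", "right"))), , drop = FALSE]
  ev$stimulus_index <- NA_integer_
  ev$consumed <- FALSE
  cur <- 1L
  engaged <- FALSE
  for (i in seq_len(nrow(ev))) {
    if (cur > np) break
    pres <- plays$presentation_frame[cur]
    if (ev$frame[i] < pres) next
    ev$stimulus_index[i] <- plays$stimulus_index[cur]
    m <- ev$target[i]
    if (is.na(m) || m != 5) engaged <- TRUE
    if (is.na(m)) next
    if (m == 5) {
      if (!engaged) next                 # still standing at the centre
      plays$kind[cur] <- "MISSED"
      plays$correct[cur] <- FALSE
    } else {
      cls <- classify_event(plays$expected_target[cur], m)
      plays$kind[cur] <- cls
      plays$reached_target[cur] <- as.integer(m)
      plays$response_time[cur] <- ev$time[i] - pres / fps
      plays$correct[cur] <- cls == "POSITIVE"
    }
    plays$resolve_frame[cur] <- ev$frame[i]
    ev$consumed[i] <- TRUE
    cur <- cur + 1L
    engaged <- FALSE
  }
  structure(list(plays = plays, events = ev, fps = fps),
            class = "agility_session")
}

#' @export
print.agility_session <- function(x, ...) {
  k <- table(factor(x$plays$kind,
                    levels = c("POSITIVE", "MISTAKEN", "MISSED", "PENDING")))
  cat(sprintf("Training session: %d plays\n", nrow(x$plays)))
  cat(sprintf("  positive %d | mistaken %d | missed %d | pending %d\n",
              k["POSITIVE"], k["MISTAKEN"], k["MISSED"], k["PENDING"]))
  rt <- x$plays$response_time[x$plays$kind == "POSITIVE"]
  if (length(rt))
    cat(sprintf("  mean response time (positive plays): %.2f s\n", mean(rt)))
  invisible(x)
}

#' @export
summary.agility_session <- function(object, ...) {
  print(object)
  invisible(object$plays)
}

#' Annotate step events with platform coordinates and matched targets
#'
#' Maps each event's pixel point to platform coordinates through the
#' calibration homography and applies the 30 cm contact-region rule.
#'
#' @param events Step-event data frame from [debounce_steps()] (columns
#'   `foot`, `frame`, `time`, `px`, `py`).
#' @param h A `homography`.
#' @param pm A `platform_model`.
#' @return The events with added columns `X`, `Y` (metres), `target`
#'   (matched id or `NA`) and `distance` (metres to the nearest centre).
#' @export
annotate_events <- function(events, h, pm) {
  if (nrow(events) == 0) {
    events$X <- numeric(0); events$Y <- numeric(0)
    events$target <- integer(0); events$distance <- numeric(0)
    return(events)
  }
  pts <- pixel_to_platform(h, cbind(events$px, events$py))
  events$X <- pts[, 1]
  events$Y <- pts[, 2]
  mt <- lapply(seq_len(nrow(pts)), function(i) match_target(pm, pts[i, ]))
  events$target <- vapply(mt, `[[`, integer(1), "target")
  events$distance <- vapply(mt, `[[`, numeric(1), "distance")
  events
}

#' Read / write a stimulus routine file
#'
#' YAML list of stimuli, each with `index`, `role` (`DEFENSIVE` or
#' `OFFENSIVE`), `expected_target` (1..9, not 5) and `presentation_frame`.
#'
#' @param path File path.
#' @return `read_routine` returns the routine data frame.
#' @export
read_routine <- function(path) {
  lst <- yaml::read_yaml(path)
  routine <- do.call(rbind, lapply(lst$stimuli, function(s)
    data.frame(index = as.integer(s$index), role = s$role,
               expected_target = as.integer(s$expected_target),
               presentation_frame = as.integer(s$presentation_frame),
               stringsAsFactors = FALSE)))
  validate_routine(routine)
  routine
}

#' @param routine Routine data frame.
#' @rdname read_routine
#' @export
write_routine <- function(routine, path) {
  validate_routine(routine)
  yaml::write_yaml(list(stimuli = lapply(seq_len(nrow(routine)), function(i)
    list(index = routine$index[i], role = routine$role[i],
         expected_target = routine$expected_target[i],
         presentation_frame = routine$presentation_frame[i]))), path)
  invisible(path)
}

validate_routine <- function(routine) {
  stopifnot(is.data.frame(routine),
            all(c("index", "role", "expected_target", "presentation_frame")
                %in% names(routine)))
  if (any(!routine$expected_target %in% c(1:4, 6:9)))
    stop("expected targets must be peripheral (1..9, not 5)")
  if (any(!routine$role %in% c("DEFENSIVE", "OFFENSIVE")))
    stop("roles must be DEFENSIVE or OFFENSIVE")
  if (is.unsorted(routine$presentation_frame))
    stop("stimuli must be in chronological order")
  invisible(routine)
}

#' Write a session event log
#'
#' One row per registered step event with its session context, as CSV.
#'
#' @param session An `agility_session`.
#' @param path Output CSV path.
#' @param session_id Identifier stamped on every row.
#' @export
write_event_log <- function(session, path, session_id = "session") {
  ev <- session$events
  out <- data.frame(
    session_id = session_id,
    stimulus_index = ev$stimulus_index,
    foot = ev$foot,
    frame = ev$frame,
    time_s = ev$time,
    px = ev$px, py = ev$py,
    X_m = ev$X, Y_m = ev$Y,
    matched_target = ev$target,
    consumed = ev$consumed,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
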