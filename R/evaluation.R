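#' Temporal tolerance of the event-matching protocol, in frames
#'
#' A detected event counts as matching a ground-truth event when it names
#' the same target within 250 ms, i.e. within `floor(0.250 * fps)` frames
#' (5 frames at 20 fps).
#'
#' @param fps Frames per second.
#' @param tol_s Temporal tolerance in seconds (default 0.250).
#' @return Integer number of frames.
#' @export
tolerance_frames <- function(fps, tol_s = 0.250) {
  stopifnot(fps > 0, tol_s >= 0)
  as.integer(floor(tol_s * fps))
}

#' Match detected events to ground truth with temporal tolerance
#'
#' Greedy one-to-one matching per play: a detection is a true positive when
#' it names the same target as a ground-truth event of the same play within
#' `tol_frames` frames.  When several detections fall within tolerance of
#' one ground-truth event, the smallest absolute frame difference wins, ties
#' broken toward the earlier frame.  Unmatched detections are false
#' positives (duplicates included), unmatched ground-truth events are false
#' negatives, and a play that has no ground-truth target event and no
#' detection is a true negative.
#'
#' @param detected Data frame with columns `play`, `frame`, `target` (the
#'   registered footstep-in-contact-region events).
#' @param gt Ground-truth data frame with the same columns.
#' @param tol_frames Tolerance in frames (see [tolerance_frames()]).
#' @param plays Vector of all play identifiers in the campaign (needed to
#'   count true negatives for plays absent from both lists).
#' @return List with `counts` (`TP`, `FP`, `FN`, `TN`) and `pairs`
#'   (matched detections: `play`, `target`, `frame_det`, `frame_gt`,
#'   `dframes`).
#' @export
match_events <- function(detected, gt, tol_frames,
                         plays = union(detected$play, gt$play)) {
  stopifnot(tol_frames >= 0)
  need <- c("play", "frame", "target")
  stopifnot(all(need %in% names(detected)), all(need %in% names(gt)))
  TP <- FP <- FN <- TN <- 0L
  pairs <- list()
  for (p in plays) {
    d <- detected[!is.na(detected$play) & detected$play == p, , drop = FALSE]
    g <- gt[gt$play == p, , drop = FALSE]
    if (nrow(g) == 0 && nrow(d) == 0) { TN <- TN + 1L; next }
    used <- rep(FALSE, nrow(d))
    if (nrow(g)) {
      g <- g[order(g$frame), , drop = FALSE]
      for (i in seq_len(nrow(g))) {
        cand <- which(!used & d$target == g$target[i] &
                        abs(d$frame - g$frame[i]) <= tol_frames)
        if (length(cand)) {
          dd <- abs(d$frame[cand] - g$frame[i])
          best <- cand[order(dd, d$frame[cand])][1]
          used[best] <- TRUE
          TP <- TP + 1L
          pairs[[length(pairs) + 1L]] <- data.frame(
            play = p, target = g$target[i],
            frame_det = d$frame[best], frame_gt = g$frame[i],
            dframes = d$frame[best] - g$frame[i])
        } else {
          FN <- FN + 1L
        }
      }
    }
    FP <- FP + sum(!used)
  }
  list(
    counts = c(TP = TP, FP = FP, FN = FN, TN = TN),
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(play = integer(), target = integer(),
                 frame_det = integer(), frame_gt = integer(),
                 dframes = integer())
  )
}

#' Detection metrics from match counts
#'
#' Precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(FP+TN)` and `F1 = 2*precision*sensitivity /
#' (precision+sensitivity)`.  A ratio with a zero denominator is reported as
#' `NA` (not applicable), never as 0/0.
#'
#' @param counts Named vector or list with `TP`, `FP`, `FN`, `TN`.
#' @return Object of class `eval_report` with the counts and metrics.
#' @export
eval_metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "FP", "FN", "TN")]
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative TP, FP, FN, TN")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(counts["TP"], counts["TP"] + counts["FP"])
  sensitivity <- ratio(counts["TP"], counts["TP"] + counts["FN"])
  specificity <- ratio(counts["TN"], counts["FP"] + counts["TN"])
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            (precision + sensitivity) > 0)
    2 * precision * sensitivity / (precision + sensitivity)
  else NA_real_
  structure(
    list(counts = counts,
         precision = unname(precision), sensitivity = unname(sensitivity),
         specificity = unname(specificity), f1 = unname(f1),
         per_target = NULL),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Event-detection evaluation\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n",
              x$counts["TP"], x$counts["FP"], x$counts["FN"], x$counts["TN"]))
  pct <- function(v) if (is.na(v)) "   n/a" else sprintf("%5.1f%%", 100 * v)
  cat(sprintf("  precision   %s\n", pct(x$precision)))
  cat(sprintf("  sensitivity %s\n", pct(x$sensitivity)))
  cat(sprintf("  specificity %s\n", pct(x$specificity)))
  cat(sprintf("  F1          %s\n", pct(x$f1)))
  if (!is.null(x$per_target)) {
    cat("  per-target timing error (s):\n")
    print(x$per_target, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Per-target timing-error statistics
#'
#' For the matched detection/ground-truth pairs, reports per target the
#' mean absolute time error, the standard deviation of the signed error
#' (seconds) and the pair count, plus an overall row.
#'
#' @param pairs Matched pairs from [match_events()].
#' @param fps Frames per second (converts frame differences to seconds).
#' @return Data frame with columns `target`, `mean_abs_error`, `sd_error`,
#'   `n`; targets with no pairs get `NA` statistics.
#' @export
timing_error_stats <- function(pairs, fps = 20) {
  dt <- pairs$dframes / fps
  one <- function(sel, label) {
    d <- dt[sel]
    data.frame(target = label,
               mean_abs_error = if (length(d)) mean(abs(d)) else NA_real_,
               sd_error = if (length(d) > 1) stats::sd(d) else
                 if (length(d) == 1) 0 else NA_real_,
               n = length(d), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(1:9, function(t)
    one(pairs$target == t, as.character(t))))
  rbind(out, one(rep(TRUE, length(dt)), "overall"))
}

#' Score a detection run against ground truth
#'
#' Convenience wrapper: matches events at the 250 ms tolerance for the given
#' frame rate, computes the metrics and the per-target timing-error table.
#'
#' @param detected,gt Event data frames (`play`, `frame`, `target`).
#' @param fps Frames per second.
#' @param plays All play identifiers of the campaign.
#' @return An `eval_report` with `per_target` filled in.
#' @export
evaluate_detection <- function(detected, gt, fps = 20,
                               plays = union(detected$play, gt$play)) {
  m <- match_events(detected, gt, tolerance_frames(fps), plays)
  rep <- eval_metrics(m$counts)
  rep$per_target <- timing_error_stats(m$pairs, fps)
  rep$pairs <- m$pairs
  rep
}

#' Serialise an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(
      counts = as.list(report$counts),
      metrics = list(precision = report$precision,
                     sensitivity = report$sensitivity,
                     specificity = report$specificity,
                     f1 = report$f1),
      per_target = report$per_target
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
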