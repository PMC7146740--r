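#' Constant-velocity transition model for foot tracking
#'
#' State is `[x, y, vx, vy, w, h]`: bounding-box reference point (pixels),
#' its velocity (pixels per frame) and the box width/height (pixels).  The
#' transition matrix is the identity except for the position-velocity
#' couplings `A[1,3] = A[2,4] = dt`; the measurement matrix selects
#' `(x, y, w, h)` — box size is measured but not propagated with velocity.
#'
#' @param dt Sample period in frames (default 1: velocities are px/frame).
#' @return List with `A` (6 x 6) and `H` (4 x 6).
#' @export
transition_model <- function(dt = 1) {
  A <- diag(6)
  A[1, 3] <- dt
  A[2, 4] <- dt
  H <- matrix(0, 4, 6)
  H[1, 1] <- 1; H[2, 2] <- 1; H[3, 5] <- 1; H[4, 6] <- 1
  list(A = A, H = H)
}

#' Create a per-foot Kalman track
#'
#' One linear Kalman filter is associated with each foot.  The filter state
#' holds the foot bounding-box position, velocity and size; measurements are
#' `(x, y, w, h)` from the segmentation stage.
#'
#' @param z Initial measurement `[x, y, w, h]` (pixels).
#' @param foot `"left"` or `"right"`.
#' @param P0 Initial state covariance (6 x 6, or length-6 diagonal).
#' @param Q Process-noise covariance (6 x 6, or length-6 diagonal).
#' @param R Measurement-noise covariance (4 x 4, or length-4 diagonal).
#' @return Object of class `foot_track`.
#' @export
foot_track <- function(z, foot = c("left", "right"),
                       P0 = c(10, 10, 25, 25, 10, 10),
                       Q = c(1, 1, 4, 4, 0.5, 0.5),
                       R = c(4, 4, 4, 4)) {
  foot <- match.arg(foot)
  stopifnot(is.numeric(z), length(z) == 4, all(is.finite(z)))
  as_cov <- function(m, d) {
    if (is.null(dim(m))) m <- diag(m, d)
    stopifnot(all(dim(m) == c(d, d)))
    m
  }
  structure(
    list(
      x = c(z[1], z[2], 0, 0, z[3], z[4]),
      P = as_cov(P0, 6),
      P0 = as_cov(P0, 6),
      Q = as_cov(Q, 6),
      R = as_cov(R, 4),
      last_z = z,
      foot = foot
    ),
    class = "foot_track"
  )
}

#' @export
print.foot_track <- function(x, ...) {
  cat(sprintf("foot_track (%s): x=%.1f y=%.1f vx=%.2f vy=%.2f w=%.1f h=%.1f\n",
              x$foot, x$x[1], x$x[2], x$x[3], x$x[4], x$x[5], x$x[6]))
  invisible(x)
}

#' Kalman predict step
#'
#' Propagates the state through the constant-velocity model:
#' `x <- A x`, `P <- A P A' + Q`.
#'
#' @param track A `foot_track`.
#' @param model A `transition_model()` list.
#' @return The track with predicted state and covariance.
#' @export
kf_predict <- function(track, model = transition_model()) {
  stopifnot(inherits(track, "foot_track"))
  track$x <- drop(model$A %*% track$x)
  P <- model$A %*% track$P %*% t(model$A) + track$Q
  track$P <- (P + t(P)) / 2          # keep symmetric against round-off
  track
}

#' Kalman update step
#'
#' Standard gain update against a `(x, y, w, h)` measurement; the innovation
#' is stored on the track as `innovation`.
#'
#' @param track A `foot_track` (normally just predicted).
#' @param z Measurement `[x, y, w, h]`.
#' @param model A `transition_model()` list.
#' @return The updated track.
#' @export
kf_update <- function(track, z, model = transition_model()) {
  stopifnot(inherits(track, "foot_track"))
  if (!is.numeric(z) || length(z) != 4 || any(!is.finite(z)))
    stop("measurement must be a finite numeric vector of length 4")
  H <- model$H
  nu <- z - drop(H %*% track$x)
  S <- H %*% track$P %*% t(H) + track$R
  K <- track$P %*% t(H) %*% solve(S)
  track$x <- track$x + drop(K %*% nu)
  IKH <- diag(6) - K %*% H
  # Joseph form for numerical symmetry/PSD preservation
  P <- IKH %*% track$P %*% t(IKH) + K %*% track$R %*% t(K)
  track$P <- (P + t(P)) / 2
  track$innovation <- nu
  track$last_z <- z
  track
}

#' Reset a foot track from a measurement
#'
#' Used when the foot is judged to be moving: the filter is re-anchored at
#' the previous measurement with zero velocity and the configured initial
#' covariance, discarding the stale dynamic state.
#'
#' @param track A `foot_track`.
#' @param z Measurement `[x, y, w, h]` to reset from (typically the previous
#'   frame's measurement).  When `NULL`, falls back to the track's stored
#'   last measurement.
#' @return The reset track.
#' @export
kf_reset <- function(track, z = NULL) {
  stopifnot(inherits(track, "foot_track"))
  if (is.null(z)) z <- track$last_z
  if (is.null(z)) stop("no measurement available to reset from")
  track$x <- c(z[1], z[2], 0, 0, z[3], z[4])
  track$P <- track$P0
  track$last_z <- z
  track
}
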