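# Independent oracles and small fixture builders shared across tests.

# Textbook Kalman recursion, written directly from the standard equations
# and independent of the package's tracking code paths.
naive_kalman <- function(z_seq, A, H, Q, R, x0, P0) {
  x <- x0
  P <- P0
  out <- vector("list", nrow(z_seq))
  for (k in seq_len(nrow(z_seq))) {
    # predict
    x <- A %*% x
    P <- A %*% P %*% t(A) + Q
    # update
    z <- z_seq[k, ]
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (z - H %*% x)
    P <- (diag(nrow(P)) - K %*% H) %*% P
    out[[k]] <- list(x = as.numeric(x), P = P)
  }
  out
}

# naive O(n k^2) binary erosion/dilation with a size x size box, used as a
# morphology oracle on small masks
naive_morph <- function(m, size, dilate) {
  half <- size %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- max(1, r - half):min(nr, r + half)
    cc <- max(1, c - half):min(nc, c + half)
    out[r, c] <- if (dilate) any(m[rr, cc]) else all(m[rr, cc])
  }
  out
}
naive_open <- function(m, size)
  naive_morph(naive_morph(m, size, FALSE), size, TRUE)
naive_close <- function(m, size)
  naive_morph(naive_morph(m, size, TRUE), size, FALSE)

# default synthetic camera + its exact homography, shared by geometry tests
test_camera <- function() synthetic_camera(synthetic_config())

# a small scripted session (few stimuli) for integration-style tests
small_session <- function(seed, n_stimuli = 3, noise = FALSE) {
  cfg <- synthetic_config(n_stimuli = n_stimuli, seed = seed)
  routine <- generate_routine(cfg, seed = seed)
  gt <- generate_trajectory(routine, cfg)
  list(cfg = cfg, gt = gt, stream = frame_stream(gt, noise = noise))
}

run_small_session <- function(seed, n_stimuli = 3, noise = FALSE) {
  s <- small_session(seed, n_stimuli, noise)
  pm <- build_platform()
  calib <- true_calibration(s$stream$camera, pm)
  h <- estimate_homography(as.matrix(calib[, 1:2]), as.matrix(calib[, 3:4]))
  det <- detect_session(s$stream, h, s$gt$routine, pm,
                        agility_config(s$cfg$frame_size[1],
                                       s$cfg$frame_size[2], s$cfg$fps))
  list(gt = s$gt, det = det)
}
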