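#' Estimate the pixel-to-platform homography
#'
#' Fits the 3 x 3 planar homography mapping image pixels to metric platform
#' (floor) coordinates from point correspondences, by the direct linear
#' transform with Hartley coordinate pre-normalisation.  At least four
#' non-degenerate correspondences are required; with more, the fit is least
#' squares and the RMS reprojection residual (in metres, on the platform
#' side) is reported.
#'
#' Pixel coordinates are 0-based `(x = column, y = row)` with the origin at
#' the top-left of the image; platform coordinates are metres, origin at the
#' centre of target 5, +Y toward the camera, +X toward the camera's right.
#'
#' @param pixel_points n x 2 matrix of pixel points `(x, y)`.
#' @param platform_points n x 2 matrix of corresponding platform points in
#'   metres.
#' @return Object of class `homography`: list with `H` (3 x 3, pixel to
#'   platform, normalised so `H[3, 3] == 1`), `Hinv` (platform to pixel) and
#'   `residual` (RMS reprojection error, metres).
#' @export
estimate_homography <- function(pixel_points, platform_points) {
  px <- as.matrix(pixel_points)
  pl <- as.matrix(platform_points)
  if (nrow(px) != nrow(pl))
    stop("correspondence lists differ in length")
  if (nrow(px) < 4)
    stop("homography calibration needs at least 4 correspondences")
  if (any(!is.finite(px)) || any(!is.finite(pl)))
    stop("non-finite calibration coordinates")

  np <- normalise_points(px)
  nq <- normalise_points(pl)
  x <- np$pts[, 1]; y <- np$pts[, 2]
  u <- nq$pts[, 1]; v <- nq$pts[, 2]
  n <- nrow(px)
  # DLT system: two rows per correspondence
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-8 * sv$d[1])
    stop("degenerate calibration configuration (collinear or coincident points)")
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nq$T) %*% Hn %*% np$T
  if (abs(H[3, 3]) < 1e-12 * max(abs(H)))
    stop("degenerate homography (vanishing scale entry)")
  H <- H / H[3, 3]
  h <- structure(
    list(H = H, Hinv = solve(H), residual = NA_real_),
    class = "homography"
  )
  mapped <- pixel_to_platform(h, px)
  h$residual <- sqrt(mean(rowSums((mapped - pl)^2)))
  h
}

# Hartley normalisation: translate centroid to origin, scale mean distance
# to sqrt(2).  Returns transformed points and the 3x3 transform.
normalise_points <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  T <- matrix(c(s, 0, -s * ctr[1],
                0, s, -s * ctr[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  list(pts = cbind(s * (pts[, 1] - ctr[1]), s * (pts[, 2] - ctr[2])), T = T)
}

#' Construct a homography object from an explicit matrix
#'
#' @param H 3 x 3 invertible matrix mapping pixel homogeneous coordinates to
#'   platform coordinates.
#' @return A `homography` object (matrix renormalised so `H[3,3] == 1`).
#' @export
homography <- function(H) {
  H <- as.matrix(H)
  stopifnot(all(dim(H) == c(3, 3)), all(is.finite(H)))
  if (abs(det(H)) < 1e-14) stop("homography matrix is singular")
  if (abs(H[3, 3]) < 1e-12 * max(abs(H)))
    stop("homography matrix has vanishing bottom-right entry")
  H <- H / H[3, 3]
  structure(list(H = H, Hinv = solve(H), residual = NA_real_),
            class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat("Pixel -> platform homography\n")
  print(signif(x$H, 6))
  if (is.finite(x$residual))
    cat(sprintf("RMS calibration residual: %.2e m\n", x$residual))
  invisible(x)
}

apply_homography <- function(M, pts) {
  pts <- if (is.null(dim(pts))) matrix(pts, ncol = 2) else as.matrix(pts)
  ph <- cbind(pts, 1) %*% t(M)
  w <- ph[, 3]
  if (any(abs(w) < 1e-12))
    stop("point maps to the plane at infinity under this homography")
  cbind(ph[, 1] / w, ph[, 2] / w)
}

#' Map pixel points to platform coordinates (and back)
#'
#' Applies the homography (homogeneous transform followed by perspective
#' division).  `platform_to_pixel` applies the inverse map.
#'
#' @param h A `homography`.
#' @param p Length-2 point or n x 2 matrix.
#' @return Point(s) in the destination frame, same shape as the input.
#' @export
pixel_to_platform <- function(h, p) {
  stopifnot(inherits(h, "homography"))
  out <- apply_homography(h$H, p)
  if (is.null(dim(p))) drop(out) else out
}

#' @rdname pixel_to_platform
#' @export
platform_to_pixel <- function(h, p) {
  stopifnot(inherits(h, "homography"))
  out <- apply_homography(h$Hinv, p)
  if (is.null(dim(p))) drop(out) else out
}

#' Pixel-level polygons enclosing each target contact region
#'
#' Samples each target's metric contact-circle boundary and maps the samples
#' through the platform-to-pixel homography, yielding one pixel polygon per
#' target.  These polygons gate the nine contact regions in the image.
#'
#' @param h A `homography` (pixel to platform).
#' @param pm A `platform_model`.
#' @param n_vertices Boundary samples per target (>= 8).
#' @return Named list (targets "1".."9") of `n_vertices` x 2 pixel matrices.
#' @export
target_regions_pixels <- function(h, pm, n_vertices = 16) {
  stopifnot(inherits(h, "homography"), inherits(pm, "platform_model"),
            n_vertices >= 8)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  circ <- cbind(cos(th), sin(th)) * pm$contact_radius
  out <- lapply(1:9, function(i) {
    platform_to_pixel(h, sweep(circ, 2, pm$centers[i, ], "+"))
  })
  names(out) <- rownames(pm$centers)
  out
}

#' Read / write a calibration correspondence file
#'
#' CSV with columns `pixel_x, pixel_y, platform_x, platform_y`, one row per
#' correspondence (pixels 0-based, platform in metres).
#'
#' @param path File path.
#' @return `read_calibration` returns the correspondence data frame;
#'   `calibrate_from_file` fits and returns the `homography`.
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pixel_x", "pixel_y", "platform_x", "platform_y")
  if (!all(need %in% names(df)))
    stop("calibration file must have columns ", paste(need, collapse = ", "))
  df[need]
}

#' @param df Correspondence data frame as returned by `read_calibration`.
#' @rdname read_calibration
#' @export
write_calibration <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_calibration
#' @export
calibrate_from_file <- function(path) {
  df <- read_calibration(path)
  estimate_homography(as.matrix(df[, c("pixel_x", "pixel_y")]),
                      as.matrix(df[, c("platform_x", "platform_y")]))
}
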