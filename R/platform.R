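#' Build the training-platform model
#'
#' The platform is a 3 x 3 grid of square targets on the floor, described in
#' metric coordinates centred on the central target (target 5).  The origin
#' is the centre of target 5, the positive Y axis points toward the camera
#' and the positive X axis toward the camera's right.  Targets are numbered
#' row-wise starting from the row nearest the camera: 1--3 front (left to
#' right in the camera view), 4--6 middle, 7--9 back.
#'
#' A footstep is considered to have reached a target when its platform
#' position lies strictly within `contact_radius` metres of that target's
#' centre (the contact region).
#'
#' @param spacing Distance in metres between adjacent target centres
#'   (row/column neighbours).  Default 2 m.
#' @param contact_radius Radius in metres of the contact region around each
#'   target centre.  Default 0.30 m.
#' @param centers Optional 9 x 2 matrix of explicit target centres (metres),
#'   rows named or ordered 1..9, overriding the regular grid.
#' @return An object of class `platform_model` with elements
#'   `centers` (9 x 2 matrix, metres), `spacing`, `contact_radius`.
#' @examples
#' pm <- build_platform()
#' pm$centers["5", ]           # c(0, 0)
#' match_target(pm, c(0.1, 0.1))
#' @export
build_platform <- function(spacing = 2, contact_radius = 0.30, centers = NULL) {
  if (!is.numeric(spacing) || length(spacing) != 1 || !is.finite(spacing) ||
      spacing <= 0)
    stop("'spacing' must be a single positive number (metres)")
  if (!is.numeric(contact_radius) || length(contact_radius) != 1 ||
      !is.finite(contact_radius) || contact_radius <= 0)
    stop("'contact_radius' must be a single positive number (metres)")
  if (is.null(centers)) {
    # row nearest the camera (y = +spacing) holds targets 1-3, back row 7-9
    xs <- c(-1, 0, 1) * spacing
    ys <- c(1, 0, -1) * spacing
    centers <- cbind(
      x = rep(xs, times = 3),
      y = rep(ys, each = 3)
    )
  } else {
    centers <- as.matrix(centers)
    if (!all(dim(centers) == c(9, 2)) || any(!is.finite(centers)))
      stop("'centers' must be a finite 9 x 2 matrix")
    colnames(centers) <- c("x", "y")
  }
  rownames(centers) <- as.character(1:9)
  structure(
    list(centers = centers, spacing = spacing,
         contact_radius = contact_radius),
    class = "platform_model"
  )
}

#' @export
print.platform_model <- function(x, ...) {
  cat("Training platform: 3x3 target grid\n")
  cat(sprintf("  spacing        %.2f m\n", x$spacing))
  cat(sprintf("  contact radius %.2f m\n", x$contact_radius))
  cat("  target centres (m):\n")
  print(round(x$centers, 3))
  invisible(x)
}

#' Match a platform point to a target contact region
#'
#' Finds the nearest target centre and reports a match when the distance is
#' strictly below the platform's contact radius (default 30 cm); otherwise no
#' target is matched.  The distance to the nearest centre is always returned.
#'
#' @param pm A `platform_model`.
#' @param p Platform point, numeric length-2 `(x, y)` in metres.
#' @return List with `target` (integer 1..9, or `NA_integer_` when no centre
#'   is within the contact radius) and `distance` (metres to nearest centre).
#' @export
match_target <- function(pm, p) {
  stopifnot(inherits(pm, "platform_model"), is.numeric(p), length(p) == 2)
  d <- sqrt((pm$centers[, 1] - p[1])^2 + (pm$centers[, 2] - p[2])^2)
  i <- which.min(d)
  list(
    target = if (d[i] < pm$contact_radius) as.integer(rownames(pm$centers)[i])
             else NA_integer_,
    distance = unname(d[i])
  )
}

#' Read / write a platform definition file
#'
#' The platform file is YAML with fields `spacing`, `contact_radius` and an
#' optional `centers` table (list of `[id, x, y]` rows) overriding the
#' regular grid.
#'
#' @param path File path.
#' @return `read_platform` returns a `platform_model`.
#' @export
read_platform <- function(path) {
  cfg <- yaml::read_yaml(path)
  centers <- NULL
  if (!is.null(cfg$centers)) {
    tab <- do.call(rbind, lapply(cfg$centers, function(r) unlist(r)))
    centers <- matrix(NA_real_, 9, 2)
    centers[tab[, 1], ] <- tab[, 2:3, drop = FALSE]
  }
  build_platform(
    spacing = if (is.null(cfg$spacing)) 2 else cfg$spacing,
    contact_radius = if (is.null(cfg$contact_radius)) 0.30 else cfg$contact_radius,
    centers = centers
  )
}

#' @param pm A `platform_model` to serialise.
#' @rdname read_platform
#' @export
write_platform <- function(pm, path) {
  stopifnot(inherits(pm, "platform_model"))
  yaml::write_yaml(
    list(
      spacing = pm$spacing,
      contact_radius = pm$contact_radius,
      centers = lapply(1:9, function(i)
        c(i, unname(pm$centers[i, 1]), unname(pm$centers[i, 2])))
    ),
    path
  )
  invisible(path)
}
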