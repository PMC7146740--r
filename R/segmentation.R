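#' Create a Gaussian-mixture background model
#'
#' Maintains, per pixel, a small mixture of Gaussians over grayscale
#' intensity (weights, means, variances).  Each frame, the matching
#' component is updated with the configured learning rate; pixels whose
#' intensity matches no high-weight component are foreground.  A grayscale
#' shadow heuristic (proportional darkening relative to the dominant
#' background component) suppresses soft shadows.
#'
#' The model object is an environment: [update_background()] advances it in
#' place and returns the cleaned foreground mask.
#'
#' @param width,height Frame size in pixels.
#' @param cfg Configuration list from [agility_config()]; the relevant
#'   entries are `seg_components`, `seg_alpha`, `seg_threshold` (squared
#'   Mahalanobis match threshold — the segmentation threshold),
#'   `seg_var_init`, `seg_var_min`, `seg_cf` and `seg_shadow`.
#' @param init_frame Optional first frame (height x width matrix in [0,1])
#'   used to seed the dominant component at each pixel.
#' @return Object of class `background_model`.
#' @export
background_model <- function(width, height, cfg = agility_config(width, height),
                             init_frame = NULL) {
  K <- as.integer(cfg$seg_components)
  stopifnot(K >= 1, width >= 1, height >= 1)
  N <- as.numeric(height) * width
  bg <- new.env(parent = emptyenv())
  bg$width <- as.integer(width)
  bg$height <- as.integer(height)
  bg$K <- K
  bg$cfg <- cfg
  bg$w <- rep(c(1, rep(0, K - 1)), N)
  mu0 <- if (is.null(init_frame)) 0.5 else {
    stopifnot(nrow(init_frame) == height, ncol(init_frame) == width)
    as.numeric(init_frame)
  }
  bg$mu <- as.numeric(rbind(matrix(mu0, nrow = 1), matrix(0, K - 1, N)))
  bg$var <- rep(c(cfg$seg_var_init, rep(0, K - 1)), N)
  class(bg) <- "background_model"
  bg
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Gaussian-mixture background model: %dx%d px, %d components\n",
              x$width, x$height, x$K))
  cat(sprintf("  learning rate %.4g, match threshold %.3g\n",
              x$cfg$seg_alpha, x$cfg$seg_threshold))
  invisible(x)
}

#' Update the background model and extract the foreground mask
#'
#' Advances the per-pixel mixture with the new frame and returns the binary
#' foreground mask after (in order) scenario masking, morphological opening
#' and closing, and small-blob removal.  Pixels outside the scenario mask
#' are always background.
#'
#' @param bg A `background_model` (updated in place).
#' @param frame height x width numeric matrix, intensities in [0, 1].
#' @param scenario_mask Optional logical matrix of the same size; `FALSE`
#'   pixels are forced to background before cleanup.
#' @param learning_rate Override of the configured mean/variance learning
#'   rate (must lie in [0, 1]).
#' @param raw If `TRUE`, skip all cleanup and return the raw mixture mask.
#' @param details If `TRUE`, return `list(mask, stats)` where `stats` is the
#'   connected-component table (area and bounding box per blob, largest
#'   first) so downstream stages need not relabel the mask.
#' @return Logical foreground mask (height x width), or a list when
#'   `details = TRUE`.
#' @export
update_background <- function(bg, frame, scenario_mask = NULL,
                              learning_rate = NULL, raw = FALSE,
                              details = FALSE) {
  stopifnot(inherits(bg, "background_model"))
  if (!is.matrix(frame) || nrow(frame) != bg$height || ncol(frame) != bg$width)
    stop("frame dimensions do not match the background model")
  alpha <- if (is.null(learning_rate)) bg$cfg$seg_alpha else learning_rate
  if (alpha < 0 || alpha > 1) stop("learning rate must lie in [0, 1]")
  cfg <- bg$cfg
  aw <- if (is.null(cfg$seg_alpha_w)) alpha else cfg$seg_alpha_w
  mask <- mog_apply(bg$w, bg$mu, bg$var, frame, bg$K, alpha, aw,
                    cfg$seg_threshold, cfg$seg_cf, cfg$seg_var_init,
                    cfg$seg_var_min, cfg$seg_var_max,
                    !is.null(cfg$seg_shadow),
                    cfg$seg_shadow[1], cfg$seg_shadow[2])
  if (!is.null(scenario_mask)) {
    stopifnot(all(dim(scenario_mask) == dim(mask)))
    mask <- mask & scenario_mask
  }
  if (raw) return(mask)
  mask <- bin_open(mask, cfg$morph_open)
  mask <- bin_close(mask, cfg$morph_close)
  min_area <- cfg$min_blob_frac * bg$height * bg$width
  res <- mask_components(mask, min_area)
  if (details) res else res$mask
}

#' Extract the silhouette and feet regions of interest
#'
#' The silhouette box is the bounding box of the largest connected
#' foreground component (subject to the minimum-area filter); the feet box
#' is its bottom fraction (default 20%), full x-extent, bottom aligned —
#' the region where the feet and lower legs project.
#'
#' @param mask Logical foreground mask.
#' @param min_area Minimum component area in pixels to count as a
#'   silhouette; defaults to 0.1% of the frame.
#' @param feet_frac Fraction of the silhouette height kept (default 0.2).
#' @param stats Optional precomputed component table (from
#'   [update_background()] with `details = TRUE`); avoids relabelling.
#' @return List with `silhouette` and `feet`, each `c(x, y, w, h)` in
#'   0-based pixels, or both `NULL` when no component passes the filter.
#' @export
extract_feet_roi <- function(mask, min_area = NULL, feet_frac = 0.2,
                             stats = NULL) {
  if (is.null(min_area)) min_area <- 0.001 * length(mask)
  st <- if (is.null(stats)) mask_components(mask, min_area)$stats else stats
  st <- st[st[, "area"] >= min_area, , drop = FALSE]
  if (nrow(st) == 0) return(list(silhouette = NULL, feet = NULL))
  sil <- c(x = unname(st[1, "x"]), y = unname(st[1, "y"]),
           w = unname(st[1, "w"]), h = unname(st[1, "h"]))
  fh <- max(1, round(feet_frac * sil["h"]))
  feet <- c(x = unname(sil["x"]), y = unname(sil["y"] + sil["h"] - fh),
            w = unname(sil["w"]), h = unname(fh))
  list(silhouette = sil, feet = feet)
}

#' Discriminate separated feet from a self-occlusion
#'
#' Labels the connected components inside the feet box.  Two components of
#' comparable area mean the feet are separated (boxes ordered left/right by
#' horizontal centre); a single dominant component is a self-occlusion
#' (feet-crossing) with one merged box; no component above the area floor
#' means the feet are absent from the box.
#'
#' @param mask Logical foreground mask (full frame).
#' @param feet_box Feet region `c(x, y, w, h)` (0-based pixels).
#' @param min_foot_area Minimum component area (px) to count as a foot.
#' @param comparable_ratio Smaller/larger area ratio above which two
#'   components count as two feet (default 0.2).
#' @return List with `mode` (`"SEPARATED"`, `"OCCLUDED"`, `"ABSENT"`) and
#'   boxes `left`, `right` (separated) or `merged` (occluded), all in
#'   full-frame 0-based pixel coordinates.
#' @export
discriminate_feet <- function(mask, feet_box, min_foot_area = 12,
                              comparable_ratio = 0.2) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- (feet_box["y"] + 1):(feet_box["y"] + feet_box["h"])
  cols <- (feet_box["x"] + 1):(feet_box["x"] + feet_box["w"])
  rows <- rows[rows >= 1 & rows <= nr]
  cols <- cols[cols >= 1 & cols <= nc]
  if (!length(rows) || !length(cols)) stop("feet box lies outside the mask")
  sub <- mask[rows, cols, drop = FALSE]
  if (!any(sub)) return(list(mode = "ABSENT"))
  st <- mask_components(sub, min_foot_area)$stats
  if (nrow(st) == 0) return(list(mode = "ABSENT"))
  # translate sub-window coords to full-frame coords
  boxes <- lapply(seq_len(nrow(st)), function(i)
    c(x = unname(st[i, "x"] + cols[1] - 1),
      y = unname(st[i, "y"] + rows[1] - 1),
      w = unname(st[i, "w"]), h = unname(st[i, "h"])))
  if (nrow(st) >= 2 && st[2, "area"] / st[1, "area"] >= comparable_ratio) {
    b1 <- boxes[[1]]; b2 <- boxes[[2]]
    c1 <- b1["x"] + b1["w"] / 2
    c2 <- b2["x"] + b2["w"] / 2
    if (c1 <= c2) list(mode = "SEPARATED", left = b1, right = b2)
    else          list(mode = "SEPARATED", left = b2, right = b1)
  } else {
    list(mode = "OCCLUDED", merged = boxes[[1]])
  }
}

#' Form the per-foot measurements from a feet observation
#'
#' Each measurement is `[x, y, w, h]` where `(x, y)` is the bounding box's
#' bottom-centre — the point of the foot that projects onto the floor plane
#' — and `(w, h)` its size.  When the feet are separated each box yields its
#' own measurement; in a self-occlusion the merged box is split vertically
#' in half, the left half measuring the left foot and the right half the
#' right foot, so both filters stay anchored through the crossing.
#'
#' When the foreground `mask` is supplied, each half's bottom is refined to
#' the lowest foreground row within that half's columns instead of the
#' merged box's shared bottom.  Feet merged while standing at different
#' depths (one behind the other, as at the far targets) then keep their own
#' ground rows: with the shared bottom, the nearer foot's row would mask
#' the farther foot's depth entirely.
#'
#' @param obs Observation from [discriminate_feet()].
#' @param mask Optional logical foreground mask (full frame) used to refine
#'   occluded-half bottoms.
#' @return List with `left` and `right` measurements (each numeric length
#'   4), or `NULL` when the observation is `ABSENT`.
#' @export
measure_feet <- function(obs, mask = NULL) {
  box_z <- function(b) c(unname(b["x"] + b["w"] / 2),
                         unname(b["y"] + b["h"]),
                         unname(b["w"]), unname(b["h"]))
  switch(obs$mode,
    ABSENT = NULL,
    SEPARATED = list(left = box_z(obs$left), right = box_z(obs$right)),
    OCCLUDED = {
      b <- obs$merged
      half <- b["w"] / 2
      half_z <- function(x0) {
        y_bot <- unname(b["y"] + b["h"])
        if (!is.null(mask)) {
          cols <- floor(x0 + 1):ceiling(x0 + half)
          cols <- cols[cols >= 1 & cols <= ncol(mask)]
          rows <- (b["y"] + 1):(b["y"] + b["h"])
          rows <- rows[rows >= 1 & rows <= nrow(mask)]
          if (length(cols) && length(rows)) {
            rr <- which(rowSums(mask[rows, cols, drop = FALSE]) > 0)
            if (length(rr)) y_bot <- unname(b["y"]) + max(rr)
          }
        }
        c(unname(x0 + half / 2), y_bot, unname(half), unname(b["h"]))
      }
      list(left = half_z(unname(b["x"])),
           right = half_z(unname(b["x"] + half)))
    },
    stop("unknown observation mode: ", obs$mode)
  )
}

#' Build a scenario mask from a pixel polygon
#'
#' The scenario mask restricts segmentation to the training-platform area of
#' the image.  Given the polygon of the platform's ground footprint, the
#' mask keeps the polygon interior and, for every image column the polygon
#' touches, everything above its lower boundary (so the standing player's
#' body is retained).
#'
#' @param poly n x 2 matrix of pixel vertices `(x, y)`, 0-based.
#' @param width,height Frame size.
#' @param extend_up Keep all rows above the polygon in covered columns
#'   (default `TRUE`).
#' @return Logical height x width mask.
#' @export
scenario_mask_from_polygon <- function(poly, width, height, extend_up = TRUE) {
  poly <- as.matrix(poly)
  px <- rep(0:(width - 1), each = height)
  py <- rep(0:(height - 1), times = width)
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  m <- matrix(inside, nrow = height, ncol = width)
  if (extend_up) {
    for (cc in seq_len(width)) {
      r <- which(m[, cc])
      if (length(r)) m[1:max(r), cc] <- TRUE
    }
  }
  m
}

#' Scenario mask from the calibrated platform geometry
#'
#' Projects the platform's ground footprint (grid extent plus a margin)
#' through the calibration homography and builds the pixel mask.
#'
#' @param h A `homography` (pixel to platform).
#' @param pm A `platform_model`.
#' @param width,height Frame size.
#' @param margin Extra metres kept around the outer target centres.
#' @return Logical height x width mask.
#' @export
scenario_mask_from_platform <- function(h, pm, width, height, margin = 0.8) {
  ext <- pm$spacing + margin
  corners <- rbind(c(-ext, ext), c(ext, ext), c(ext, -ext), c(-ext, -ext))
  poly <- platform_to_pixel(h, corners)
  scenario_mask_from_polygon(poly, width, height)
}
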