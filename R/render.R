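#' Rendering parameters for synthetic backlit arena stacks
#'
#' The assay backlights the arena so worms appear as dark blobs on a
#' bright background. Intensities are on the 0-255 scale; the worm must
#' be at least 50 intensity units darker than the background to preserve
#' backlit contrast.
#'
#' @param mm_per_px Spatial scale of the rendered image.
#' @param background Background intensity (default 200).
#' @param worm Worm intensity (default 40).
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise.
#' @param aspect Worm length:width ratio (default 5).
#' @return An object of class `render_params`.
#' @export
render_params <- function(mm_per_px = 0.25, background = 200, worm = 40,
                          noise_sd = 3, aspect = 5) {
  stopifnot(mm_per_px > 0, noise_sd >= 0, aspect > 0)
  if (background - worm < 50)
    stop("worm must be at least 50 intensity units darker than background")
  structure(list(mm_per_px = as.numeric(mm_per_px),
                 background = as.numeric(background),
                 worm = as.numeric(worm),
                 noise_sd = as.numeric(noise_sd),
                 aspect = as.numeric(aspect)),
            class = "render_params")
}

# Paint a filled rotated ellipse (worm body) into an intensity matrix.
# Center (y_mm, x_mm); major axis along the heading. Pixel i has center
# (i - 0.5) * mm_per_px. Only the bounding box of the ellipse is touched.
paint_worm <- function(img, y_mm, x_mm, heading_rad, body_length_mm,
                       rp) {
  s <- rp$mm_per_px
  a <- body_length_mm / 2
  b <- a / rp$aspect
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor((y_mm - a) / s)); r1 <- min(nr, ceiling((y_mm + a) / s) + 1L)
  c0 <- max(1L, floor((x_mm - a) / s)); c1 <- min(nc, ceiling((x_mm + a) / s) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  yy <- (rows - 0.5) * s - y_mm
  xx <- (cols - 0.5) * s - x_mm
  Y <- matrix(yy, length(rows), length(cols))
  X <- matrix(xx, length(rows), length(cols), byrow = TRUE)
  # axial/transverse coordinates in the worm frame
  ca <- cos(heading_rad); sa <- sin(heading_rad)
  U <- X * ca + Y * sa
  V <- -X * sa + Y * ca
  inside <- (U / a)^2 + (V / b)^2 <= 1
  sub <- img[rows, cols, drop = FALSE]
  sub[inside] <- rp$worm
  img[rows, cols] <- sub
  img
}

#' Render a trajectory into a backlit image stack
#'
#' Draws each visible frame as one filled dark ellipse (major axis equal
#' to the worm's body length, oriented along its current heading) on a
#' bright noisy background; invisible frames contain background only. A
#' separate worm-free background frame is rendered for background
#' subtraction, mirroring the assay's practice of recording a background
#' image at the start of each experiment.
#'
#' Image layout: rows correspond to the arena's axial coordinate `y`
#' (row 1 toward `y = 0`), columns to the transverse coordinate `x`. The
#' frame extends beyond the trough by half a body length on every side,
#' mirroring the slack left when rectangles are drawn around each arena;
#' this keeps the worm's silhouette whole when it hugs a wall (the rigid
#' ellipse does not model body flexion against the trough sides). The
#' returned `origin_mm` gives the arena coordinate offset of the pixel
#' grid; pass it to [track_com()] to map centroids back to arena
#' coordinates.
#'
#' @param traj A `worm_trajectory` (must carry `params` and `arena`
#'   attributes, as produced by [simulate_trajectory()]).
#' @param rp A `render_params` object.
#' @param arena An `arena_geometry`; defaults to the trajectory's.
#' @param seed Integer seed for the pixel noise.
#' @return A list with `frames` (a `nrow x ncol x nframes` numeric array,
#'   intensities in 0-255), `background` (matrix), `origin_mm` (named
#'   vector `c(y, x)`), and `rp`.
#' @export
render_frames <- function(traj, rp, arena = attr(traj, "arena"), seed = 1) {
  stopifnot(inherits(rp, "render_params"), inherits(arena, "arena_geometry"))
  params <- attr(traj, "params")
  if (is.null(params)) stop("trajectory carries no worm_params attribute")
  s <- rp$mm_per_px
  margin_px <- as.integer(ceiling(params$body_length_mm / 2 / s))
  nr <- as.integer(ceiling(arena$length_mm / s)) + 2L * margin_px
  nc <- as.integer(ceiling(arena$top_width_mm / s)) + 2L * margin_px
  if (params$body_length_mm / s > min(nr, nc) * 2)
    stop("worm is larger than the arena image")
  origin <- c(y = margin_px * s, x = margin_px * s)
  set.seed(as.integer(seed))
  n <- nrow(traj)
  frames <- array(0, dim = c(nr, nc, n))
  background <- rp$background +
    matrix(stats::rnorm(nr * nc, 0, rp$noise_sd), nr, nc)
  for (j in seq_len(n)) {
    img <- matrix(rp$background, nr, nc)
    if (traj$visible[j])
      img <- paint_worm(img, traj$y_mm[j] + origin[["y"]],
                        traj$x_mm[j] + origin[["x"]],
                        traj$heading_rad[j], params$body_length_mm, rp)
    if (rp$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, rp$noise_sd), nr, nc)
    frames[, , j] <- img
  }
  frames[frames < 0] <- 0
  frames[frames > 255] <- 255
  background[background < 0] <- 0
  background[background > 255] <- 255
  list(frames = frames, background = background, origin_mm = origin,
       rp = rp)
}
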