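#' Arena regions of interest
#'
#' Equal-sized, non-overlapping rectangles marking each arena inside a
#' composite multi-arena frame, in 1-based pixel coordinates
#' (`row0`/`col0` top-left corner, `height`/`width` extents).
#'
#' @param row0,col0 Integer vectors of top-left corners (1-based).
#' @param height,width Scalar rectangle extents in px (equal for all
#'   ROIs).
#' @return A data frame of class `arena_roi` with one row per arena.
#' @export
arena_roi <- function(row0, col0, height, width) {
  stopifnot(length(row0) == length(col0), height >= 1, width >= 1)
  structure(data.frame(arena = seq_along(row0) - 1L,
                       row0 = as.integer(row0), col0 = as.integer(col0),
                       height = as.integer(height),
                       width = as.integer(width)),
            class = c("arena_roi", "data.frame"))
}

rects_overlap <- function(r) {
  n <- nrow(r)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (r$row0[i] < r$row0[j] + r$height[j] &&
        r$row0[j] < r$row0[i] + r$height[i] &&
        r$col0[i] < r$col0[j] + r$width[j] &&
        r$col0[j] < r$col0[i] + r$width[i]) return(TRUE)
  }
  FALSE
}

#' Split a composite stack into per-arena stacks
#'
#' Crops each ROI rectangle out of every frame, preserving pixel values,
#' so a recording of several side-by-side troughs becomes one stack per
#' arena.
#'
#' @param stack A `nrow x ncol x nframes` array (or a matrix for a single
#'   frame).
#' @param rois An `arena_roi` data frame.
#' @return A list of cropped arrays, one per ROI, in ROI order.
#' @export
split_arenas <- function(stack, rois) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  if (any(rois$row0 < 1 | rois$col0 < 1 |
          rois$row0 + rois$height - 1 > nr |
          rois$col0 + rois$width - 1 > nc))
    stop("ROI exceeds frame bounds")
  if (rects_overlap(rois)) stop("ROIs overlap")
  lapply(seq_len(nrow(rois)), function(i) {
    r <- rois$row0[i]:(rois$row0[i] + rois$height[i] - 1L)
    cl <- rois$col0[i]:(rois$col0[i] + rois$width[i] - 1L)
    stack[r, cl, , drop = FALSE]
  })
}

#' Subtract the arena background from a stack
#'
#' Per-pixel absolute difference between each frame and the worm-free
#' background frame, so a dark worm on a bright background becomes a
#' bright blob on a near-zero background.
#'
#' @param stack A `nrow x ncol x nframes` array.
#' @param background A matrix with the same row/column dimensions.
#' @return An array of absolute differences.
#' @export
subtract_background <- function(stack, background) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  d <- dim(stack)
  if (!all(dim(background) == d[1:2]))
    stop("background dimensions do not match the stack")
  abs(stack - as.vector(background))
}

#' Threshold a difference image
#'
#' @param frame A numeric matrix (difference image).
#' @param threshold Intensity threshold; pixels strictly above it are
#'   foreground.
#' @return A logical mask.
#' @export
binarize <- function(frame, threshold) frame > threshold

#' Automatic threshold for a difference stack
#'
#' Otsu's method applied to the pixelwise maximum difference projection
#' over up to `max_frames` evenly spaced frames. The maximum projection
#' contains the worm's whole trail, so its histogram is strongly bimodal
#' (background noise vs. worm contrast) wherever the worm moved, making
#' Otsu's split stable; a median projection would mostly contain noise,
#' since the worm rarely occupies one pixel in more than half the
#' frames. This replaces the manual per-experiment threshold of the
#' original workflow with a deterministic, parameter-free default; a
#' fixed scalar can always be supplied instead.
#'
#' @param diff_stack Background-subtracted array.
#' @param max_frames Number of frames entering the projection
#'   (default 101).
#' @return A scalar threshold on the 0-255 intensity scale.
#' @export
auto_threshold <- function(diff_stack, max_frames = 101) {
  nf <- dim(diff_stack)[3]
  idx <- unique(round(seq(1, nf, length.out = min(max_frames, nf))))
  proj <- apply(diff_stack[, , idx, drop = FALSE], c(1, 2), max)
  proj <- pmin(pmax(proj, 0), 255)
  255 * EBImage::otsu(EBImage::Image(proj / 255), range = c(0, 1))
}

# Label connected components with 8-connectivity: EBImage::bwlabel is
# 4-connected, so labels touching diagonally are merged afterwards.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left diagonal pairs
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                        pairs[, 1] != pairs[, 2], , drop = FALSE])
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(nlab)
  for (k in seq_len(nrow(pairs))) {
    ra <- pairs[k, 1]; rb <- pairs[k, 2]
    while (parent[ra] != ra) ra <- parent[ra]
    while (parent[rb] != rb) rb <- parent[rb]
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- seq_len(nlab)
  for (i in seq_len(nlab)) { r <- i; while (parent[r] != r) r <- parent[r]; root[i] <- r }
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

#' Track the worm's centre of mass through a per-arena stack
#'
#' For each frame: subtract the background, binarize, keep the largest
#' 8-connected component, and if its pixel area reaches `min_area_px`
#' record the unweighted centroid of the mask (a thresholded
#' particle-style centroid, not intensity weighted) converted to mm;
#' otherwise the frame is marked invisible and the position is missing.
#'
#' `min_area_px = NULL` uses 25% of the median blob area over frames that
#' contain any blob, which rejects noise specks while keeping partially
#' occluded worms.
#'
#' @param stack A `nrow x ncol x nframes` array for one arena.
#' @param background The worm-free background frame.
#' @param config An `experiment_config`; supplies `fps` and `mm_per_px`.
#' @param threshold Intensity threshold; `NULL` selects it automatically
#'   with [auto_threshold()].
#' @param min_area_px Minimum blob area in px; `NULL` for the adaptive
#'   default.
#' @param worm_id Identifier for the output trajectory.
#' @param origin_mm Arena coordinate of the image's top-left pixel edge,
#'   as `c(y, x)` in mm; use the `origin_mm` returned by
#'   [render_frames()] when the frame includes a margin around the
#'   trough.
#' @return A `worm_trajectory` data frame (no `heading_rad` column;
#'   positions are `NA` on invisible frames).
#' @export
track_com <- function(stack, background, config, threshold = NULL,
                      min_area_px = NULL, worm_id = "worm-1",
                      origin_mm = c(y = 0, x = 0)) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  dstack <- subtract_background(stack, background)
  if (is.null(threshold)) threshold <- auto_threshold(dstack)
  n <- dim(dstack)[3]
  s <- config$mm_per_px
  areas <- integer(n)
  blobs <- vector("list", n)
  for (j in seq_len(n)) {
    mask <- dstack[, , j] > threshold
    if (!any(mask)) { areas[j] <- 0L; next }
    lab <- label_components(mask)
    tab <- tabulate(lab[lab > 0])
    big <- which.max(tab)
    areas[j] <- tab[big]
    blobs[[j]] <- which(lab == big, arr.ind = TRUE)
  }
  if (is.null(min_area_px)) {
    nz <- areas[areas > 0]
    min_area_px <- if (length(nz)) max(5, 0.25 * stats::median(nz)) else 5
  }
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  visible <- areas >= min_area_px
  for (j in which(visible)) {
    y[j] <- (mean(blobs[[j]][, 1]) - 0.5) * s - origin_mm[[1]]
    x[j] <- (mean(blobs[[j]][, 2]) - 0.5) * s - origin_mm[[2]]
  }
  traj <- data.frame(worm_id = worm_id, frame = seq_len(n) - 1L,
                     t_s = (seq_len(n) - 1L) / config$fps,
                     x_mm = x, y_mm = y, visible = visible,
                     stringsAsFactors = FALSE)
  structure(traj, config = config, threshold = threshold,
            min_area_px = min_area_px,
            class = c("worm_trajectory", "data.frame"))
}
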