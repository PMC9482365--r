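#' Worm behavioural parameters for the trajectory simulator
#'
#' Parameterises one simulated planarian. Size classes follow the assay's
#' length bins: small 2.0-3.5 mm, medium 4.6-7.5 mm, large 7.6-12.4 mm;
#' the default body length of each class is the midpoint of its bin.
#' Default gliding speeds are 1.02 mm/s (small) and 1.70 mm/s (large),
#' with medium interpolated at 1.36 mm/s.
#'
#' @param size_class `"small"`, `"medium"` or `"large"`; sets defaults for
#'   `body_length_mm` and `speed_mm_s`.
#' @param body_length_mm Body length in mm, within `[2.0, 12.4]`.
#' @param speed_mm_s Gliding speed in mm/s (> 0).
#' @param electrotaxis_bias Weight of the drift toward the current
#'   cathode, in `[0, 1]`: 0 is an unbiased walk, 1 is pure drift
#'   (implemented as the per-step probability of orienting toward the
#'   cathode).
#' @param persistence Direction correlation between successive walk
#'   steps, in `[0, 1)`. The default 0.9 (a ~1 s heading correlation
#'   time at 8 fps) reproduces gliding runs long enough that unbiased
#'   worms explore the whole trough within a 120 s trial, as 0 V
#'   animals do.
#' @param wall_affinity Weight of attraction toward the nearer long wall
#'   (transverse axis only), in `[0, 1]`.
#' @param head_body_area_ratio Head area divided by whole-body area, in
#'   `[0, 1)`; used by the renderer/morphometrics fixtures and by the
#'   head-regression scenario preset.
#' @param blind_zone_mm Distance from either electrode within which the
#'   worm is occluded by the electrode and invisible to the camera
#'   (default 3 mm, the electrode thickness).
#' @return An object of class `worm_params`.
#' @export
worm_params <- function(size_class = c("large", "medium", "small"),
                        body_length_mm = NULL, speed_mm_s = NULL,
                        electrotaxis_bias = 0, persistence = 0.9,
                        wall_affinity = 0, head_body_area_ratio = 0.2,
                        blind_zone_mm = 3) {
  size_class <- match.arg(size_class)
  defaults <- list(small  = c(len = 2.75, spd = 1.02),
                   medium = c(len = 6.00, spd = 1.36),
                   large  = c(len = 10.0, spd = 1.70))[[size_class]]
  if (is.null(body_length_mm)) body_length_mm <- defaults[["len"]]
  if (is.null(speed_mm_s)) speed_mm_s <- defaults[["spd"]]
  stopifnot(body_length_mm >= 2.0, body_length_mm <= 12.4,
            speed_mm_s > 0,
            electrotaxis_bias >= 0, electrotaxis_bias <= 1,
            persistence >= 0, persistence < 1,
            wall_affinity >= 0, wall_affinity <= 1,
            head_body_area_ratio >= 0, head_body_area_ratio < 1,
            blind_zone_mm >= 0)
  structure(list(size_class = size_class,
                 body_length_mm = as.numeric(body_length_mm),
                 speed_mm_s = as.numeric(speed_mm_s),
                 electrotaxis_bias = as.numeric(electrotaxis_bias),
                 persistence = as.numeric(persistence),
                 wall_affinity = as.numeric(wall_affinity),
                 head_body_area_ratio = as.numeric(head_body_area_ratio),
                 blind_zone_mm = as.numeric(blind_zone_mm)),
            class = "worm_params")
}

# Reflect positions into [0, hi], mirroring at both boundaries.
reflect_into <- function(v, hi) {
  v <- abs(v)
  over <- v > hi
  v[over] <- 2 * hi - v[over]
  pmin(pmax(v, 0), hi)
}

#' Simulate one worm trajectory
#'
#' Discrete-time biased persistent random walk in the arena plane. At
#' each frame the worm either orients its step straight toward the
#' current cathode (with probability `electrotaxis_bias`) or takes a
#' persistent random-walk step: a normalised blend of the
#' persistence-weighted previous walk heading, a uniformly random turn,
#' and a transverse wall-attraction component. The per-step heading is
#' therefore the mixture `(1 - bias) * walk + bias * toward-cathode`,
#' taken at the step level so the response in the bias stays graded
#' (expected toward-cathode step fraction `(1 + bias) / 2`) instead of
#' saturating through the heading memory. The bias direction flips at
#' the polarity swap. The step length is `speed_mm_s / fps` and
#' boundaries reflect. The worm is released at the trough midpoint and
#' is marked invisible whenever its axial position lies within
#' `blind_zone_mm` of either electrode.
#'
#' @param params A `worm_params` object.
#' @param config An `experiment_config`.
#' @param arena An `arena_geometry`.
#' @param seed Integer seed; the same seed reproduces the trajectory
#'   exactly.
#' @param worm_id Identifier stored in the trajectory table.
#' @return A `worm_trajectory`: a data frame with columns `worm_id`,
#'   `frame` (0-based), `t_s`, `x_mm`, `y_mm`, `heading_rad`, `visible`,
#'   carrying `params`, `config` and `arena` as attributes.
#' @examples
#' traj <- simulate_trajectory(worm_params(electrotaxis_bias = 0.8),
#'                             experiment_config(2, 120), arena_geometry(),
#'                             seed = 1)
#' head(traj)
#' @export
simulate_trajectory <- function(params, config, arena, seed,
                                worm_id = "worm-1") {
  stopifnot(inherits(params, "worm_params"),
            inherits(config, "experiment_config"),
            inherits(arena, "arena_geometry"))
  set.seed(as.integer(seed))
  n_steps <- round(config$duration_s * config$fps)
  n <- n_steps + 1L
  t_s <- (0:n_steps) / config$fps
  phase <- frame_phase(t_s, config)
  L <- arena$length_mm
  W <- arena$top_width_mm
  step <- params$speed_mm_s / config$fps
  b <- params$electrotaxis_bias
  p <- params$persistence
  wa <- params$wall_affinity

  x <- numeric(n); y <- numeric(n); hd <- numeric(n)
  x[1] <- W / 2
  y[1] <- L / 2
  theta0 <- stats::runif(1, 0, 2 * pi)
  hx <- cos(theta0); hy <- sin(theta0)
  hd[1] <- theta0
  turns <- stats::runif(n_steps, 0, 2 * pi)
  reorient <- stats::runif(n_steps) < b

  for (j in seq_len(n_steps)) {
    cat_y <- cathode_y(phase[j + 1L], config, arena)
    uy_cat <- if (cat_y <= y[j]) -1 else 1
    # persistent random-walk state advances every frame; the taxis drift
    # never enters the heading memory, so the dose-response in the bias
    # stays graded instead of compounding
    rx <- p * hx + (1 - p) * cos(turns[j])
    ry <- p * hy + (1 - p) * sin(turns[j])
    nr <- sqrt(rx^2 + ry^2)
    if (nr < 1e-12) { rx <- cos(turns[j]); ry <- sin(turns[j]); nr <- 1 }
    rx <- rx / nr; ry <- ry / nr
    if (reorient[j]) {
      dx <- 0; dy <- uy_cat
    } else {
      # transverse wall attraction (toward the nearer long wall)
      wx <- if (x[j] < W / 2) -1 else 1
      dx <- rx + wa * wx
      dy <- ry
      nd <- sqrt(dx^2 + dy^2)
      if (nd < 1e-12) { dx <- rx; dy <- ry; nd <- 1 }
      dx <- dx / nd; dy <- dy / nd
    }
    xn <- x[j] + step * dx
    yn <- y[j] + step * dy
    # reflect position, the motion direction and the walk state at walls
    if (xn < 0 || xn > W) { dx <- -dx; rx <- -rx }
    if (yn < 0 || yn > L) { dy <- -dy; ry <- -ry }
    x[j + 1L] <- reflect_into(xn, W)
    y[j + 1L] <- reflect_into(yn, L)
    hx <- rx; hy <- ry
    hd[j + 1L] <- atan2(dy, dx)
  }

  bz <- params$blind_zone_mm
  visible <- y >= bz & y <= L - bz
  traj <- data.frame(worm_id = worm_id, frame = 0:n_steps, t_s = t_s,
                     x_mm = x, y_mm = y, heading_rad = hd,
                     visible = visible, stringsAsFactors = FALSE)
  structure(traj, params = params, config = config, arena = arena,
            class = c("worm_trajectory", "data.frame"))
}

#' Simulate a cohort of worms over a factorial design
#'
#' Expands a design (a list of cells, each with a worm count, worm
#' parameters, an experiment configuration and a label) into one
#' trajectory per worm. Per-worm seeds are child seeds drawn once from
#' the master seed, so the full cohort is reproducible and each worm's
#' trajectory is independent of cohort size ordering.
#'
#' @param design A list of cells; each cell is a list with elements `n`
#'   (worm count), `params` (`worm_params`), `config`
#'   (`experiment_config`) and optionally `label` (design-cell label).
#' @param arena An `arena_geometry` shared by all cells.
#' @param seed Master integer seed.
#' @return A list of `worm_trajectory` objects; each carries a `label`
#'   attribute for downstream ANOVA.
#' @export
generate_cohort <- function(design, arena, seed) {
  if (length(design) == 0) stop("design must contain at least one cell")
  n_total <- sum(vapply(design, function(cell) as.integer(cell$n), 1L))
  set.seed(as.integer(seed))
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  out <- vector("list", n_total)
  k <- 0L
  for (ci in seq_along(design)) {
    cell <- design[[ci]]
    label <- if (is.null(cell$label)) paste0("cell", ci) else cell$label
    for (w in seq_len(cell$n)) {
      k <- k + 1L
      id <- sprintf("%s-w%02d", label, w)
      traj <- simulate_trajectory(cell$params, cell$config, arena,
                                  seed = child_seeds[k], worm_id = id)
      attr(traj, "label") <- label
      out[[k]] <- traj
    }
  }
  out
}

#' Synthetic worm silhouette with a known head boundary
#'
#' Builds a binary worm mask (an ellipse, optionally tapered toward the
#' anterior end) aligned with the image row axis, together with the
#' ground-truth axial position of the head/body boundary. Intended as a
#' fixture for morphometric code: the true head fraction is known by
#' construction.
#'
#' @param body_length_mm Worm length in mm.
#' @param head_fraction Fraction of the axial extent, measured from the
#'   anterior (low-row) end, that is head; in `(0, 1)`.
#' @param mm_per_px Spatial scale.
#' @param aspect Length:width ratio of the ellipse (default 5).
#' @param taper Anterior tapering strength in `[0, 1)`: 0 gives a plain
#'   ellipse; larger values narrow the anterior tip linearly.
#' @return A list with `mask` (logical matrix, worm axis along rows,
#'   anterior at row 1), `cut_row_px` (head boundary as a row coordinate,
#'   in pixels from the anterior mask edge), and `head_fraction`.
#' @export
synth_worm_mask <- function(body_length_mm, head_fraction, mm_per_px,
                            aspect = 5, taper = 0) {
  stopifnot(head_fraction > 0, head_fraction < 1, mm_per_px > 0,
            taper >= 0, taper < 1)
  a <- body_length_mm / 2 / mm_per_px          # semi-major axis, px
  b <- a / aspect                              # semi-minor axis, px
  nr <- ceiling(2 * a) + 4L
  nc <- ceiling(2 * b) + 4L
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r <- matrix(seq_len(nr), nr, nc) - cr
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  u <- r / a                                   # normalised axial coord [-1,1]
  half_width <- b * sqrt(pmax(0, 1 - u^2))
  # taper the anterior (u < 0) half linearly toward the tip
  tf <- ifelse(u < 0, 1 - taper * (-u), 1)
  mask <- abs(cl) <= half_width * tf & abs(u) <= 1
  rows_in <- which(rowSums(mask) > 0)
  r0 <- min(rows_in); r1 <- max(rows_in)
  cut_row_px <- head_fraction * (r1 - r0 + 1)
  list(mask = mask, cut_row_px = cut_row_px, anterior_row = r0,
       head_fraction = head_fraction, mm_per_px = mm_per_px)
}
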