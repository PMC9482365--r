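#' Electrotaxis metrics
#'
#' The assay's per-worm response metrics, computed separately before
#' ("1") and after ("2") the polarity swap:
#'
#' * `f_cat-1/2` — fraction of phase time spent in the quadrant containing
#'   the current cathode.
#' * `f_mov-1/2` — fraction of visible phase frames in which the worm's
#'   axial coordinate moved strictly closer to the current cathode than
#'   in the previous frame.
#' * quadrant occupancies for the cathode quadrant, the middle two
#'   quadrants, and the anode quadrant, per phase.
#' * mean gliding speed over consecutive visible frame pairs.
#'
#' Conventions: scoring transforms the axial coordinate so the current
#' cathode sits at 0. Ties (no strict approach) do not count toward
#' `f_mov`; the first frame of a phase enters the denominator but never
#' the numerator; the denominator of `f_mov` is the number of visible
#' frames in the phase. Worms are invisible while touching an electrode,
#' so occupancy attributes invisible frames to the last known quadrant;
#' frames before the first detection are unattributed and excluded from
#' occupancy denominators.
#'
#' @name electrotaxis-metrics
NULL

phase_of <- function(traj, config) frame_phase(traj$t_s, config)

# distance to the current cathode, per frame
dist_to_cathode <- function(traj, config, arena) {
  ph <- phase_of(traj, config)
  cat_pos <- vapply(ph, cathode_y, 0, config = config, arena = arena)
  abs(traj$y_mm - cat_pos)
}

# quadrant attributed to each frame: observed when visible, else carried
# from the last visible frame; NA before first detection. Tracked
# positions may overshoot the arena by sub-pixel noise, so they are
# clamped into [0, L] before the quadrant lookup.
attributed_quadrant <- function(traj, arena) {
  q <- rep(NA_integer_, nrow(traj))
  vis <- traj$visible & !is.na(traj$y_mm)
  q[vis] <- quadrant_index(pmin(pmax(traj$y_mm[vis], 0), arena$length_mm),
                           arena)
  if (!any(vis)) return(q)
  # carry last observation forward
  idx <- cummax(ifelse(vis, seq_along(q), 0L))
  q[idx > 0] <- q[idx[idx > 0]]
  q
}

#' Fraction of time moving toward the cathode, per phase
#'
#' @param traj A `worm_trajectory` (ordered frames).
#' @param config An `experiment_config`.
#' @param arena An `arena_geometry`.
#' @return Named numeric vector `c(f_mov_1, f_mov_2)`; an element is `NA`
#'   when its phase has no visible frames (and `f_mov_2` is `NA` for
#'   no-swap runs).
#' @export
f_mov <- function(traj, config, arena) {
  if (nrow(traj) == 0) stop("empty trajectory")
  ph <- phase_of(traj, config)
  d <- dist_to_cathode(traj, config, arena)
  vis <- traj$visible & !is.na(traj$y_mm)
  out <- c(f_mov_1 = NA_real_, f_mov_2 = NA_real_)
  for (p in unique(ph)) {
    in_p <- ph == p
    denom <- sum(vis & in_p)
    if (denom == 0) next
    j <- which(in_p)
    j <- j[j > 1]                      # frames with a predecessor
    j <- j[ph[j - 1] == p]             # predecessor in the same phase
    ok <- vis[j] & vis[j - 1] & d[j] < d[j - 1]
    out[p] <- sum(ok) / denom
  }
  out
}

#' Fraction of time spent in the cathode quadrant, per phase
#'
#' @inheritParams f_mov
#' @return Named numeric vector `c(f_cat_1, f_cat_2)`.
#' @export
f_cat <- function(traj, config, arena) {
  qf <- quadrant_fractions(traj, config, arena)
  c(f_cat_1 = qf["cathode", "phase1"], f_cat_2 = qf["cathode", "phase2"])
}

#' Occupancy of the cathode, middle and anode zones, per phase
#'
#' The middle zone is the union of the two central quadrants; the
#' cathode/anode zones are the electrode quadrants, identified per phase
#' (they exchange at the polarity swap). Within each phase with at least
#' one attributable frame, the three fractions sum to 1.
#'
#' @inheritParams f_mov
#' @return A 3 x 2 matrix (rows `cathode`, `middle`, `anode`; columns
#'   `phase1`, `phase2`), `NA` for phases with no attributable frames.
#' @export
quadrant_fractions <- function(traj, config, arena) {
  if (nrow(traj) == 0) stop("empty trajectory")
  ph <- phase_of(traj, config)
  q <- attributed_quadrant(traj, arena)
  out <- matrix(NA_real_, 3, 2,
                dimnames = list(c("cathode", "middle", "anode"),
                                c("phase1", "phase2")))
  for (p in unique(ph)) {
    in_p <- ph == p & !is.na(q)
    n <- sum(in_p)
    if (n == 0) next
    cat_q <- if (cathode_y(p, config, arena) == 0) 0L else 3L
    ano_q <- 3L - cat_q
    out["cathode", p] <- sum(q[in_p] == cat_q) / n
    out["anode", p] <- sum(q[in_p] == ano_q) / n
    out["middle", p] <- sum(q[in_p] %in% c(1L, 2L)) / n
  }
  out
}

#' Raw per-quadrant occupancy, ignoring phases
#'
#' Fraction of attributable frames spent in each of the four axial
#' quadrants over the whole experiment; useful for no-field null checks
#' where each quadrant is expected at 25%.
#'
#' @param traj A `worm_trajectory`.
#' @param arena An `arena_geometry`.
#' @return Numeric vector of four fractions (quadrants 0-3) summing to 1,
#'   or all-`NA` when no frame is attributable.
#' @export
quadrant_occupancy <- function(traj, arena) {
  q <- attributed_quadrant(traj, arena)
  n <- sum(!is.na(q))
  if (n == 0) return(rep(NA_real_, 4))
  tabulate(q + 1L, nbins = 4) / n
}

#' Mean gliding speed
#'
#' Mean Euclidean displacement between consecutive visible frames,
#' multiplied by the frame rate, in mm/s.
#'
#' @inheritParams f_mov
#' @return Speed in mm/s; `NA` if no consecutive visible pair exists.
#' @export
mean_speed <- function(traj, config) {
  vis <- traj$visible & !is.na(traj$x_mm) & !is.na(traj$y_mm)
  j <- which(vis[-1] & vis[-length(vis)]) + 1L
  if (length(j) == 0) return(NA_real_)
  d <- sqrt((traj$x_mm[j] - traj$x_mm[j - 1])^2 +
            (traj$y_mm[j] - traj$y_mm[j - 1])^2)
  mean(d) * config$fps
}

#' Score one trajectory
#'
#' Computes the full metric set for one worm.
#'
#' @inheritParams f_mov
#' @return A one-row data frame with columns `worm_id`, `f_cat_1`,
#'   `f_cat_2`, `f_mov_1`, `f_mov_2`, `occ_mid_1`, `occ_mid_2`,
#'   `occ_anode_1`, `occ_anode_2`, `mean_speed_mm_s`, `n_visible_1`,
#'   `n_visible_2`.
#' @export
score_trajectory <- function(traj, config = attr(traj, "config"),
                             arena = attr(traj, "arena")) {
  if (is.null(config)) stop("config required")
  if (is.null(arena)) arena <- arena_geometry()
  fm <- f_mov(traj, config, arena)
  qf <- quadrant_fractions(traj, config, arena)
  ph <- phase_of(traj, config)
  vis <- traj$visible & !is.na(traj$y_mm)
  data.frame(worm_id = traj$worm_id[1],
             f_cat_1 = qf["cathode", 1], f_cat_2 = qf["cathode", 2],
             f_mov_1 = fm[[1]], f_mov_2 = fm[[2]],
             occ_mid_1 = qf["middle", 1], occ_mid_2 = qf["middle", 2],
             occ_anode_1 = qf["anode", 1], occ_anode_2 = qf["anode", 2],
             mean_speed_mm_s = mean_speed(traj, config),
             n_visible_1 = sum(vis & ph == 1L),
             n_visible_2 = sum(vis & ph == 2L),
             stringsAsFactors = FALSE)
}

#' Score a cohort of trajectories
#'
#' @param trajs A list of `worm_trajectory` objects sharing one
#'   configuration and arena (as produced by [generate_cohort()]).
#' @param config,arena Shared configuration and arena; default to the
#'   first trajectory's attributes.
#' @return A data frame with one row per worm, ordered by `worm_id`, with
#'   a `label` column carrying each trajectory's design-cell label.
#' @export
score_cohort <- function(trajs, config = NULL, arena = NULL) {
  stopifnot(length(trajs) > 0)
  rows <- lapply(trajs, function(tr) {
    cfg <- if (is.null(config)) attr(tr, "config") else config
    ar <- if (is.null(arena)) attr(tr, "arena") else arena
    row <- score_trajectory(tr, cfg, ar)
    row$label <- if (is.null(attr(tr, "label"))) NA_character_
                 else attr(tr, "label")
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$worm_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
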