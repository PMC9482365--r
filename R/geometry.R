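#' Arena geometry for a trough electrotaxis assay
#'
#' Describes one trough arena: a narrow channel with a trapezoidal cross
#' section whose long axis carries the electric field. The long axis is
#' partitioned into four equal quadrants; the outermost two contain the
#' electrodes. All lengths are in millimetres.
#'
#' The axial coordinate `y` runs along the long axis, from 0 at one
#' electrode face to `length_mm` at the other. The transverse coordinate
#' `x` spans `[0, top_width_mm]` and is carried through trajectories but
#' ignored by all electrotaxis metrics, which are one-dimensional.
#'
#' @param length_mm Long-axis length of the trough.
#' @param top_width_mm Channel width at the top of the trapezoidal section.
#' @param bottom_width_mm Channel width at the bottom.
#' @param depth_mm Channel depth.
#' @return An object of class `arena_geometry`.
#' @examples
#' arena <- arena_geometry()
#' quadrant_width(arena)  # 15 mm
#' @export
arena_geometry <- function(length_mm = 60, top_width_mm = 17.3,
                           bottom_width_mm = 4.4, depth_mm = 10) {
  stopifnot(length_mm > 0, bottom_width_mm > 0, depth_mm > 0)
  if (top_width_mm < bottom_width_mm)
    stop("top_width_mm must be >= bottom_width_mm")
  structure(list(length_mm = as.numeric(length_mm),
                 top_width_mm = as.numeric(top_width_mm),
                 bottom_width_mm = as.numeric(bottom_width_mm),
                 depth_mm = as.numeric(depth_mm),
                 n_quadrants = 4L),
            class = "arena_geometry")
}

#' @rdname arena_geometry
#' @param arena An `arena_geometry` object.
#' @export
quadrant_width <- function(arena) arena$length_mm / arena$n_quadrants

#' Experiment configuration
#'
#' Voltage, timing and imaging parameters for one electrotaxis run. The
#' polarity of the field is reversed once, at `swap_s`; experiments without
#' a swap encode `swap_s = duration_s`. `cathode1_end` names the trough end
#' that is the cathode before the swap ("low" = the `y = 0` end).
#'
#' @param voltage_V Applied voltage in volts (>= 0).
#' @param duration_s Total experiment duration in seconds.
#' @param swap_s Time of the polarity swap in seconds; defaults to half
#'   the duration. Use `swap_s = duration_s` for a no-swap run.
#' @param fps Imaging frame rate in frames per second.
#' @param mm_per_px Spatial scale of the recording.
#' @param water Water type label, `"IO"` (instant ocean) or `"MQ"`
#'   (ultrapure).
#' @param cathode1_end `"low"` or `"high"`: which trough end is the
#'   phase-1 cathode.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(voltage_V, duration_s, swap_s = duration_s / 2,
                              fps = 8, mm_per_px = 0.25,
                              water = c("IO", "MQ"),
                              cathode1_end = c("low", "high")) {
  water <- match.arg(water)
  cathode1_end <- match.arg(cathode1_end)
  stopifnot(voltage_V >= 0, duration_s > 0, fps > 0, mm_per_px > 0)
  if (!(swap_s > 0 && swap_s <= duration_s))
    stop("swap_s must satisfy 0 < swap_s <= duration_s")
  structure(list(voltage_V = as.numeric(voltage_V),
                 duration_s = as.numeric(duration_s),
                 swap_s = as.numeric(swap_s),
                 fps = as.numeric(fps),
                 mm_per_px = as.numeric(mm_per_px),
                 water = water,
                 cathode1_end = cathode1_end),
            class = "experiment_config")
}

#' Does this configuration include a polarity swap?
#' @param config An `experiment_config`.
#' @return Logical.
#' @export
has_swap <- function(config) config$swap_s < config$duration_s

#' Quadrant index of an axial position
#'
#' The long axis is split into four equal, half-open bins
#' `[0, L/4), [L/4, L/2), [L/2, 3L/4), [3L/4, L]`; the last bin is closed
#' so `y = L` is quadrant 3. Quadrants are numbered 0 to 3 from the
#' `y = 0` end.
#'
#' @param y Axial position(s) in mm; must lie in `[0, length_mm]`.
#' @param arena An `arena_geometry`.
#' @return Integer vector of quadrant indices in `0:3`.
#' @export
quadrant_index <- function(y, arena) {
  L <- arena$length_mm
  if (any(y < 0 | y > L, na.rm = TRUE))
    stop("axial position outside the arena [0, ", L, "] mm")
  q <- floor(y / quadrant_width(arena))
  as.integer(pmin(q, arena$n_quadrants - 1L))
}

#' Axial coordinate of the cathode in a given phase
#'
#' Phase 1 is the interval before the polarity swap, phase 2 after it.
#' For a no-swap configuration phase 2 does not exist and requesting it
#' is an error.
#'
#' @param phase 1 or 2.
#' @param config An `experiment_config`.
#' @param arena An `arena_geometry`.
#' @return 0 or `length_mm`.
#' @export
cathode_y <- function(phase, config, arena) {
  if (!phase %in% c(1, 2)) stop("phase must be 1 or 2")
  if (phase == 2 && !has_swap(config))
    stop("phase 2 requested for a configuration without a polarity swap")
  low_is_cathode <- (config$cathode1_end == "low") == (phase == 1)
  if (low_is_cathode) 0 else arena$length_mm
}

#' Phase of each frame time
#'
#' Frames at `t < swap_s` belong to phase 1, frames at `t >= swap_s` to
#' phase 2 (the swap frame itself is phase 2). Every frame of a no-swap
#' run is phase 1.
#'
#' @param t_s Vector of frame times in seconds.
#' @param config An `experiment_config`.
#' @return Integer vector of 1s and 2s.
#' @export
frame_phase <- function(t_s, config) {
  if (!has_swap(config)) return(rep(1L, length(t_s)))
  ifelse(t_s < config$swap_s, 1L, 2L)
}

#' Mean axial field strength
#'
#' The applied voltage divided by the trough length, in V/cm. A 2 V
#' differential across a 60 mm trough gives 0.33 V/cm.
#'
#' @param voltage_V Applied voltage (>= 0).
#' @param arena An `arena_geometry`.
#' @return Field strength in V/cm.
#' @export
field_strength <- function(voltage_V, arena) {
  stopifnot(voltage_V >= 0)
  voltage_V / (arena$length_mm / 10)
}

#' Resistivity from conductivity
#'
#' Converts a water conductivity in microsiemens per centimetre to a
#' resistivity in ohm metres (780 uS/cm corresponds to 12.8 Ohm m).
#'
#' @param conductivity_uS_cm Conductivity in uS/cm (> 0).
#' @return Resistivity in Ohm m.
#' @export
resistivity_from_conductivity <- function(conductivity_uS_cm) {
  if (any(conductivity_uS_cm <= 0)) stop("conductivity must be positive")
  1 / (conductivity_uS_cm * 1e-6 * 100)
}
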