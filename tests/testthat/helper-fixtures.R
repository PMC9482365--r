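# Shared fixture builders for the test suite. All stochastic fixtures
# take explicit seeds so every test is reproducible.

default_arena <- function() arena_geometry()

swap_config <- function(duration_s = 120, voltage_V = 2, ...)
  experiment_config(voltage_V, duration_s, ...)

# A hand-built trajectory from an axial coordinate vector: x fixed,
# every frame visible unless stated otherwise.
traj_from_y <- function(y, config, visible = rep(TRUE, length(y)),
                        x = rep(8, length(y)), worm_id = "manual-1") {
  n <- length(y)
  if (n == 0) worm_id <- character(0)
  structure(data.frame(worm_id = worm_id, frame = seq_len(n) - 1L,
                       t_s = (seq_len(n) - 1L) / config$fps,
                       x_mm = x, y_mm = y, visible = visible,
                       stringsAsFactors = FALSE),
            class = c("worm_trajectory", "data.frame"))
}

quick_worm <- function(bias = 0, speed = 1.7, wall = 0, ...)
  worm_params(electrotaxis_bias = bias, speed_mm_s = speed,
              wall_affinity = wall, ...)

# Random piecewise trajectory generator for oracle cross-checks:
# arbitrary visible patterns and positions, independent of the
# random-walk simulator.
random_test_traj <- function(config, arena, seed) {
  set.seed(seed)
  n <- round(config$duration_s * config$fps) + 1L
  y <- pmin(pmax(cumsum(c(runif(1, 0, arena$length_mm),
                          rnorm(n - 1, 0, 0.4))), 0), arena$length_mm)
  vis <- runif(n) > 0.2
  traj_from_y(y, config, visible = vis,
              x = runif(n, 0, arena$top_width_mm))
}
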