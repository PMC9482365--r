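#' Read and write trajectory tables
#'
#' Trajectories travel as plain CSV (dot decimal, UTF-8, header row;
#' units embedded in column names): `worm_id, frame, t_s, x_mm, y_mm,
#' visible` plus `heading_rad` for simulated worms.
#'
#' @param traj A `worm_trajectory` or a list of them.
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (is.list(traj) && !is.data.frame(traj)) traj <- do.call(rbind, traj)
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param config,arena Optional configuration/arena attached to the
#'   returned trajectories.
#' @return `read_trajectory_csv()` returns a list of `worm_trajectory`
#'   objects, one per distinct `worm_id`.
#' @export
read_trajectory_csv <- function(path, config = NULL, arena = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("worm_id", "frame", "t_s", "x_mm", "y_mm", "visible")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must contain columns: ", paste(need, collapse = ", "))
  df$visible <- as.logical(df$visible)
  lapply(split(df, df$worm_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    rownames(d) <- NULL
    structure(d, config = config, arena = arena,
              class = c("worm_trajectory", "data.frame"))
  })
}

#' Write a scores table to CSV
#' @param scores Data frame from [score_cohort()].
#' @param path Output CSV path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' Read and write experiment configuration files
#'
#' One flat YAML file drives all pipeline stages. Recognised keys:
#' arena geometry (`length_mm`, `top_width_mm`, `bottom_width_mm`,
#' `depth_mm`), run parameters (`voltage_V`, `duration_s`, `swap_s`,
#' `fps`, `mm_per_px`, `water`, `cathode1_end`), the master `seed`, and
#' an optional `cells` list describing the cohort design (each cell:
#' `label`, `n`, and `worm_params` arguments such as `size_class`,
#' `electrotaxis_bias`, `persistence`, `wall_affinity`, `speed_mm_s`,
#' `body_length_mm`, `blind_zone_mm`). Unknown top-level keys are an
#' error, which catches typos before a long run.
#'
#' @param path Path to a YAML config file.
#' @return A list with `arena` (`arena_geometry`), `config`
#'   (`experiment_config`), `seed`, and `cells`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  arena_keys <- c("length_mm", "top_width_mm", "bottom_width_mm", "depth_mm")
  run_keys <- c("voltage_V", "duration_s", "swap_s", "fps", "mm_per_px",
                "water", "cathode1_end")
  known <- c(arena_keys, run_keys, "seed", "cells")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(raw$voltage_V) || is.null(raw$duration_s))
    stop("config must set voltage_V and duration_s")
  arena <- do.call(arena_geometry, raw[intersect(arena_keys, names(raw))])
  config <- do.call(experiment_config, raw[intersect(run_keys, names(raw))])
  list(arena = arena, config = config,
       seed = raw$seed %||% 1L, cells = raw$cells)
}

cells_to_design <- function(cells, config) {
  if (is.null(cells)) stop("config has no cells section")
  lapply(cells, function(cell) {
    wp_args <- cell[setdiff(names(cell), c("label", "n"))]
    list(n = cell$n %||% 1L,
         params = do.call(worm_params, wp_args),
         config = config,
         label = cell$label %||% "cell")
  })
}

# Tiny FNV-1a hash over a serialized object, for manifests.
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(out_dir, cfg, seeds, inputs, outputs) {
  manifest <- list(config_hash = fnv1a_hash(cfg),
                   seeds = seeds,
                   package_version = as.character(utils::packageVersion("electrotax")),
                   inputs = inputs, outputs = outputs,
                   settings = list(threshold_mode = "otsu-median-frame",
                                   ss_type = "II",
                                   occupancy_attribution = "last-known-quadrant",
                                   pre_detection_frames = "excluded"),
                   timestamp = format(Sys.time(), tz = "UTC"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort from a config file
#'
#' Expands the config's `cells` design with [generate_cohort()] and
#' writes one trajectory CSV per design cell, a combined
#' `trajectories.csv`, and a run manifest recording the config hash and
#' all seeds. Reruns with the same config and seed produce identical
#' CSVs. With `render = TRUE`, each worm's image stack and background
#' frame are written as multi-page/single-page TIFF.
#'
#' @param config_path Path to a YAML config (see [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed override; `NULL` uses the config's seed.
#' @param render Also render image stacks.
#' @param rp `render_params` used when `render = TRUE`.
#' @return Invisibly, the list of simulated trajectories.
#' @export
run_simulate <- function(config_path, out_dir, seed = NULL, render = FALSE,
                         rp = render_params()) {
  cfg <- read_config(config_path)
  seed <- as.integer(seed %||% cfg$seed)
  design <- cells_to_design(cfg$cells, cfg$config)
  trajs <- generate_cohort(design, cfg$arena, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traj_path <- file.path(out_dir, "trajectories.csv")
  write_trajectory_csv(trajs, traj_path)
  outputs <- traj_path
  if (render) {
    for (k in seq_along(trajs)) {
      stack <- render_frames(trajs[[k]], rp, cfg$arena, seed = seed + k)
      id <- trajs[[k]]$worm_id[1]
      fstem <- file.path(out_dir, gsub("[^A-Za-z0-9_-]", "_", id))
      EBImage::writeImage(EBImage::Image(aperm(stack$frames / 255,
                                               c(2, 1, 3))),
                          paste0(fstem, "_stack.tif"), type = "tiff")
      EBImage::writeImage(EBImage::Image(t(stack$background / 255)),
                          paste0(fstem, "_background.tif"), type = "tiff")
      outputs <- c(outputs, paste0(fstem, "_stack.tif"))
    }
  }
  write_manifest(out_dir, cfg, seeds = list(master = seed),
                 inputs = config_path, outputs = outputs)
  invisible(trajs)
}

#' Run the scoring-and-statistics pipeline on trajectories
#'
#' Reads a trajectory CSV (e.g. from [run_simulate()] or from tracking),
#' scores every worm, and runs the default analysis: a one-way ANOVA of
#' each electrotaxis metric on the design label, with assumption checks
#' and a randomization confirmation, writing `scores.csv` and a JSON
#' `report.json` plus a manifest.
#'
#' @param traj_path Path to a trajectory CSV.
#' @param config_path Path to the YAML config used to produce it.
#' @param out_dir Output directory.
#' @param labels Optional named character vector mapping `worm_id` to a
#'   design label; by default the label is the `worm_id` prefix before
#'   the final `-wNN` suffix.
#' @param n_perm Permutations for the randomization confirmation.
#' @return Invisibly, a list with `scores` and `report`.
#' @export
run_pipeline <- function(traj_path, config_path, out_dir,
                         labels = NULL, n_perm = 999) {
  if (!file.exists(traj_path)) stop("trajectory input not found: ", traj_path)
  cfg <- read_config(config_path)
  trajs <- read_trajectory_csv(traj_path, cfg$config, cfg$arena)
  scores <- score_cohort(trajs, cfg$config, cfg$arena)
  scores$label <- if (is.null(labels))
    sub("-w[0-9]+$", "", scores$worm_id)
  else unname(labels[scores$worm_id])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scores_path <- file.path(out_dir, "scores.csv")
  write_scores_csv(scores, scores_path)
  report <- list()
  metrics <- c("f_cat_1", "f_cat_2", "f_mov_1", "f_mov_2")
  for (mname in metrics) {
    v <- scores[[mname]]
    keep <- !is.na(v)
    if (length(unique(scores$label[keep])) < 2 ||
        any(table(scores$label[keep]) < 2)) next
    an <- one_way_anova(v[keep], scores$label[keep])
    fit <- stats::lm(v[keep] ~ factor(scores$label[keep]))
    checks <- assumption_checks(fit)
    perm <- randomization_anova(v[keep],
                                data.frame(label = scores$label[keep]),
                                n_perm = n_perm, seed = cfg$seed)
    report[[mname]] <- list(
      anova = an$table, flags = an$flags,
      normality_p = checks$normality_p,
      heteroscedasticity_p = checks$heteroscedasticity_p,
      randomization_p = perm)
  }
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  write_manifest(out_dir, cfg, seeds = list(master = cfg$seed),
                 inputs = c(traj_path, config_path),
                 outputs = c(scores_path, report_path))
  invisible(list(scores = scores, report = report))
}
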