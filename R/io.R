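# Readers and writers for the tabular and config file contracts.
#
# CSV dialect: UTF-8, comma separators, header row, '.' decimal, no index
# column, floats at 6 significant digits.

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 6, format = "g"))
}

write_hd_csv <- function(tbl, path) {
  out <- mutate(tbl, across(dplyr::where(is.numeric),
                            function(x) fmt_num(x)))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write and read trial tables
#'
#' Trial CSV columns: `trial_id`, `loc_id`, `nominal_x_deg`,
#' `nominal_y_deg`, `log_contrast`, `seen`, `is_catch`, `block_id` (plus any
#' gaze-filter columns present).
#'
#' @param trials A trial tibble (e.g. `zest_session$trials`).
#' @param path File path.
#' @return `write_trials()` the path, invisibly; `read_trials()` a tibble.
#' @export
write_trials <- function(trials, path) {
  write_hd_csv(trials, path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read per-location threshold estimates
#'
#' Threshold CSV columns: `loc_id`, `x_deg`, `y_deg`, `threshold_log`,
#' `n_trials`.
#'
#' @param estimates Estimates tibble (e.g. `zest_session$estimates`).
#' @param path File path.
#' @export
write_thresholds <- function(estimates, path) {
  write_hd_csv(estimates, path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read per-frame gaze tables
#'
#' Gaze CSV columns: `trial_id`, `frame_idx` (1..3), `dx_px`, `dy_px`,
#' `missing_reason`.
#'
#' @param gaze Gaze tibble.
#' @param path File path.
#' @export
write_gaze <- function(gaze, path) {
  write_hd_csv(gaze, path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a grid or ladder to JSON
#'
#' Grids serialise extents, spacing and locations; ladders their levels and
#' endpoints.
#'
#' @param x A `field_grid` or `contrast_ladder`.
#' @param path File path.
#' @export
write_geometry_json <- function(x, path) {
  obj <- if (inherits(x, "field_grid")) {
    ext <- grid_extents(x)
    list(type = "field_grid", x_min = ext$x_min, x_max = ext$x_max,
         y_min = ext$y_min, y_max = ext$y_max, spacing = ext$spacing,
         locations = as_tibble(x[c("loc_id", "x_deg", "y_deg")]))
  } else if (inherits(x, "contrast_ladder")) {
    list(type = "contrast_ladder", min = min(as.numeric(x)),
         max = max(as.numeric(x)), levels = as.numeric(x))
  } else {
    abort("Only field_grid and contrast_ladder objects are serialised.")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "field_grid")) {
    build_grid(obj$x_min, obj$x_max, obj$y_min, obj$y_max, obj$spacing)
  } else if (identical(obj$type, "contrast_ladder")) {
    structure(as.numeric(obj$levels),
              class = c("contrast_ladder", "numeric"))
  } else {
    abort(sprintf("Unknown geometry type in %s.", path))
  }
}

#' Write a sweep manifest
#'
#' Per-frame subset counts of a [slice_sweep()] as JSON.
#'
#' @param sweep A `slice_sweep`.
#' @param path File path.
#' @export
write_sweep_manifest <- function(sweep, path) {
  jsonlite::write_json(
    list(n_frames = length(sweep$thresholds), frames = sweep$counts),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration with optional blocks `grid`, `ladder`,
#' `zest`, `gaze`, `map`, `slice`, `wave`, `observer` and a top-level
#' `seed`, validates types and ranges, fills defaults, and returns the
#' resolved config.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config file.
#' @return A named list with all blocks present and defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    seed = 1L,
    grid = list(x_min = 11, x_max = 17, y_min = -3, y_max = 6,
                spacing = 0.5),
    ladder = list(min_log = -0.9, max_log = 0.6, n_levels = 74,
                  scale = "linear"),
    zest = list(prior = "uniform", beta = 3.5, gamma = 0.02, lambda = 0.02,
                n_presentations = 6, rule = "mean",
                catch_fp_rate = 0, catch_fn_rate = 0),
    gaze = list(pixel_scale = 1.64, max_range_deg = 0.5, max_shift_deg = 1,
                range_metric = "per_axis"),
    map = list(lattice_spacing = 0.05, radius = 0.5, kernel_sd = 0.5,
               gamma = 0.02, lambda = 0.02, min_trials = 4),
    slice = list(start = 0.5, stop = -0.5, step = -0.01),
    wave = list(center_x = 15, center_y = 1.5, contrast = -0.35,
                ring_step = 0.5, along_ring_spacing = 1,
                presentations_per_location = 2),
    observer = list(preset = "paper_like", baseline_alpha = -0.35,
                    drift_sd = 0.15, microsaccade_rate = 0.8,
                    blink_prob = 0.05)
  )
}

#' @rdname load_config
#' @param cfg A config list (possibly partial); unknown blocks or keys,
#'   non-integer seeds and out-of-range rates are rejected.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) abort("Config must be a mapping/object.")
  defs <- config_defaults()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown)) {
    abort(sprintf("Unknown config block(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  out <- defs
  for (blk in names(cfg)) {
    if (blk == "seed") {
      if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
        abort("`seed` must be an integer.")
      }
      out$seed <- as.integer(cfg$seed)
      next
    }
    if (!is.list(cfg[[blk]])) abort(sprintf("Block `%s` must be a mapping.",
                                            blk))
    bad <- setdiff(names(cfg[[blk]]), names(defs[[blk]]))
    if (length(bad)) {
      abort(sprintf("Unknown key(s) in `%s`: %s.", blk,
                    paste(bad, collapse = ", ")))
    }
    out[[blk]] <- modifyList(defs[[blk]], cfg[[blk]])
  }
  check_pos <- function(x, name) {
    if (!is.numeric(x) || x <= 0) abort(sprintf("`%s` must be > 0.", name))
  }
  check_pos(out$grid$spacing, "grid.spacing")
  check_pos(out$map$radius, "map.radius")
  check_pos(out$map$kernel_sd, "map.kernel_sd")
  check_pos(out$wave$ring_step, "wave.ring_step")
  for (r in c("gamma", "lambda")) {
    v <- out$zest[[r]]
    if (!is.numeric(v) || v < 0 || v >= 1) {
      abort(sprintf("zest.%s must lie in [0, 1).", r))
    }
  }
  out
}

#' Run the full synthetic pipeline from one configuration
#'
#' One-command reproducible run: build the surface and grid, simulate the
#' session, filter trials by eye position, fit the conventional and local
#' maximum-likelihood maps, sweep the slice display, and run the wave
#' search — all from a single config and seed. Outputs (CSV/JSON plus a
#' resolved-config copy) are written under `out_dir` when given.
#'
#' @param config A config list from [load_config()] (or a path to one).
#' @param out_dir Optional output directory.
#' @param lattice_spacing Override of the map lattice spacing (the full
#'   0.05-degree lattice is expensive; coarser values are useful for quick
#'   runs).
#' @return A list with `session`, `filtered`, `conventional`, `ml_map`,
#'   `sweep`, `wave`, and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, lattice_spacing = NULL) {
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  if (!is.null(lattice_spacing)) config$map$lattice_spacing <- lattice_spacing
  g <- config$grid
  grid <- build_grid(g$x_min, g$x_max, g$y_min, g$y_max, g$spacing)
  ladder <- build_ladder(config$ladder$min_log, config$ladder$max_log,
                         config$ladder$n_levels, scale = config$ladder$scale)
  obs <- config$observer
  surface <- make_paper_like_subject(seed = config$seed)
  if (!is.null(obs$baseline_alpha)) {
    surface$baseline_alpha <- obs$baseline_alpha
  }
  session <- simulate_session(
    surface, grid,
    eye_model = eye_movement_model(drift_sd = obs$drift_sd,
                                   microsaccade_rate = obs$microsaccade_rate,
                                   blink_prob = obs$blink_prob),
    seed = config$seed, ladder = ladder,
    n_presentations = config$zest$n_presentations,
    likelihood = psychometric_params(0, config$zest$beta,
                                     config$zest$gamma, config$zest$lambda),
    prior = config$zest$prior, rule = config$zest$rule,
    catch_fp_rate = config$zest$catch_fp_rate,
    catch_fn_rate = config$zest$catch_fn_rate
  )
  filtered <- filter_session(session$trials, session$gaze,
                             pixel_scale = config$gaze$pixel_scale,
                             max_range_deg = config$gaze$max_range_deg,
                             max_shift_deg = config$gaze$max_shift_deg,
                             range_metric = config$gaze$range_metric)
  valid <- filter(filtered$trials, .data$valid)
  conventional <- conventional_map(
    mutate(session$estimates, threshold_log = .data$threshold_log), grid)
  lattice <- build_estimation_lattice(grid, config$map$lattice_spacing)
  ml_map <- ml_threshold_map(valid, lattice,
                             radius = config$map$radius,
                             kernel_sd = config$map$kernel_sd,
                             gamma = config$map$gamma,
                             lam = config$map$lambda,
                             min_trials = config$map$min_trials)
  sweep <- slice_sweep(valid, config$slice$start, config$slice$stop,
                       config$slice$step)
  wcfg <- wave_search_config(
    config$wave$center_x, config$wave$center_y, config$wave$contrast,
    ring_step = config$wave$ring_step,
    along_ring_spacing = config$wave$along_ring_spacing,
    presentations_per_location = config$wave$presentations_per_location,
    bounds = grid
  )
  wave <- run_wave_search(wcfg, simulated_observer_from_map(surface),
                          seed = config$seed + 1L)
  result <- list(session = session, filtered = filtered,
                 conventional = conventional, ml_map = ml_map,
                 sweep = sweep, wave = wave, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(session$trials, file.path(out_dir, "trials.csv"))
    write_gaze(session$gaze, file.path(out_dir, "gaze.csv"))
    write_trials(filtered$trials, file.path(out_dir, "trials_filtered.csv"))
    write_thresholds(session$estimates, file.path(out_dir, "thresholds.csv"))
    write_hd_csv(tidy(ml_map), file.path(out_dir, "ml_map.csv"))
    write_sweep_manifest(sweep, file.path(out_dir, "sweep.json"))
    write_hd_csv(tidy(wave), file.path(out_dir, "wave_trace.csv"))
    jsonlite::write_json(
      list(status = wave$status,
           n_locations_tested = wave$n_locations_tested,
           n_presentations = wave$n_presentations,
           per_wave = wave$per_wave),
      file.path(out_dir, "wave_summary.json"), auto_unbox = TRUE, digits = NA
    )
    yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  }
  result
}
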