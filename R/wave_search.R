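# Wave-based adaptive scotoma-boundary search.
#
# The search is blind-spot specific: it starts on the smallest circle around
# the blind-spot centre (all locations expected missed), then expands
# outward in waves, opening on each larger circle only the locations that
# are Voronoi neighbours of an already-tested location with at least one
# miss. It stops when the boundary closes (every edge location responded on
# both presentations and no new locations open) or when it reaches the
# boundary of the test area.

#' Locations on a circle around the blind-spot centre
#'
#' Evenly spaced points (approximately `spacing` apart along the arc, never
#' fewer than 4) on the circle of radius `radius` around the centre,
#' starting at angle 0 (temporal direction) and proceeding counterclockwise.
#'
#' @param center_x,center_y Circle centre, degrees.
#' @param radius Circle radius, degrees (> 0).
#' @param spacing Target along-circle spacing, degrees (default 1).
#' @return A tibble with columns `x_deg`, `y_deg`, `angle_rad`.
#' @export
ring_locations <- function(center_x, center_y, radius, spacing = 1) {
  stopifnot(radius > 0, spacing > 0)
  n <- max(4L, as.integer(round(2 * pi * radius / spacing)))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  tibble(
    x_deg = center_x + radius * cos(theta),
    y_deg = center_y + radius * sin(theta),
    angle_rad = theta
  )
}

#' Wave-search configuration
#'
#' @param center_x,center_y Blind-spot centre in field degrees (required; the
#'   search assumes the innermost circle is not expected to be seen).
#' @param contrast Fixed stimulus contrast for the whole run, log units
#'   (chosen per subject by inspecting the slice display in practice).
#' @param ring_step Radius increment between waves, degrees (default 0.5).
#' @param along_ring_spacing Along-circle spacing, degrees (default 1).
#' @param presentations_per_location Presentations per tested location
#'   (default 2).
#' @param bounds Test-area extents `c(x_min, x_max, y_min, y_max)` (default
#'   the 13 x 19 degree region) or a `field_grid`.
#' @param max_waves Safety cap on the number of waves.
#' @return A list of class `wave_search_config`.
#' @export
wave_search_config <- function(center_x, center_y, contrast,
                               ring_step = 0.5, along_ring_spacing = 1,
                               presentations_per_location = 2L,
                               bounds = c(11, 17, -3, 6),
                               max_waves = 60L) {
  if (inherits(bounds, "field_grid") || is.data.frame(bounds)) {
    ext <- grid_extents(bounds)
    bounds <- c(ext$x_min, ext$x_max, ext$y_min, ext$y_max)
  }
  stopifnot(ring_step > 0, presentations_per_location >= 1)
  if (center_x < bounds[1] || center_x > bounds[2] ||
      center_y < bounds[3] || center_y > bounds[4]) {
    abort("Blind-spot centre must lie within the test-area bounds.")
  }
  structure(
    list(center_x = center_x, center_y = center_y, contrast = contrast,
         ring_step = ring_step, along_ring_spacing = along_ring_spacing,
         presentations_per_location = as.integer(presentations_per_location),
         bounds = bounds, max_waves = as.integer(max_waves)),
    class = "wave_search_config"
  )
}

#' Run the wave-based scotoma-boundary search
#'
#' Simulates the adaptive search against an observer callback
#' `function(x_deg, y_deg, contrast) -> logical`. Wave 1 tests every
#' location on the innermost circle. Each subsequent wave adds the next
#' circle outward and then repeatedly opens any still-untested generated
#' location that is Voronoi-adjacent (over all circle locations generated so
#' far) to a tested location with at least one missed presentation — so
#' next-circle locations beyond misses, and same-circle gap locations next
#' to freshly missed ones, are all tested before the wave advances. An
#' opened location falling outside the test area cannot be tested: it is
#' flagged and skipped while the search continues elsewhere. The run ends
#' once a wave tests no new location; the status is `"edges_closed"` when
#' every boundary location was seen on both presentations and the search
#' never left the area, and `"out_of_range"` when it reached the area
#' boundary.
#'
#' @param config A [wave_search_config()].
#' @param observer Response callback.
#' @param seed Optional integer seed applied to the run (covers the
#'   observer's randomness when it uses the R RNG).
#' @return A `wave_search` list: `locations` (tibble: loc_id, wave,
#'   ring_radius_deg, x_deg, y_deg, tested, out_of_bounds, n_seen, n_missed
#'   — untested rows are generated candidates that never opened, or opened
#'   outside the area), `presentations` (tibble:
#'   presentation_id, loc_id, wave, x_deg, y_deg, ring_radius_deg,
#'   contrast_log, seen), `status`, `n_locations_tested`,
#'   `n_presentations`, and `per_wave` tested counts.
#' @export
run_wave_search <- function(config, observer, seed = NULL) {
  stopifnot(inherits(config, "wave_search_config"), is.function(observer))
  run <- function() wave_search_impl(config, observer)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

wave_search_impl <- function(config, observer) {
  bounds <- config$bounds
  npp <- config$presentations_per_location
  in_bounds <- function(x, y) {
    x >= bounds[1] & x <= bounds[2] & y >= bounds[3] & y <= bounds[4]
  }
  ring_tbl <- function(k) {
    r <- ring_locations(config$center_x, config$center_y,
                        radius = k * config$ring_step,
                        spacing = config$along_ring_spacing)
    tibble(x_deg = r$x_deg, y_deg = r$y_deg, wave = k,
           ring_radius_deg = k * config$ring_step,
           tested = FALSE, out_of_bounds = !in_bounds(r$x_deg, r$y_deg),
           n_seen = 0L, n_missed = 0L)
  }
  locations <- ring_tbl(1L)
  locations$loc_id <- seq_len(nrow(locations))
  presentations <- list()
  pres_id <- 0L
  left_area <- FALSE

  test_location <- function(i) {
    for (p in seq_len(npp)) {
      seen <- observe_at(observer, locations$x_deg[i], locations$y_deg[i],
                         config$contrast, i)
      pres_id <<- pres_id + 1L
      presentations[[pres_id]] <<- tibble(
        presentation_id = pres_id, loc_id = locations$loc_id[i],
        wave = locations$wave[i],
        x_deg = locations$x_deg[i], y_deg = locations$y_deg[i],
        ring_radius_deg = locations$ring_radius_deg[i],
        contrast_log = config$contrast, seen = seen
      )
      if (seen) locations$n_seen[i] <<- locations$n_seen[i] + 1L
      else locations$n_missed[i] <<- locations$n_missed[i] + 1L
    }
    locations$tested[i] <<- TRUE
  }

  # wave 1: the whole innermost circle (out-of-area points are untestable)
  left_area <- any(locations$out_of_bounds)
  for (i in which(!locations$out_of_bounds)) test_location(i)

  wave <- 1L
  while (any(locations$tested)) {
    if (wave >= config$max_waves) {
      abort("Wave cap reached without termination; raise `max_waves`.")
    }
    nxt <- ring_tbl(wave + 1L)
    nxt$loc_id <- nrow(locations) + seq_len(nrow(nxt))
    locations <- bind_rows(locations, nxt)
    adj <- neighbor_list(voronoi_neighbors(locations), nrow(locations))
    tested_any <- FALSE
    # `dismissed` marks openings already skipped as out of area this wave
    dismissed <- logical(nrow(locations))
    repeat {
      miss_idx <- which(locations$tested & locations$n_missed > 0)
      open_idx <- sort(unique(unlist(adj[miss_idx])))
      open_idx <- open_idx[!locations$tested[open_idx] & !dismissed[open_idx]]
      if (length(open_idx) == 0) break
      oob <- locations$out_of_bounds[open_idx]
      if (any(oob)) {
        left_area <- TRUE
        dismissed[open_idx[oob]] <- TRUE
      }
      for (i in open_idx[!oob]) {
        test_location(i)
        tested_any <- TRUE
      }
    }
    if (!tested_any) break
    wave <- wave + 1L
  }
  status <- if (left_area) "out_of_range" else "edges_closed"

  presentations <- bind_rows(presentations)
  tested <- filter(locations, .data$tested)
  structure(
    list(
      locations = select(as_tibble(locations), "loc_id", dplyr::everything()),
      presentations = presentations,
      status = status,
      n_locations_tested = nrow(tested),
      n_presentations = nrow(presentations),
      per_wave = count(tested, wave = .data$wave, name = "n_tested"),
      config = config
    ),
    class = "wave_search"
  )
}

#' @export
print.wave_search <- function(x, ...) {
  cat(sprintf("<wave_search> status %s: %d locations, %d presentations\n",
              x$status, x$n_locations_tested, x$n_presentations))
  invisible(x)
}

#' @describeIn run_wave_search `tidy()` returns the presentation trace.
#' @param x A `wave_search`.
#' @param ... Unused.
#' @method tidy wave_search
#' @export
tidy.wave_search <- function(x, ...) {
  x$presentations
}

#' @describeIn run_wave_search `glance()` returns the one-row run summary.
#' @method glance wave_search
#' @export
glance.wave_search <- function(x, ...) {
  tibble(
    status = x$status,
    n_locations_tested = x$n_locations_tested,
    n_presentations = x$n_presentations,
    n_waves = if (x$n_locations_tested) max(x$per_wave$wave) else 0L
  )
}

#' Simulated observer from a sensitivity map or surface
#'
#' Builds a response callback whose frequency-of-seeing curve at each query
#' point comes from local psychometric parameters: a fitted
#' [ml_threshold_map()] (nearest defined map point) or a ground-truth
#' [sensitivity_surface()]. Each presentation is answered by comparing a
#' uniform random draw with the local detection probability.
#'
#' @param map A `threshold_map` with `alpha_log`/`beta` columns, or a
#'   `sensitivity_surface`.
#' @param gamma,lam Guess and lapse rates of the simulated observer.
#' @param max_snap_deg Maximum distance to the nearest defined map point
#'   before a query is treated as outside the map (default 0.5).
#' @return A function `(x_deg, y_deg, contrast) -> logical`.
#' @export
simulated_observer_from_map <- function(map, gamma = 0.02, lam = 0.02,
                                        max_snap_deg = 0.5) {
  if (inherits(map, "sensitivity_surface")) {
    return(function(x_deg, y_deg, contrast) {
      params <- surface_params(map, x_deg, y_deg, gamma = gamma, lam = lam)
      runif(1) < detection_probability(params, contrast)
    })
  }
  stopifnot(inherits(map, "threshold_map"))
  pts <- filter(map$map, !is.na(.data$alpha_log))
  if (nrow(pts) == 0) abort("Map has no defined fits.")
  function(x_deg, y_deg, contrast) {
    d2 <- (pts$x_deg - x_deg)^2 + (pts$y_deg - y_deg)^2
    k <- which.min(d2)
    if (d2[k] > max_snap_deg^2) {
      abort(sprintf("Query (%.2f, %.2f) is outside the fitted map.",
                    x_deg, y_deg))
    }
    params <- list(alpha = pts$alpha_log[k], beta = pts$beta[k],
                   gamma = gamma, lam = lam)
    runif(1) < detection_probability(params, contrast)
  }
}
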