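# ggplot2 displays for maps, slices and search traces.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_path
#'   scale_color_gradientn scale_fill_gradientn coord_fixed labs theme_minimal
NULL

#' @export
ggplot2::autoplot

diverging_scale <- function(fill = FALSE, range = c(-0.5, 1.0)) {
  # red = depressed sensitivity, blue = sensitive
  cols <- c("#b2182b", "#f4a582", "#f7f7f7", "#92c5de", "#2166ac")
  if (fill) {
    scale_fill_gradientn(colors = cols, limits = range, oob = scales_squish)
  } else {
    scale_color_gradientn(colors = cols, limits = range, oob = scales_squish)
  }
}

# clamp out-of-bounds values into the limits (avoids a scales dependency
# beyond what ggplot2 itself provides)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot a threshold map
#'
#' Relative contrast sensitivity over the field, on the standard display
#' range of -0.5 to 1.0 log units (red = depressed, blue = sensitive).
#' Conventional maps draw one point per nominal location; local
#' maximum-likelihood maps draw a raster over the estimation lattice.
#'
#' @param object A `threshold_map`.
#' @param relative_to Sensitivity (log units) subtracted before display;
#'   defaults to the map median, so colours show relative sensitivity.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threshold_map
#' @export
autoplot.threshold_map <- function(object, relative_to = NULL, ...) {
  tbl <- filter(object$map, !is.na(.data$sensitivity_log))
  rel <- relative_to %||% median(tbl$sensitivity_log, na.rm = TRUE)
  tbl <- mutate(tbl, rel_sens = clamp_display(.data$sensitivity_log - rel))
  p <- if (object$kind == "ml") {
    ggplot(tbl, aes(.data$x_deg, .data$y_deg, fill = .data$rel_sens)) +
      geom_tile() + diverging_scale(fill = TRUE)
  } else {
    ggplot(tbl, aes(.data$x_deg, .data$y_deg, color = .data$rel_sens)) +
      geom_point(size = 3) + diverging_scale()
  }
  p + coord_fixed() + theme_minimal() +
    labs(x = "Temporal eccentricity (deg)", y = "Elevation (deg)",
         color = "Rel. sensitivity\n(log units)",
         fill = "Rel. sensitivity\n(log units)",
         title = sprintf("%s threshold map", object$kind))
}

#' Plot a slice selection
#'
#' Crossover trials at their (inferred when available, else nominal) field
#' locations: seen-below-threshold trials in blue, not-seen-at-or-above
#' trials in red; concordant trials are suppressed.
#'
#' @param object A `slice_selection` from [slice_select()].
#' @param show_concordant Also draw concordant trials, faint (default
#'   `FALSE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot slice_selection
#' @export
autoplot.slice_selection <- function(object, show_concordant = FALSE, ...) {
  tbl <- ensure_inferred(as_tibble(object))
  cross <- filter(tbl, .data$subset != "concordant")
  p <- ggplot(cross, aes(.data$inferred_x_deg, .data$inferred_y_deg,
                         color = .data$subset))
  if (show_concordant) {
    p <- p + geom_point(
      data = filter(tbl, .data$subset == "concordant"),
      color = "grey80", size = 1
    )
  }
  p + geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(crossover_seen = "#2166ac",
                                           crossover_notseen = "#b2182b")) +
    coord_fixed() + theme_minimal() +
    labs(x = "Temporal eccentricity (deg)", y = "Elevation (deg)",
         title = sprintf("Slice display at C0 = %.2f log units",
                         object$display_threshold[1]))
}

#' Plot a wave-search trace
#'
#' Tested locations coloured by outcome: both presentations seen (blue), one
#' missed (yellow), both missed (red); untested generated candidates in
#' faint grey.
#'
#' @param object A `wave_search` from [run_wave_search()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wave_search
#' @export
autoplot.wave_search <- function(object, ...) {
  tbl <- mutate(
    object$locations,
    outcome = dplyr::case_when(
      !.data$tested ~ "untested",
      .data$n_missed == 0 ~ "seen both",
      .data$n_seen == 0 ~ "missed both",
      TRUE ~ "missed one"
    )
  )
  ggplot(tbl, aes(.data$x_deg, .data$y_deg, color = .data$outcome)) +
    geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(
      "seen both" = "#2166ac", "missed one" = "#e6b800",
      "missed both" = "#b2182b", untested = "grey85"
    )) +
    coord_fixed() + theme_minimal() +
    labs(x = "Temporal eccentricity (deg)", y = "Elevation (deg)",
         title = sprintf("Wave search (%s, %d locations tested)",
                         object$status, object$n_locations_tested))
}

#' Plot a ground-truth sensitivity surface
#'
#' Raster of the true threshold over the region (blind spot shown at the
#' display floor), with vessel centrelines overlaid.
#'
#' @param object A `sensitivity_surface`.
#' @param bounds Extents `c(x_min, x_max, y_min, y_max)`.
#' @param spacing Raster spacing in degrees.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sensitivity_surface
#' @export
autoplot.sensitivity_surface <- function(object, bounds = c(11, 17, -3, 6),
                                         spacing = 0.1, ...) {
  grid <- build_grid(bounds[1], bounds[2], bounds[3], bounds[4], spacing)
  tbl <- mutate(as_tibble(grid),
                alpha = surface_alpha(object, .data$x_deg, .data$y_deg),
                rel_sens = clamp_display(-(.data$alpha -
                                             object$baseline_alpha)))
  p <- ggplot(tbl, aes(.data$x_deg, .data$y_deg, fill = .data$rel_sens)) +
    geom_tile() + diverging_scale(fill = TRUE)
  for (v in object$vessels) {
    p <- p + geom_path(
      data = tibble(x_deg = v$path[, 1], y_deg = v$path[, 2]),
      aes(.data$x_deg, .data$y_deg), inherit.aes = FALSE,
      linewidth = 0.3, color = "black", linetype = "22"
    )
  }
  p + coord_fixed() + theme_minimal() +
    labs(x = "Temporal eccentricity (deg)", y = "Elevation (deg)",
         fill = "Rel. sensitivity\n(log units)",
         title = "Ground-truth sensitivity surface")
}

#' Per-frame crossover counts across a sweep
#'
#' Line plot of crossover-seen and crossover-not-seen counts against the
#' display threshold.
#'
#' @param object A `slice_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot slice_sweep
#' @export
autoplot.slice_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$counts,
                              c("n_crossover_seen", "n_crossover_notseen"),
                              names_to = "subset", values_to = "n")
  ggplot(long, aes(.data$display_threshold, .data$n,
                   color = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    theme_minimal() +
    labs(x = "Display threshold C0 (log units)", y = "Trials",
         title = "Display-threshold sweep")
}
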