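# Visual-field coordinate conventions, test grids and the contrast ladder.
#
# All positions are degrees of visual angle in right-eye field coordinates:
# temporal = +x, superior = +y. Contrasts are log10 Weber contrast.

#' Build a rectangular visual-field test grid
#'
#' Constructs the full Cartesian product of two inclusive arithmetic ranges of
#' visual-field positions. The default arguments reproduce the 247-location
#' grid used for high-density testing around the optic nerve head of a right
#' eye: 0.5 degree spacing from 11 to 17 degrees temporally and from -3 to +6
#' degrees vertically (13 columns by 19 rows).
#'
#' @param x_min,x_max Horizontal extent in degrees (temporal positive).
#' @param y_min,y_max Vertical extent in degrees (superior positive).
#' @param spacing Grid spacing in degrees; both ranges must be integer
#'   multiples of it.
#' @return A tibble of class `field_grid` with columns `loc_id`, `x_deg`,
#'   `y_deg` in row-major order (y outer, x inner), and the extents and
#'   spacing stored as attributes.
#' @examples
#' grid <- build_grid()
#' nrow(grid) # 247
#' @export
build_grid <- function(x_min = 11, x_max = 17, y_min = -3, y_max = 6,
                       spacing = 0.5) {
  stopifnot(is.numeric(spacing), length(spacing) == 1)
  if (!is.finite(spacing) || spacing <= 0) {
    abort("`spacing` must be a positive number.")
  }
  if (x_max < x_min) abort("`x_max` must be >= `x_min`.")
  if (y_max < y_min) abort("`y_max` must be >= `y_min`.")
  nx <- axis_steps(x_min, x_max, spacing, "x")
  ny <- axis_steps(y_min, y_max, spacing, "y")
  xs <- x_min + spacing * seq_len(nx + 1) - spacing
  ys <- y_min + spacing * seq_len(ny + 1) - spacing
  grid <- tidyr::expand_grid(y_deg = ys, x_deg = xs)
  grid <- tibble(
    loc_id = seq_len(nrow(grid)),
    x_deg = grid$x_deg,
    y_deg = grid$y_deg
  )
  structure(
    grid,
    class = c("field_grid", class(grid)),
    x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
    spacing = spacing
  )
}

# number of steps along one axis; errors when the range is not a multiple of
# the spacing (tolerance 1e-9 on the fractional part)
axis_steps <- function(lo, hi, spacing, axis) {
  steps <- (hi - lo) / spacing
  if (abs(steps - round(steps)) > 1e-9 * max(1, abs(steps))) {
    abort(sprintf(
      "Range of the %s axis (%g to %g) is not divisible by spacing %g.",
      axis, lo, hi, spacing
    ))
  }
  as.integer(round(steps))
}

#' Build a fine estimation lattice over a grid's extents
#'
#' Returns a `field_grid` spanning the same rectangular extents as `grid` at a
#' finer (or equal) spacing. At 0.05 degrees over the default test region this
#' yields the 121 x 181 = 21,901 estimation locations used by the local
#' maximum-likelihood threshold map.
#'
#' @param grid A `field_grid` (see [build_grid()]).
#' @param spacing Lattice spacing in degrees.
#' @return A `field_grid` tibble.
#' @export
build_estimation_lattice <- function(grid, spacing = 0.05) {
  ext <- grid_extents(grid)
  build_grid(ext$x_min, ext$x_max, ext$y_min, ext$y_max, spacing = spacing)
}

grid_extents <- function(grid) {
  if (inherits(grid, "field_grid")) {
    list(
      x_min = attr(grid, "x_min"), x_max = attr(grid, "x_max"),
      y_min = attr(grid, "y_min"), y_max = attr(grid, "y_max"),
      spacing = attr(grid, "spacing")
    )
  } else {
    stopifnot(all(c("x_deg", "y_deg") %in% names(grid)))
    list(
      x_min = min(grid$x_deg), x_max = max(grid$x_deg),
      y_min = min(grid$y_deg), y_max = max(grid$y_deg),
      spacing = NA_real_
    )
  }
}

#' Build the contrast ladder
#'
#' The set of log10 Weber contrast levels available to the adaptive procedure.
#' The default reproduces the published span: 74 levels from -0.9 to +0.6 log
#' units, so the maximum Weber contrast is 10^0.6 (about 398%, under the 400%
#' device ceiling). The exact level placement on the device is not published;
#' by default levels are uniform in *linear* contrast between the endpoints
#' (which yields a non-uniform log spacing, denser at high contrast), with
#' `scale = "log"` giving uniform log spacing instead.
#'
#' @param min_log,max_log Endpoints in log10 Weber contrast.
#' @param n_levels Number of levels (>= 2).
#' @param scale `"linear"` (default) or `"log"` level placement.
#' @return A numeric vector of strictly increasing log-contrast levels, of
#'   class `contrast_ladder`.
#' @export
build_ladder <- function(min_log = -0.9, max_log = 0.6, n_levels = 74,
                         scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (!is.numeric(n_levels) || n_levels < 2) {
    abort("`n_levels` must be at least 2.")
  }
  if (min_log >= max_log) abort("`min_log` must be below `max_log`.")
  levels <- switch(scale,
    linear = log10(seq(10^min_log, 10^max_log, length.out = n_levels)),
    log = seq(min_log, max_log, length.out = n_levels)
  )
  # endpoints exact despite floating-point round trips
  levels[1] <- min_log
  levels[n_levels] <- max_log
  structure(levels, class = c("contrast_ladder", "numeric"))
}

#' Weber contrast in percent
#'
#' Weber contrast of a luminance increment over a background, as a
#' percentage: `100 * increment / background`. The testing device's maximum
#' increment of 80 cd/m^2 on a 20 cd/m^2 background gives 400%.
#'
#' @param increment Luminance increment in cd/m^2 (>= 0).
#' @param background Background luminance in cd/m^2 (> 0).
#' @return Weber contrast in percent.
#' @examples
#' weber_contrast(80, 20) # 400
#' @export
weber_contrast <- function(increment, background) {
  if (any(background <= 0)) abort("`background` must be positive.")
  if (any(increment < 0)) abort("`increment` must be non-negative.")
  100 * increment / background
}
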