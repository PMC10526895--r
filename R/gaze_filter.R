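# Eye-position trial filtering.
#
# Each stimulus presentation carries three fundus-image frames (two during
# the 60 ms stimulus, one after; one frame every 40 ms). Optic-disc
# displacement from a reference image, in camera pixels, gives eye position
# per frame; the per-axis medians over the three frames give the trial's eye
# displacement, and the nominal stimulus location plus that displacement
# gives the inferred retinal location. Trials are excluded when a frame is
# missing (blink, disc out of image), when displacement varies by more than
# 0.5 degrees among the three frames, or when any frame is shifted by more
# than 1 degree from the reference.

#' Convert camera-pixel displacement to degrees
#'
#' One camera pixel subtends 1.64 arc minutes (0.027 degrees) on the testing
#' device, so displacement in degrees is `pixels * scale / 60`.
#'
#' @param displacement Displacement in camera pixels.
#' @param pixel_scale Arc minutes per pixel (default 1.64).
#' @return Displacement in degrees of visual angle.
#' @examples
#' pixels_to_degrees(1) # 0.0273
#' @export
pixels_to_degrees <- function(displacement, pixel_scale = 1.64) {
  if (pixel_scale <= 0) abort("`pixel_scale` must be positive.")
  displacement * pixel_scale / 60
}

#' Per-trial eye displacement from three frames
#'
#' Applies the frame-validity rules to one trial's three frames and, when the
#' trial is valid, returns the per-axis median displacement in degrees.
#' Exclusions are returned as values (with a reason), never as errors.
#'
#' @param dx_px,dy_px Numeric length-3 frame displacements in camera pixels;
#'   `NA` marks a missing frame.
#' @param missing_reason Optional character length-3: `"none"`, `"blink"` or
#'   `"disc_out_of_image"` per frame.
#' @param pixel_scale Arc minutes per pixel.
#' @param max_range_deg Maximum per-axis spread (max - min) among the three
#'   frames (default 0.5 degrees).
#' @param max_shift_deg Maximum per-axis frame displacement from the
#'   reference image (default 1 degree).
#' @param range_metric `"per_axis"` (default) applies `max_range_deg` to each
#'   axis separately; `"euclidean"` applies it to the largest pairwise
#'   Euclidean distance among the frames.
#' @return A list with `valid` (logical), `reason` (`NA`, `"blink"`,
#'   `"out_of_image"`, `"jitter"` or `"shift"`), and `dx_deg`, `dy_deg`
#'   (medians; `NA` when excluded).
#' @export
trial_displacement <- function(dx_px, dy_px, missing_reason = NULL,
                               pixel_scale = 1.64,
                               max_range_deg = 0.5, max_shift_deg = 1,
                               range_metric = c("per_axis", "euclidean")) {
  range_metric <- match.arg(range_metric)
  stopifnot(length(dx_px) == 3, length(dy_px) == 3)
  excluded <- function(reason) {
    list(valid = FALSE, reason = reason, dx_deg = NA_real_, dy_deg = NA_real_)
  }
  if (anyNA(dx_px) || anyNA(dy_px)) {
    reason <- "blink"
    if (!is.null(missing_reason) &&
        any(missing_reason == "disc_out_of_image", na.rm = TRUE)) {
      reason <- "out_of_image"
    }
    return(excluded(reason))
  }
  dx <- pixels_to_degrees(dx_px, pixel_scale)
  dy <- pixels_to_degrees(dy_px, pixel_scale)
  jitter <- switch(range_metric,
    per_axis = max(diff(range(dx)), diff(range(dy))) > max_range_deg,
    euclidean = max(dist(cbind(dx, dy))) > max_range_deg
  )
  shifted <- any(abs(dx) > max_shift_deg) || any(abs(dy) > max_shift_deg)
  # rule order fixes the label only; the excluded set is order-independent
  if (jitter) return(excluded("jitter"))
  if (shifted) return(excluded("shift"))
  list(valid = TRUE, reason = NA_character_,
       dx_deg = median(dx), dy_deg = median(dy))
}

#' Inferred retinal stimulus location
#'
#' Shifts a nominal stimulus location by the trial's eye displacement. The
#' convention is that the reported displacement is the eye movement, so the
#' stimulus lands at `nominal + displacement` in field coordinates;
#' `infer_retinal_location(x, y, d)` followed by displacement `-d` round-trips
#' to the nominal location.
#'
#' @param x_deg,y_deg Nominal location, degrees.
#' @param dx_deg,dy_deg Trial eye displacement, degrees.
#' @return A list with `x_deg`, `y_deg` of the inferred location.
#' @export
infer_retinal_location <- function(x_deg, y_deg, dx_deg, dy_deg) {
  list(x_deg = x_deg + dx_deg, y_deg = y_deg + dy_deg)
}

#' Filter a session's trials by eye-position validity
#'
#' Joins a trial table with its per-frame gaze table, applies the exclusion
#' rules trial by trial, and augments valid trials with the inferred retinal
#' location. Returns the filtered table plus a per-reason exclusion summary.
#'
#' @param trials Tibble with columns `trial_id`, `nominal_x_deg`,
#'   `nominal_y_deg` (e.g. a `zest_session$trials`).
#' @param gaze Tibble with columns `trial_id`, `frame_idx` (1..3), `dx_px`,
#'   `dy_px`, and optionally `missing_reason`.
#' @param ... Passed to [trial_displacement()] (pixel scale, rule settings).
#' @return A list of class `gaze_filtered`: `trials` (input columns plus
#'   `valid`, `exclusion_reason`, `dx_deg`, `dy_deg`, `inferred_x_deg`,
#'   `inferred_y_deg`) and `summary` (tibble of per-reason counts plus the
#'   overall excluded fraction as attribute columns `n_total`,
#'   `excluded_fraction`).
#' @export
filter_session <- function(trials, gaze, ...) {
  stopifnot(all(c("trial_id", "nominal_x_deg", "nominal_y_deg") %in%
                  names(trials)))
  stopifnot(all(c("trial_id", "frame_idx", "dx_px", "dy_px") %in% names(gaze)))
  gaze <- arrange(gaze, .data$trial_id, .data$frame_idx)
  split_gaze <- split(gaze, gaze$trial_id)
  res <- purrr::map(as.character(trials$trial_id), function(id) {
    g <- split_gaze[[id]]
    if (is.null(g) || nrow(g) != 3) {
      abort(sprintf("Trial %s does not have exactly 3 gaze frames.", id))
    }
    trial_displacement(g$dx_px, g$dy_px,
                       missing_reason = g[["missing_reason"]], ...)
  })
  out <- mutate(
    trials,
    valid = purrr::map_lgl(res, "valid"),
    exclusion_reason = purrr::map_chr(res, "reason"),
    dx_deg = purrr::map_dbl(res, "dx_deg"),
    dy_deg = purrr::map_dbl(res, "dy_deg"),
    inferred_x_deg = .data$nominal_x_deg + .data$dx_deg,
    inferred_y_deg = .data$nominal_y_deg + .data$dy_deg
  )
  summary <- out |>
    filter(!.data$valid) |>
    count(reason = .data$exclusion_reason, name = "n")
  structure(
    list(
      trials = out,
      summary = mutate(summary,
                       n_total = nrow(out),
                       fraction = .data$n / nrow(out)),
      excluded_fraction = mean(!out$valid)
    ),
    class = "gaze_filtered"
  )
}

#' @export
print.gaze_filtered <- function(x, ...) {
  cat(sprintf("<gaze_filtered> %d trials, %.1f%% excluded\n",
              nrow(x$trials), 100 * x$excluded_fraction))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' @describeIn filter_session `tidy()` returns the augmented trial table.
#' @param x A `gaze_filtered` object.
#' @method tidy gaze_filtered
#' @export
tidy.gaze_filtered <- function(x, ...) {
  as_tibble(x$trials)
}

#' @describeIn filter_session `glance()` returns counts and exclusion rate.
#' @method glance gaze_filtered
#' @export
glance.gaze_filtered <- function(x, ...) {
  tibble(
    n_trials = nrow(x$trials),
    n_excluded = sum(!x$trials$valid),
    excluded_fraction = x$excluded_fraction
  )
}

#' Probability of a microsaccade within an imaging window
#'
#' Fixational microsaccades occur at roughly 0.8 per second, so the chance of
#' one landing in the 120 ms spanned by a trial's three frames is about
#' `0.8 * 0.12` = 9.6%, i.e. approximately 10% of trials.
#'
#' @param rate_per_s Microsaccade rate (default 0.8 / s).
#' @param window_s Window duration in seconds (default 0.12).
#' @return Probability of at least one event, linear (rate x window)
#'   approximation.
#' @export
microsaccade_probability <- function(rate_per_s = 0.8, window_s = 0.12) {
  stopifnot(rate_per_s >= 0, window_s >= 0)
  rate_per_s * window_s
}
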