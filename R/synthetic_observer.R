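# Synthetic observer: ground-truth sensitivity surfaces (blind spot plus
# vessel angioscotomas) and full simulated test sessions with fixational
# eye movements and frame corruption.

#' Ground-truth sensitivity surface
#'
#' Defines a synthetic right-eye visual-field region containing a deep
#' blind-spot scotoma (an ellipse where nothing is seen at any available
#' contrast) and shallow, narrow angioscotomas — threshold elevations along
#' vessel polylines with a Gaussian cross-section. The local threshold is
#' `baseline_alpha` plus the vessel depressions, or unseeable (infinite)
#' inside the blind spot.
#'
#' @param baseline_alpha Background log-contrast threshold (default -0.35,
#'   inside the range of display thresholds used for real subjects).
#' @param blind_spot List with `center_x`, `center_y`, `semi_x`, `semi_y`
#'   (degrees) describing the blind-spot ellipse, or `NULL` for none.
#' @param vessels List of vessel descriptors, each a list with `path` (a
#'   2-column matrix/data frame of polyline vertices in degrees), `width`
#'   (full width, degrees; default 0.5) and `depth` (threshold elevation at
#'   the centreline, log units; default 0.3).
#' @param beta Slope of the frequency-of-seeing curve everywhere
#'   (default 3.5).
#' @param gamma,lam Guess and lapse rates (default 0.02).
#' @param vessel_profile `"gaussian"` (scale = width / 2; default) or
#'   `"rect"` cross-section.
#' @return A list of class `sensitivity_surface`.
#' @export
sensitivity_surface <- function(baseline_alpha = -0.35, blind_spot = NULL,
                                vessels = list(), beta = 3.5,
                                gamma = 0.02, lam = 0.02,
                                vessel_profile = c("gaussian", "rect")) {
  vessel_profile <- match.arg(vessel_profile)
  vessels <- purrr::map(vessels, function(v) {
    v$path <- as.matrix(v$path)
    v$width <- v$width %||% 0.5
    v$depth <- v$depth %||% 0.3
    v
  })
  structure(
    list(baseline_alpha = baseline_alpha, blind_spot = blind_spot,
         vessels = vessels, beta = beta, gamma = gamma, lam = lam,
         vessel_profile = vessel_profile),
    class = "sensitivity_surface"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# distance from point to a polyline (minimum over segments)
point_polyline_distance <- function(x, y, path) {
  dmin <- Inf
  for (s in seq_len(nrow(path) - 1)) {
    ax <- path[s, 1]; ay <- path[s, 2]
    bx <- path[s + 1, 1]; by <- path[s + 1, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) 0 else pmin(pmax(((x - ax) * vx + (y - ay) * vy) /
                                           len2, 0), 1)
    d <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
    dmin <- pmin(dmin, d)
  }
  dmin
}

in_blind_spot <- function(surface, x, y) {
  bs <- surface$blind_spot
  if (is.null(bs)) return(rep(FALSE, length(x)))
  ((x - bs$center_x) / bs$semi_x)^2 + ((y - bs$center_y) / bs$semi_y)^2 <= 1
}

#' Ground-truth threshold at field locations
#'
#' The local log-contrast threshold of a surface: baseline plus the summed
#' vessel depressions, and `Inf` (unseeable — detection probability stays at
#' the guess rate for any available contrast) inside the blind spot.
#' Vectorised over locations.
#'
#' @param surface A [sensitivity_surface()].
#' @param x_deg,y_deg Query locations, degrees.
#' @return Thresholds in log units (`Inf` inside the blind spot).
#' @export
surface_alpha <- function(surface, x_deg, y_deg) {
  stopifnot(all(is.finite(x_deg)), all(is.finite(y_deg)))
  alpha <- rep(surface$baseline_alpha, length(x_deg))
  for (v in surface$vessels) {
    d <- point_polyline_distance(x_deg, y_deg, v$path)
    bump <- switch(surface$vessel_profile,
      gaussian = v$depth * exp(-d^2 / (2 * (v$width / 2)^2)),
      rect = ifelse(d <= v$width / 2, v$depth, 0)
    )
    alpha <- alpha + bump
  }
  alpha[in_blind_spot(surface, x_deg, y_deg)] <- Inf
  alpha
}

# psychometric parameters of the surface at one point
surface_params <- function(surface, x_deg, y_deg, gamma = NULL, lam = NULL) {
  list(alpha = surface_alpha(surface, x_deg, y_deg),
       beta = surface$beta,
       gamma = gamma %||% surface$gamma,
       lam = lam %||% surface$lam)
}

#' Deterministic response-free observer from a surface
#'
#' Returns a stochastic observer callback drawing each response from the
#' surface's local frequency-of-seeing curve (uses the session RNG).
#'
#' @param surface A [sensitivity_surface()].
#' @return A function `(x_deg, y_deg, contrast) -> logical`.
#' @export
surface_observer <- function(surface) {
  function(x_deg, y_deg, contrast) {
    runif(1) < detection_probability(surface_params(surface, x_deg, y_deg),
                                     contrast)
  }
}

#' A synthetic subject resembling the optic-nerve-head region
#'
#' A ready-made surface for the default 11-17 x -3-6 degree test region of a
#' right eye: a deep elliptical blind spot centred near (15, 1.5) with
#' semi-axes of roughly 2.5 x 3.5 degrees, and vessel angioscotomas
#' (0.5-degree-wide, 0.3-log-unit-deep) arcing away from the disc. The
#' vessel paths are jittered deterministically by `seed`.
#'
#' @param seed Integer seed controlling the vessel-path jitter.
#' @param n_vessels Number of vessels (2 or 3; default 2).
#' @return A [sensitivity_surface()].
#' @export
make_paper_like_subject <- function(seed = 1, n_vessels = 2) {
  stopifnot(n_vessels %in% 2:3)
  withr::with_seed(seed, {
    jitter <- function(n) rnorm(n, 0, 0.08)
    # vessels leave the disc (near x = 14.2) and arc temporally/vertically
    xs <- seq(11, 14.2, by = 0.4)
    v1 <- list(
      path = cbind(xs, -1.2 + 0.25 * (xs - 11) + jitter(length(xs))),
      width = 0.5, depth = 0.3
    )
    v2 <- list(
      path = cbind(xs, 4.6 - 0.35 * (xs - 11) + jitter(length(xs))),
      width = 0.5, depth = 0.3
    )
    vessels <- list(v1, v2)
    if (n_vessels == 3) {
      vessels[[3]] <- list(
        path = cbind(xs, 1.4 - 0.05 * (xs - 11) + jitter(length(xs))),
        width = 0.5, depth = 0.3
      )
    }
    sensitivity_surface(
      baseline_alpha = -0.35,
      blind_spot = list(center_x = 15, center_y = 1.5,
                        semi_x = 2.5, semi_y = 3.5),
      vessels = vessels
    )
  })
}

#' Fixational eye-movement model
#'
#' Per-trial eye displacement for the simulated sessions: a Gaussian
#' fixational drift (constant across a trial's three 40-ms frames),
#' microsaccade events at about 0.8 per second (so roughly 10% of 120-ms
#' frame windows contain one) that shift the later frames, and blinks that
#' obscure one frame.
#'
#' @param drift_sd Per-trial drift SD per axis, degrees (default 0.15).
#' @param microsaccade_rate Events per second (default 0.8).
#' @param microsaccade_amplitude_sd Per-axis amplitude SD of a microsaccade,
#'   degrees (default 0.4).
#' @param blink_prob Probability a trial contains a blink (default 0.05).
#' @param frame_interval_ms Frame spacing (default 40 ms; three frames span
#'   120 ms).
#' @return A list of class `eye_movement_model`.
#' @export
eye_movement_model <- function(drift_sd = 0.15, microsaccade_rate = 0.8,
                               microsaccade_amplitude_sd = 0.4,
                               blink_prob = 0.05, frame_interval_ms = 40) {
  stopifnot(drift_sd >= 0, microsaccade_rate >= 0, blink_prob >= 0,
            blink_prob <= 1)
  structure(
    list(drift_sd = drift_sd, microsaccade_rate = microsaccade_rate,
         microsaccade_amplitude_sd = microsaccade_amplitude_sd,
         blink_prob = blink_prob, frame_interval_ms = frame_interval_ms,
         frames_per_trial = 3L),
    class = "eye_movement_model"
  )
}

# one trial's eye state: displacement per frame (degrees) + blink flag
draw_trial_gaze <- function(model) {
  drift <- rnorm(2, 0, model$drift_sd)
  dx <- rep(drift[1], 3)
  dy <- rep(drift[2], 3)
  window_s <- model$frames_per_trial * model$frame_interval_ms / 1000
  saccade <- runif(1) < microsaccade_probability(model$microsaccade_rate,
                                                window_s)
  if (saccade) {
    amp <- rnorm(2, 0, model$microsaccade_amplitude_sd)
    from <- sample(2:3, 1)  # saccade lands mid-trial; later frames shift
    dx[from:3] <- dx[from:3] + amp[1]
    dy[from:3] <- dy[from:3] + amp[2]
  }
  blink_frame <- if (runif(1) < model$blink_prob) sample(1:3, 1) else 0L
  list(dx = dx, dy = dy, saccade = saccade, blink_frame = blink_frame)
}

#' Simulate a full high-density testing session
#'
#' Runs a ZEST session over a grid against a ground-truth surface while
#' simulating fixational eye movements: on each presentation the eye is
#' displaced, the response is drawn from the frequency-of-seeing curve at
#' the *displaced* retinal location, and three frame records (with optional
#' blink corruption) are produced for the gaze filter. Identical seeds give
#' identical outputs.
#'
#' @param surface A [sensitivity_surface()].
#' @param grid A `field_grid` of nominal locations.
#' @param eye_model An [eye_movement_model()].
#' @param seed Integer seed.
#' @param pixel_scale Arc minutes per camera pixel used to encode frame
#'   displacements (default 1.64).
#' @param frame_noise_px Per-frame, per-axis registration noise SD in camera
#'   pixels (default 0.5; about 0.014 degrees).
#' @param ... Passed to [run_zest_session()] (ladder, n_presentations, ...).
#' @return A list of class `simulated_session`: `trials` (the ZEST trial
#'   table), `estimates`, `gaze` (tibble: trial_id, frame_idx, dx_px, dy_px,
#'   missing_reason), and `truth` (tibble of per-trial true displacement and
#'   true retinal location, plus the surface in `$surface`).
#' @export
simulate_session <- function(surface, grid = build_grid(),
                             eye_model = eye_movement_model(),
                             seed = 1, pixel_scale = 1.64,
                             frame_noise_px = 0.5, ...) {
  gaze_log <- list()
  truth_log <- list()
  counter <- 0L
  observer <- function(x, y, contrast) {
    counter <<- counter + 1L
    g <- draw_trial_gaze(eye_model)
    # response uses the eye position during the stimulus (frame 1 drift)
    rx <- x + g$dx[1]
    ry <- y + g$dy[1]
    seen <- runif(1) < detection_probability(surface_params(surface, rx, ry),
                                             contrast)
    noisy_dx <- g$dx / (pixel_scale / 60) + rnorm(3, 0, frame_noise_px)
    noisy_dy <- g$dy / (pixel_scale / 60) + rnorm(3, 0, frame_noise_px)
    missing <- rep("none", 3)
    if (g$blink_frame > 0) {
      missing[g$blink_frame] <- "blink"
      noisy_dx[g$blink_frame] <- NA_real_
      noisy_dy[g$blink_frame] <- NA_real_
    }
    gaze_log[[counter]] <<- tibble(
      obs_index = counter, frame_idx = 1:3,
      dx_px = noisy_dx, dy_px = noisy_dy, missing_reason = missing
    )
    truth_log[[counter]] <<- tibble(
      obs_index = counter, true_dx_deg = g$dx[1], true_dy_deg = g$dy[1],
      true_x_deg = rx, true_y_deg = ry,
      saccade = g$saccade, blink = g$blink_frame > 0
    )
    seen
  }
  session <- run_zest_session(grid, observer, seed = seed, ...)
  trials <- session$trials
  gaze <- bind_rows(gaze_log)
  truth <- bind_rows(truth_log)
  # observer calls happen in trial order, so obs_index aligns with trial_id
  gaze$trial_id <- trials$trial_id[gaze$obs_index]
  truth$trial_id <- trials$trial_id[truth$obs_index]
  structure(
    list(
      trials = trials,
      estimates = session$estimates,
      gaze = select(gaze, "trial_id", "frame_idx", "dx_px", "dy_px",
                    "missing_reason"),
      truth = list(per_trial = select(truth, "trial_id",
                                      dplyr::everything(), -"obs_index"),
                   surface = surface,
                   eye_model = eye_model, seed = seed),
      config = session$config
    ),
    class = "simulated_session"
  )
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("<simulated_session> %d trials over %d locations\n",
              nrow(x$trials), nrow(x$estimates)))
  invisible(x)
}
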