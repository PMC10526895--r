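# Shared fixtures and independent oracles for the test suite.

# deterministic observer: sees iff contrast is at or above a fixed threshold
step_observer <- function(threshold) {
  function(x, y, contrast) contrast >= threshold
}

# brute-force ZEST posterior: normalised product of prior and per-trial
# Quick-Weibull likelihoods, computed directly (independent of zest_update)
brute_force_posterior <- function(domain, prior, responses, likelihood) {
  post <- prior
  for (r in seq_len(nrow(responses))) {
    p_seen <- likelihood$gamma + (1 - likelihood$gamma - likelihood$lam) *
      (1 - 2^(-(10^(likelihood$beta *
                      (responses$contrast[r] - domain)))))
    post <- post * if (responses$seen[r]) p_seen else 1 - p_seen
  }
  post / sum(post)
}

# independent fine grid search over (alpha, beta) for the weighted
# Quick-Weibull likelihood; used as the oracle against optim-based fits
grid_search_fit <- function(contrast, seen, w, gamma = 0.02, lam = 0.02,
                            alpha_grid = seq(-1.2, 0.9, by = 0.005),
                            beta_grid = exp(seq(log(0.5), log(20),
                                                length.out = 60))) {
  best <- c(NA, NA, -Inf)
  for (b in beta_grid) {
    for (a in alpha_grid) {
      p <- gamma + (1 - gamma - lam) * (1 - 2^(-(10^(b * (contrast - a)))))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- sum(w * (seen * log(p) + (1 - seen) * log(1 - p)))
      if (ll > best[3]) best <- c(a, b, ll)
    }
  }
  list(alpha = best[1], beta = best[2], logLik = best[3])
}

# small flat-sensitivity surface (no blind spot, no vessels)
flat_surface <- function(alpha = -0.35, beta = 3.5) {
  sensitivity_surface(baseline_alpha = alpha, blind_spot = NULL,
                      vessels = list(), beta = beta)
}

# gaze frames for a clean trial with constant displacement, in pixels
constant_frames <- function(dx_deg, dy_deg, pixel_scale = 1.64) {
  list(dx_px = rep(dx_deg * 60 / pixel_scale, 3),
       dy_px = rep(dy_deg * 60 / pixel_scale, 3))
}

# build a trial + gaze table pair with prescribed per-trial frame sets
make_gaze_tables <- function(frame_sets) {
  trials <- tibble::tibble(
    trial_id = seq_along(frame_sets),
    nominal_x_deg = 12, nominal_y_deg = 0,
    log_contrast = -0.3, seen = TRUE
  )
  gaze <- purrr::imap(frame_sets, function(fr, id) {
    tibble::tibble(
      trial_id = id, frame_idx = 1:3,
      dx_px = fr$dx_px, dy_px = fr$dy_px,
      missing_reason = fr$missing_reason %||% rep("none", 3)
    )
  })
  list(trials = trials, gaze = dplyr::bind_rows(gaze))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
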