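# Quick-Weibull frequency-of-seeing model and ZEST adaptive thresholding.

#' Psychometric parameters for the Quick-Weibull frequency-of-seeing curve
#'
#' @param alpha Contrast threshold in log10 Weber contrast.
#' @param beta Dimensionless slope (> 0).
#' @param gamma False-positive (guess) rate in \[0, 1).
#' @param lam False-negative (lapse) rate in \[0, 1); `gamma + lam < 1`.
#' @return A list of class `psychometric_params`.
#' @export
psychometric_params <- function(alpha, beta = 3.5, gamma = 0.02, lam = 0.02) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            is.numeric(lam))
  if (beta <= 0) abort("`beta` must be positive.")
  if (gamma < 0 || gamma >= 1 || lam < 0 || lam >= 1 || gamma + lam >= 1) {
    abort("`gamma` and `lam` must lie in [0, 1) with gamma + lam < 1.")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lam = lam),
            class = "psychometric_params")
}

#' Probability of detecting a stimulus
#'
#' Quick's form of the Weibull psychometric function with guess and lapse
#' rates:
#' \deqn{\Psi(c) = \gamma + (1 - \gamma - \lambda)\,
#'   \left(1 - 2^{-(C/A)^{\beta}}\right)}
#' where \eqn{C = 10^{c}} and \eqn{A = 10^{\alpha}} are linear Weber
#' contrasts. At `contrast == alpha` with equal guess and lapse rates the
#' probability is exactly 0.5 — threshold is the contrast seen half the time.
#'
#' @param params A [psychometric_params()] object (or list with fields
#'   `alpha`, `beta`, `gamma`, `lam`).
#' @param contrast Stimulus contrast(s), log10 Weber contrast. Vectorised
#'   over `contrast` and over `params$alpha`.
#' @return Detection probability in `[gamma, 1 - lam]`.
#' @examples
#' detection_probability(psychometric_params(alpha = -0.2), -0.2) # 0.5
#' @export
detection_probability <- function(params, contrast) {
  # (C/A)^beta = 10^(beta * (c - alpha)); for alpha = +Inf (absolute
  # scotoma) the exponent is 0 and the probability collapses to gamma
  expo <- 10^(params$beta * (contrast - params$alpha))
  params$gamma + (1 - params$gamma - params$lam) * (1 - 2^(-expo))
}

#' Initialise a ZEST state
#'
#' ZEST (Zippy Estimation by Sequential Testing) maintains a probability mass
#' function over candidate thresholds — here, the contrast-ladder levels —
#' and updates it by Bayes' rule after each response. The default prior is
#' uniform over the ladder; a Gaussian prior centred on `prior_mean` (SD
#' `prior_sd`) is available.
#'
#' @param domain A [build_ladder()] vector (candidate thresholds, log units).
#' @param prior `"uniform"`, `"gaussian"`, or a numeric vector of unnormalised
#'   prior masses of the same length as `domain`.
#' @param prior_mean,prior_sd Centre and width (log units) of the Gaussian
#'   prior.
#' @return A list of class `zest_state` with fields `domain`, `pdf`,
#'   `n_presented`, `history` (tibble of contrast/seen).
#' @export
zest_init <- function(domain, prior = "uniform", prior_mean = 0,
                      prior_sd = 0.5) {
  domain <- as.numeric(domain)
  if (length(domain) == 0) abort("ZEST domain must be non-empty.")
  pdf <- if (is.numeric(prior)) {
    if (length(prior) != length(domain)) {
      abort("Numeric prior must match the domain length.")
    }
    if (any(prior < 0) || sum(prior) <= 0) {
      abort("Prior masses must be non-negative with positive sum.")
    }
    prior
  } else {
    switch(match.arg(prior, c("uniform", "gaussian")),
      uniform = rep(1, length(domain)),
      gaussian = exp(-(domain - prior_mean)^2 / (2 * prior_sd^2))
    )
  }
  structure(
    list(
      domain = domain,
      pdf = pdf / sum(pdf),
      n_presented = 0L,
      history = tibble(contrast = numeric(), seen = logical())
    ),
    class = "zest_state"
  )
}

#' Next stimulus contrast for a ZEST state
#'
#' The posterior mean threshold, snapped to the nearest ladder level (ties
#' broken toward the lower contrast). Deterministic given the state.
#'
#' @param state A `zest_state`.
#' @param rule `"mean"` (default) or `"mode"` of the posterior.
#' @return A log-contrast level from the state's domain.
#' @export
zest_next_stimulus <- function(state, rule = c("mean", "mode")) {
  rule <- match.arg(rule)
  target <- switch(rule,
    mean = sum(state$domain * state$pdf),
    mode = state$domain[which.max(state$pdf)]
  )
  snap_to_domain(target, state$domain)
}

# nearest domain level; on an exact tie prefer the lower contrast
snap_to_domain <- function(x, domain) {
  d <- abs(domain - x)
  idx <- which(d <= min(d) + 1e-12)
  domain[min(idx)]
}

#' Bayes update of a ZEST state after one response
#'
#' Multiplies the threshold pdf by the likelihood of the observed response
#' under the Quick-Weibull curve with each candidate threshold, then
#' renormalises. Seen responses move mass toward lower thresholds; not-seen
#' responses toward higher ones.
#'
#' @param state A `zest_state`.
#' @param contrast Presented contrast, log units.
#' @param seen Logical response.
#' @param likelihood Psychometric parameters of the update likelihood; its
#'   `alpha` is ignored (replaced by each domain level in turn).
#' @return The updated `zest_state`.
#' @export
zest_update <- function(state, contrast, seen,
                        likelihood = psychometric_params(alpha = 0)) {
  p_seen <- detection_probability(
    list(alpha = state$domain, beta = likelihood$beta,
         gamma = likelihood$gamma, lam = likelihood$lam),
    contrast
  )
  lik <- if (isTRUE(seen)) p_seen else 1 - p_seen
  post <- state$pdf * lik
  total <- sum(post)
  if (!is.finite(total) || total <= 0) {
    abort("ZEST update produced zero posterior mass; check gamma/lam > 0.")
  }
  state$pdf <- post / total
  state$n_presented <- state$n_presented + 1L
  state$history <- bind_rows(state$history,
                             tibble(contrast = contrast, seen = isTRUE(seen)))
  state
}

#' Threshold estimate from a ZEST state
#'
#' The mean of the current threshold pdf, in log units.
#'
#' @param state A `zest_state`.
#' @return Log-contrast threshold estimate.
#' @export
zest_estimate <- function(state) {
  sum(state$domain * state$pdf)
}

#' Run a full ZEST session over a test grid
#'
#' Runs an independent ZEST track at every grid location, presenting
#' `n_presentations` stimuli per location (six in the published procedure, so
#' the default 247-location grid yields 1,482 threshold trials). The observer
#' is a callback `function(x_deg, y_deg, contrast)` returning `TRUE` when the
#' stimulus is seen. Optional catch trials — blank presentations
#' (false-positive probes) and maximum-contrast presentations (false-negative
#' probes) — are interleaved at the configured per-trial rates and reported
#' separately from threshold trials.
#'
#' @param grid A `field_grid` of nominal locations.
#' @param observer Response callback `function(x_deg, y_deg, contrast)`.
#' @param ladder Contrast ladder, the ZEST domain.
#' @param n_presentations Presentations per location (default 6).
#' @param likelihood ZEST update likelihood parameters (slope beta = 3.5,
#'   gamma = lam = 0.02 by default).
#' @param prior,prior_mean,prior_sd Passed to [zest_init()].
#' @param rule Stimulus-placement rule, `"mean"` or `"mode"` of the pdf.
#' @param catch_fp_rate,catch_fn_rate Per-trial probabilities of inserting a
#'   blank or a maximum-contrast catch trial (default 0 = off).
#' @param stimulus_duration_ms,isi_mean_ms Timing metadata copied onto each
#'   trial record (not enforced).
#' @param seed Integer seed for catch-trial randomisation (and for any
#'   randomness in `observer` if it uses the session RNG stream).
#' @return A list of class `zest_session`: `trials` (tibble: trial_id,
#'   loc_id, nominal_x_deg, nominal_y_deg, log_contrast, seen, is_catch,
#'   block_id, duration_ms, isi_ms), `estimates` (tibble: loc_id, x_deg,
#'   y_deg, threshold_log, n_trials), and `config`.
#' @export
run_zest_session <- function(grid, observer,
                             ladder = build_ladder(),
                             n_presentations = 6L,
                             likelihood = psychometric_params(alpha = 0),
                             prior = "uniform", prior_mean = 0, prior_sd = 0.5,
                             rule = "mean",
                             catch_fp_rate = 0, catch_fn_rate = 0,
                             stimulus_duration_ms = 60,
                             isi_mean_ms = 1200,
                             seed = NULL) {
  stopifnot(is.function(observer), n_presentations >= 1)
  run <- function() {
    blocks <- assign_blocks(grid)
    trial_rows <- vector("list", nrow(grid))
    est_rows <- vector("list", nrow(grid))
    trial_id <- 0L
    max_level <- max(as.numeric(ladder))
    for (i in seq_len(nrow(grid))) {
      x <- grid$x_deg[i]; y <- grid$y_deg[i]
      state <- zest_init(ladder, prior = prior, prior_mean = prior_mean,
                         prior_sd = prior_sd)
      rows <- list()
      for (k in seq_len(n_presentations)) {
        # catch trials do not count toward the ZEST presentation budget
        for (catch in catch_draw(catch_fp_rate, catch_fn_rate)) {
          c_catch <- if (catch == "fp") -Inf else max_level
          seen_c <- observe_at(observer, x, y, c_catch, i)
          trial_id <- trial_id + 1L
          rows[[length(rows) + 1L]] <- tibble(
            trial_id = trial_id, loc_id = grid$loc_id[i],
            nominal_x_deg = x, nominal_y_deg = y,
            log_contrast = c_catch, seen = seen_c,
            is_catch = TRUE, catch_kind = catch
          )
        }
        contrast <- zest_next_stimulus(state, rule = rule)
        seen <- observe_at(observer, x, y, contrast, i)
        state <- zest_update(state, contrast, seen, likelihood = likelihood)
        trial_id <- trial_id + 1L
        rows[[length(rows) + 1L]] <- tibble(
          trial_id = trial_id, loc_id = grid$loc_id[i],
          nominal_x_deg = x, nominal_y_deg = y,
          log_contrast = contrast, seen = seen,
          is_catch = FALSE, catch_kind = NA_character_
        )
      }
      trial_rows[[i]] <- bind_rows(rows)
      est_rows[[i]] <- tibble(
        loc_id = grid$loc_id[i], x_deg = x, y_deg = y,
        threshold_log = zest_estimate(state),
        n_trials = n_presentations
      )
    }
    trials <- bind_rows(trial_rows)
    trials$block_id <- blocks[match(trials$loc_id, grid$loc_id)]
    trials$duration_ms <- stimulus_duration_ms
    trials$isi_ms <- isi_mean_ms
    structure(
      list(
        trials = trials,
        estimates = bind_rows(est_rows),
        config = list(
          n_presentations = n_presentations, rule = rule,
          likelihood = unclass(likelihood), prior = prior,
          catch_fp_rate = catch_fp_rate, catch_fn_rate = catch_fn_rate,
          seed = seed
        )
      ),
      class = "zest_session"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

observe_at <- function(observer, x, y, contrast, loc_index) {
  seen <- tryCatch(observer(x, y, contrast), error = function(e) {
    abort(sprintf("Observer failed at location %d (%.2f, %.2f): %s",
                  loc_index, x, y, conditionMessage(e)))
  })
  isTRUE(as.logical(seen))
}

catch_draw <- function(fp_rate, fn_rate) {
  kinds <- character()
  if (fp_rate > 0 && runif(1) < fp_rate) kinds <- c(kinds, "fp")
  if (fn_rate > 0 && runif(1) < fn_rate) kinds <- c(kinds, "fn")
  kinds
}

# Block labels: locations sharing the same offset within a 2-degree cell are
# tested together (the published sessions combined coarse 2-degree blocks into
# the 0.5-degree grid; the exact partition was not published, so this is one
# deterministic choice).
assign_blocks <- function(grid, block_deg = 2) {
  sp <- attr(grid, "spacing")
  if (is.null(sp) || !is.finite(sp) || block_deg %% sp != 0) {
    return(rep(1L, nrow(grid)))
  }
  ox <- round((grid$x_deg - min(grid$x_deg)) / sp) %% round(block_deg / sp)
  oy <- round((grid$y_deg - min(grid$y_deg)) / sp) %% round(block_deg / sp)
  as.integer(ox + round(block_deg / sp) * oy + 1)
}

#' @export
print.zest_session <- function(x, ...) {
  cat(sprintf(
    "<zest_session> %d locations, %d trials (%d catch)\n",
    nrow(x$estimates), nrow(x$trials), sum(x$trials$is_catch)
  ))
  invisible(x)
}

#' @describeIn run_zest_session `tidy()` returns the per-location threshold
#'   estimates with sensitivity in log units.
#' @param x A `zest_session`.
#' @param ... Unused.
#' @method tidy zest_session
#' @export
tidy.zest_session <- function(x, ...) {
  mutate(x$estimates, sensitivity_log = -.data$threshold_log)
}

#' @describeIn run_zest_session `glance()` returns one-row session summary.
#' @method glance zest_session
#' @export
glance.zest_session <- function(x, ...) {
  tibble(
    n_locations = nrow(x$estimates),
    n_trials = sum(!x$trials$is_catch),
    n_catch = sum(x$trials$is_catch),
    mean_threshold_log = mean(x$estimates$threshold_log)
  )
}
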