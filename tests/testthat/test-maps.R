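test_that("conventional map is the sign-flipped threshold field", {
  est <- tibble::tibble(x_deg = c(11, 11.5, 12), y_deg = 0,
                        threshold_log = c(0, -0.3, log10(2)))
  m <- conventional_map(est)
  expect_equal(m$map$sensitivity_log, c(0, 0.3, -log10(2)))
  expect_true(all(m$map$fit_status == "ok"))
})

test_that("missing grid locations are flagged, not dropped", {
  g <- build_grid(11, 12, 0, 0, 0.5)
  est <- tibble::tibble(x_deg = c(11, 12), y_deg = 0,
                        threshold_log = c(0.1, 0.2))
  expect_warning(m <- conventional_map(est, g), "no threshold estimate")
  expect_equal(nrow(m$map), 3)
  expect_equal(sum(m$map$fit_status == "missing"), 1)
})

test_that("kernel weight follows the Gaussian with SD 0.5 degrees", {
  expect_equal(kernel_weight(0), 1)
  expect_equal(kernel_weight(0.5), exp(-0.5))
  expect_equal(kernel_weight(1, kernel_sd = 1), exp(-0.5))
})

test_that("weighted ML fit recovers parameters from co-located trials", {
  # trials generated from a known curve at 6 contrasts x 20 repetitions,
  # all at distance 0; alpha recovered within 0.05 log units and the fit
  # agrees with an independent fine grid search of the same likelihood
  truth <- psychometric_params(alpha = 0.1, beta = 3.5)
  contrasts <- rep(seq(-0.2, 0.4, length.out = 6), each = 20)
  seen <- withr::with_seed(31, runif(length(contrasts)) <
                             detection_probability(truth, contrasts))
  trials <- tibble::tibble(
    inferred_x_deg = 12, inferred_y_deg = 1,
    log_contrast = contrasts, seen = seen
  )
  fit <- weighted_ml_fit(trials, 12, 1)
  expect_equal(fit$fit_status, "ok")
  expect_lt(abs(fit$alpha_log - 0.1), 0.05)
  oracle <- grid_search_fit(contrasts, as.numeric(seen),
                            rep(1, length(contrasts)))
  expect_lt(abs(fit$alpha_log - oracle$alpha), 0.01)
  expect_equal(fit$sensitivity_log, -fit$alpha_log)
})

test_that("degenerate neighbourhoods are flagged instead of crashing", {
  # all-seen single-contrast data carries no crossing information: alpha
  # is pinned at the search floor and flagged
  trials <- tibble::tibble(inferred_x_deg = 12, inferred_y_deg = 1,
                           log_contrast = 0, seen = TRUE)
  trials <- trials[rep(1, 10), ]
  fit <- weighted_ml_fit(trials, 12, 1)
  expect_equal(fit$fit_status, "boundary")
  expect_lt(fit$alpha_log, -1.1)

  sparse <- trials[1:2, ]
  expect_equal(weighted_ml_fit(sparse, 12, 1)$fit_status, "too_few_trials")
})

test_that("only trials within the inclusion radius enter a fit", {
  trials <- tibble::tibble(
    inferred_x_deg = c(rep(12, 6), rep(13.5, 6)),
    inferred_y_deg = 1,
    log_contrast = rep(c(-0.5, 0.5), 6),
    seen = rep(c(FALSE, TRUE), 6)
  )
  fit <- weighted_ml_fit(trials, 12, 1, radius = 0.5)
  expect_equal(fit$n_trials_in_radius, 6L)
})

test_that("the map equals pointwise fits over its lattice", {
  surf <- flat_surface()
  sess <- simulate_session(surf, build_grid(11, 13, 0, 2, 0.5),
                           eye_movement_model(blink_prob = 0), seed = 17)
  f <- filter_session(sess$trials, sess$gaze)
  valid <- dplyr::filter(f$trials, valid)
  lattice <- build_grid(11.5, 12.5, 0.5, 1.5, 0.5)
  m <- ml_threshold_map(valid, lattice)
  direct <- dplyr::bind_rows(purrr::map2(
    lattice$x_deg, lattice$y_deg,
    function(x, y) weighted_ml_fit(valid, x, y)
  ))
  expect_equal(m$map$alpha_log, direct$alpha_log)
  expect_equal(m$map$beta, direct$beta)
  expect_equal(m$map$point_id, lattice$loc_id)
})

test_that("an empty trial set yields an all-undefined map", {
  empty <- tibble::tibble(inferred_x_deg = numeric(), inferred_y_deg =
                            numeric(), log_contrast = numeric(),
                          seen = logical())
  m <- ml_threshold_map(empty, build_grid(11, 12, 0, 1, 0.5))
  expect_true(all(is.na(m$map$alpha_log)))
  expect_true(all(m$map$fit_status == "too_few_trials"))
})

test_that("nominal locations are used when gaze columns are absent", {
  trials <- tibble::tibble(nominal_x_deg = 12, nominal_y_deg = 1,
                           log_contrast = rep(c(-0.5, 0.5), 10),
                           seen = rep(c(FALSE, TRUE), 10))
  m <- ml_threshold_map(trials, build_grid(12, 12, 1, 1, 0.5))
  expect_equal(m$map$fit_status, "ok")
})

test_that("map recovery on a flat observer stays within 0.1 log units", {
  surf <- flat_surface()
  grid <- build_grid(11, 14, 0, 3, 0.5)
  sess <- simulate_session(surf, grid,
                           eye_movement_model(drift_sd = 0.1,
                                              blink_prob = 0),
                           seed = 29)
  f <- filter_session(sess$trials, sess$gaze)
  valid <- dplyr::filter(f$trials, valid)
  lattice <- build_grid(11.5, 13.5, 0.5, 2.5, 0.25)
  m <- ml_threshold_map(valid, lattice)
  ok <- dplyr::filter(m$map, fit_status == "ok")
  expect_gt(nrow(ok), 0.5 * nrow(lattice))
  err <- abs(ok$alpha_log - surf$baseline_alpha)
  expect_lte(median(err), 0.1)
})

test_that("display clamping respects the rendering range", {
  expect_equal(clamp_display(c(-2, 0, 2)), c(-0.5, 0, 1))
})
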