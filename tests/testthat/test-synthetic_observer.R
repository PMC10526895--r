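test_that("surface thresholds combine baseline, vessels and blind spot", {
  surf <- sensitivity_surface(
    baseline_alpha = -0.35,
    blind_spot = list(center_x = 15, center_y = 1.5,
                      semi_x = 2.5, semi_y = 3.5),
    vessels = list(list(path = cbind(c(11, 13), c(0, 0)),
                        width = 0.5, depth = 0.3))
  )
  # far from all features
  expect_equal(surface_alpha(surf, 11, -3), -0.35, tolerance = 1e-6)
  # on the vessel centreline the full depth applies
  expect_equal(surface_alpha(surf, 12, 0), -0.05, tolerance = 1e-9)
  # half-width off the centreline the Gaussian profile has decayed
  expect_lt(surface_alpha(surf, 12, 0.25), -0.35 + 0.3 * exp(-0.5) + 1e-9)
  # inside the blind spot nothing is seen even at the ladder maximum
  expect_equal(surface_alpha(surf, 15, 1.5), Inf)
  p <- detection_probability(
    list(alpha = surface_alpha(surf, 15, 1.5), beta = 3.5,
         gamma = 0.02, lam = 0.02), max(build_ladder()))
  expect_equal(p, 0.02)
})

test_that("rectangular vessel profiles are available", {
  surf <- sensitivity_surface(
    vessels = list(list(path = cbind(c(0, 2), c(0, 0)), width = 0.5,
                        depth = 0.3)),
    vessel_profile = "rect"
  )
  expect_equal(surface_alpha(surf, 1, 0.2), -0.05)
  expect_equal(surface_alpha(surf, 1, 0.3), -0.35)
})

test_that("the ready-made subject matches its documented geometry", {
  surf <- make_paper_like_subject(seed = 2)
  expect_equal(surface_alpha(surf, 11, -3), surf$baseline_alpha,
               tolerance = 1e-3)
  expect_equal(surface_alpha(surf, 15, 1.5), Inf)
  # unseeable grid locations match direct point-in-ellipse enumeration
  g <- build_grid()
  unseeable <- !is.finite(surface_alpha(surf, g$x_deg, g$y_deg))
  in_ellipse <- ((g$x_deg - 15) / 2.5)^2 + ((g$y_deg - 1.5) / 3.5)^2 <= 1
  expect_equal(unseeable, in_ellipse)
  expect_gt(sum(unseeable), 0)
  # deterministic per seed
  surf2 <- make_paper_like_subject(seed = 2)
  expect_equal(surf, surf2)
})

test_that("a motionless eye leaves nominal locations intact", {
  surf <- flat_surface()
  g <- build_grid(11, 12, 0, 1, 0.5)
  em <- eye_movement_model(drift_sd = 0, microsaccade_rate = 0,
                           blink_prob = 0)
  sess <- simulate_session(surf, g, em, seed = 5, frame_noise_px = 0)
  f <- filter_session(sess$trials, sess$gaze)
  expect_equal(f$excluded_fraction, 0)
  expect_equal(f$trials$inferred_x_deg, f$trials$nominal_x_deg)
  expect_equal(f$trials$inferred_y_deg, f$trials$nominal_y_deg)
})

test_that("microsaccades land in about a tenth of frame windows", {
  surf <- flat_surface()
  g <- build_grid(11, 15, -2, 4, 0.5)
  em <- eye_movement_model(drift_sd = 0.05, microsaccade_rate = 0.8,
                           blink_prob = 0)
  sess <- simulate_session(surf, g, em, seed = 55)
  rate <- mean(sess$truth$per_trial$saccade)
  n <- nrow(sess$truth$per_trial)
  ci <- 2.58 * sqrt(0.096 * (1 - 0.096) / n)
  expect_lt(abs(rate - 0.096), ci + 0.005)
})

test_that("identical seeds reproduce sessions byte for byte", {
  surf <- make_paper_like_subject(1)
  g <- build_grid(11, 12.5, 0, 1.5, 0.5)
  s1 <- simulate_session(surf, g, seed = 77)
  s2 <- simulate_session(surf, g, seed = 77)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(s1$trials, f1)
  write_trials(s2$trials, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  g1 <- withr::local_tempfile(fileext = ".csv")
  g2 <- withr::local_tempfile(fileext = ".csv")
  write_gaze(s1$gaze, g1)
  write_gaze(s2$gaze, g2)
  expect_identical(readBin(g1, "raw", file.size(g1)),
                   readBin(g2, "raw", file.size(g2)))
  s3 <- simulate_session(surf, g, seed = 78)
  expect_false(identical(s1$trials$seen, s3$trials$seen))
})

test_that("responses are drawn at the displaced retinal location", {
  # deep scotoma for x > 12.75: with a rightward drift, nominal locations
  # just left of the border produce misses when the eye pushes the
  # stimulus across it
  surf <- sensitivity_surface(
    baseline_alpha = -0.35,
    blind_spot = list(center_x = 20, center_y = 0.5,
                      semi_x = 7.25, semi_y = 50),
    beta = 50
  )
  g <- build_grid(12.5, 12.5, 0.5, 0.5, 0.5)  # single location near border
  em <- eye_movement_model(drift_sd = 0.5, microsaccade_rate = 0,
                           blink_prob = 0)
  sess <- simulate_session(surf, g, em, seed = 91,
                           n_presentations = 40)
  truth <- sess$truth$per_trial
  crossed <- truth$true_x_deg > 12.75
  expect_gt(sum(crossed), 0)
  # stimuli carried into the scotoma are never seen (beyond guesses)
  seen_in_scotoma <- sess$trials$seen[crossed]
  expect_lt(mean(seen_in_scotoma), 0.15)
})
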