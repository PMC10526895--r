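test_that("pixel displacements convert through the device scale", {
  expect_equal(round(pixels_to_degrees(1), 3), 0.027)
  expect_equal(pixels_to_degrees(1), 1.64 / 60)
  expect_equal(pixels_to_degrees(0), 0)
  expect_equal(pixels_to_degrees(10), 16.4 / 60)
  expect_error(pixels_to_degrees(1, pixel_scale = 0), "positive")
})

test_that("trial displacement is the per-axis median of clean frames", {
  px <- function(deg) deg * 60 / 1.64
  res <- trial_displacement(px(c(0.10, 0.20, 0.15)), px(c(0.10, 0.10, 0.12)))
  expect_true(res$valid)
  expect_equal(res$dx_deg, 0.15)
  expect_equal(res$dy_deg, 0.10)
  # identical frames give that frame's displacement exactly
  same <- trial_displacement(rep(px(0.3), 3), rep(px(-0.2), 3))
  expect_equal(c(same$dx_deg, same$dy_deg), c(0.3, -0.2))
})

test_that("exclusion rules fire on blinks, jitter and large shifts", {
  px <- function(deg) deg * 60 / 1.64
  blink <- trial_displacement(c(NA, 1, 2), c(0, 0, 0),
                              missing_reason = c("blink", "none", "none"))
  expect_false(blink$valid)
  expect_equal(blink$reason, "blink")

  oob <- trial_displacement(c(NA, 1, 2), c(0, 0, 0),
                            missing_reason = c("disc_out_of_image", "none",
                                               "none"))
  expect_equal(oob$reason, "out_of_image")

  jitter <- trial_displacement(px(c(0, 0.6, 0.3)), px(c(0, 0, 0)))
  expect_false(jitter$valid)
  expect_equal(jitter$reason, "jitter")
  # range exactly 0.5 is allowed (strict >)
  edge <- trial_displacement(px(c(0, 0.5, 0.25)), px(c(0, 0, 0)))
  expect_true(edge$valid)

  shift <- trial_displacement(px(c(1.1, 1.2, 1.15)), px(c(0, 0, 0)))
  expect_false(shift$valid)
  expect_equal(shift$reason, "shift")
})

test_that("the excluded set is independent of rule order", {
  # a trial is excluded iff it violates any rule; the per-rule predicates
  # are evaluated independently and compared with the filter's verdict
  set.seed(21)
  px <- function(deg) deg * 60 / 1.64
  for (rep in 1:200) {
    dx <- px(rnorm(3, 0, 0.4))
    dy <- px(rnorm(3, 0, 0.4))
    if (runif(1) < 0.15) dx[sample(3, 1)] <- NA
    res <- trial_displacement(dx, dy)
    viol_missing <- anyNA(dx) || anyNA(dy)
    viol_jitter <- !viol_missing &&
      max(diff(range(pixels_to_degrees(dx))),
          diff(range(pixels_to_degrees(dy)))) > 0.5
    viol_shift <- !viol_missing &&
      any(abs(pixels_to_degrees(c(dx, dy))) > 1)
    expect_equal(res$valid, !(viol_missing || viol_jitter || viol_shift))
  }
})

test_that("inferred retinal location shifts by the eye displacement", {
  expect_equal(infer_retinal_location(12, 0, 0, 0),
               list(x_deg = 12, y_deg = 0))
  expect_equal(infer_retinal_location(12, 0, 0.2, -0.1),
               list(x_deg = 12.2, y_deg = -0.1))
  # round trip with the opposite displacement
  fwd <- infer_retinal_location(12, 0, 0.2, -0.1)
  back <- infer_retinal_location(fwd$x_deg, fwd$y_deg, -0.2, 0.1)
  expect_equal(back, list(x_deg = 12, y_deg = 0))
})

test_that("session filtering reports per-reason counts and fraction", {
  px <- function(deg) deg * 60 / 1.64
  clean <- lapply(1:88, function(i) constant_frames(0.05, -0.05))
  blinks <- lapply(1:7, function(i) {
    list(dx_px = c(NA, 0, 0), dy_px = c(0, 0, 0),
         missing_reason = c("blink", "none", "none"))
  })
  jitters <- lapply(1:3, function(i) {
    list(dx_px = px(c(0, 0.7, 0.3)), dy_px = px(c(0, 0, 0)))
  })
  shifts <- lapply(1:2, function(i) constant_frames(1.5, 0))
  fx <- make_gaze_tables(c(clean, blinks, jitters, shifts))
  f <- filter_session(fx$trials, fx$gaze)
  expect_equal(f$excluded_fraction, 0.12)
  counts <- setNames(f$summary$n, f$summary$reason)
  expect_equal(counts[["blink"]], 7L)
  expect_equal(counts[["jitter"]], 3L)
  expect_equal(counts[["shift"]], 2L)
  # valid trials carry inferred locations
  ok <- dplyr::filter(f$trials, valid)
  expect_equal(ok$inferred_x_deg, ok$nominal_x_deg + ok$dx_deg)

  all_valid <- make_gaze_tables(clean)
  expect_equal(filter_session(all_valid$trials, all_valid$gaze)$
                 excluded_fraction, 0)
})

test_that("microsaccade probability over three frames is about 10%", {
  expect_equal(microsaccade_probability(0.8, 0.12), 0.096)
  expect_equal(round(microsaccade_probability(), 1), 0.1)
})

test_that("excluded fraction tracks the generator's corruption rates", {
  # blink-only corruption: excluded fraction within the binomial 99% CI
  surf <- flat_surface()
  g <- build_grid(11, 14, 0, 3, 0.5)
  em <- eye_movement_model(drift_sd = 0.05, microsaccade_rate = 0,
                           blink_prob = 0.1)
  sess <- simulate_session(surf, g, em, seed = 123)
  f <- filter_session(sess$trials, sess$gaze)
  n <- nrow(sess$trials)
  ci <- 2.58 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(f$excluded_fraction - 0.1), ci + 0.01)
  expect_true(all(f$summary$reason == "blink"))
})
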