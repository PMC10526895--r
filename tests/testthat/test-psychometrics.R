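test_that("detection probability passes through the threshold identity", {
  # at contrast == alpha with symmetric guess/lapse rates, Psi = 0.5
  p <- psychometric_params(alpha = -0.2, beta = 3.5, gamma = 0.02,
                           lam = 0.02)
  expect_equal(detection_probability(p, -0.2), 0.5)
  # floor of the curve at very low contrast
  expect_equal(detection_probability(p, -100), 0.02)
  # closed-form evaluation: alpha = 0, beta = 1, no guess/lapse, C = 2
  p0 <- psychometric_params(alpha = 0, beta = 1, gamma = 0, lam = 0)
  expect_equal(detection_probability(p0, log10(2)), 1 - 2^(-2))
})

test_that("detection probability is nondecreasing and bounded", {
  set.seed(11)
  for (rep in 1:30) {
    p <- psychometric_params(alpha = runif(1, -1, 1),
                             beta = runif(1, 0.5, 20),
                             gamma = runif(1, 0, 0.2),
                             lam = runif(1, 0, 0.2))
    cs <- sort(runif(50, -3, 3))
    probs <- detection_probability(p, cs)
    expect_true(all(diff(probs) >= -1e-12))
    expect_true(all(probs >= p$gamma - 1e-12))
    expect_true(all(probs <= 1 - p$lam + 1e-12))
  }
})

test_that("invalid psychometric parameters are rejected", {
  expect_error(psychometric_params(0, beta = -1), "beta")
  expect_error(psychometric_params(0, gamma = 0.6, lam = 0.6), "gamma")
})

test_that("ZEST initialisation normalises any prior", {
  lad <- build_ladder()
  s <- zest_init(lad)
  expect_equal(s$pdf, rep(1 / 74, 74))
  point <- c(rep(0, 40), 1, rep(0, 33))
  s2 <- zest_init(lad, prior = point)
  expect_equal(zest_estimate(s2), as.numeric(lad)[41])
  set.seed(3)
  for (rep in 1:10) {
    s3 <- zest_init(lad, prior = runif(74))
    expect_equal(sum(s3$pdf), 1, tolerance = 1e-9)
  }
  expect_error(zest_init(numeric(0)), "non-empty")
})

test_that("stimulus placement is the snapped posterior mean", {
  s <- zest_init(c(-0.2, 0, 0.2))
  expect_equal(zest_next_stimulus(s), 0)
  s2 <- zest_init(c(-0.2, 0, 0.3), prior = c(0, 0, 1))
  expect_equal(zest_next_stimulus(s2), 0.3)
  # a seen response shifts the next stimulus strictly lower
  lad <- build_ladder()
  s3 <- zest_init(lad)
  first <- zest_next_stimulus(s3)
  s3 <- zest_update(s3, first, seen = TRUE)
  expect_lt(zest_next_stimulus(s3), first)
  # exact ties snap toward the lower level
  s4 <- zest_init(c(-0.1, 0.1))
  expect_equal(zest_next_stimulus(s4), -0.1)
})

test_that("Bayes updates move mass in the expected direction", {
  dom <- c(-0.3, 0, 0.3)
  s <- zest_init(dom)
  up <- zest_update(s, -0.3, seen = TRUE)
  expect_lt(zest_estimate(up), zest_estimate(s))
  down <- zest_update(s, 0.3, seen = FALSE)
  expect_gt(zest_estimate(down), zest_estimate(s))
  # a flat likelihood (gamma = lam = 0.5) leaves the pdf unchanged
  flat <- zest_update(s, 0, seen = TRUE,
                      likelihood = list(alpha = 0, beta = 3.5,
                                        gamma = 0.5, lam = 0.4999999))
  expect_equal(flat$pdf, s$pdf, tolerance = 1e-6)
})

test_that("pdf remains a probability distribution through random updates", {
  set.seed(5)
  lad <- build_ladder()
  s <- zest_init(lad)
  for (k in 1:20) {
    s <- zest_update(s, sample(as.numeric(lad), 1), runif(1) < 0.5)
    expect_true(all(s$pdf >= 0))
    expect_equal(sum(s$pdf), 1, tolerance = 1e-9)
  }
  expect_equal(s$n_presented, 20L)
  expect_equal(nrow(s$history), 20L)
})

test_that("update chain equals the brute-force posterior product", {
  dom <- c(-0.4, -0.2, 0, 0.2, 0.4)
  lik <- psychometric_params(alpha = 0, beta = 3.5)
  contrasts <- c(-0.2, 0.2, 0)
  for (bits in 0:7) {
    seen <- as.logical(bitwAnd(bits, c(1L, 2L, 4L)))
    s <- zest_init(dom)
    for (k in 1:3) s <- zest_update(s, contrasts[k], seen[k], likelihood = lik)
    oracle <- brute_force_posterior(
      dom, rep(1 / 5, 5),
      data.frame(contrast = contrasts, seen = seen), lik
    )
    expect_equal(s$pdf, oracle, tolerance = 1e-12)
  }
})

test_that("estimates follow the pdf mean", {
  expect_equal(zest_estimate(zest_init(c(-0.9, 0.6))), -0.15)
  # 6 deterministic trials against a very steep observer recover the
  # threshold within one ladder step
  lad <- build_ladder()
  obs <- step_observer(0.1)
  s <- zest_init(lad, prior = "uniform")
  for (k in 1:6) {
    cc <- zest_next_stimulus(s)
    s <- zest_update(s, cc, obs(0, 0, cc),
                     likelihood = psychometric_params(0, beta = 50))
  }
  step <- max(diff(as.numeric(lad)))
  expect_lt(abs(zest_estimate(s) - 0.1), step + 1e-9)
})

test_that("a full session presents six stimuli per location", {
  g <- build_grid(11, 17, -3, 6, 0.5)
  sess <- run_zest_session(g, step_observer(-0.2))
  expect_equal(nrow(sess$trials), 247 * 6)
  expect_equal(nrow(sess$estimates), 247)
  expect_true(all(table(sess$trials$loc_id) == 6))
  expect_false(any(sess$trials$is_catch))

  tiny <- run_zest_session(build_grid(0, 1, 0, 1, 0.5), step_observer(0),
                           n_presentations = 1)
  expect_equal(nrow(tiny$trials), 9)
})

test_that("an all-seeing observer drives estimates to the domain floor", {
  g <- build_grid(0, 1, 0, 1, 0.5)
  sess <- run_zest_session(g, function(x, y, c) TRUE)
  lad <- build_ladder()
  # repeated downward updates: estimates end in the lowest quarter
  expect_true(all(sess$estimates$threshold_log <
                    min(lad) + 0.25 * diff(range(lad))))
})

test_that("catch trials are reported separately at configured rates", {
  g <- build_grid(0, 2, 0, 2, 0.5)
  sess <- run_zest_session(g, step_observer(-0.2), catch_fp_rate = 0.5,
                           catch_fn_rate = 0.5, seed = 9)
  catches <- dplyr::filter(sess$trials, is_catch)
  expect_gt(nrow(catches), 0)
  expect_setequal(unique(catches$catch_kind), c("fp", "fn"))
  # threshold trial count unaffected by catch insertion
  expect_equal(sum(!sess$trials$is_catch), nrow(g) * 6)
  # blank probes unseen, max-contrast probes seen for this observer
  expect_false(any(catches$seen[catches$catch_kind == "fp"]))
  expect_true(all(catches$seen[catches$catch_kind == "fn"]))
})

test_that("tidy and glance summarise a session", {
  sess <- run_zest_session(build_grid(0, 1, 0, 1, 0.5), step_observer(0))
  td <- tidy(sess)
  expect_equal(td$sensitivity_log, -td$threshold_log)
  gl <- glance(sess)
  expect_equal(gl$n_locations, 9L)
  expect_equal(gl$n_trials, 54L)
})
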