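test_that("cross-validated R-squared follows its defining arithmetic", {
  # predictions equal to observations: R2 = 1
  expect_equal(loo_r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  # predictions equal to the observed mean: R2 = 0
  expect_equal(loo_r_squared(c(1, 2, 3), rep(2, 3)), 0)
  # worked case: y = (0,1,2), constant-zero predictions
  # SS_res = 0 + 1 + 4 = 5, SS_tot = 1 + 0 + 1 = 2 -> R2 = -1.5
  expect_equal(loo_r_squared(c(0, 1, 2), c(0, 0, 0)), -1.5)
})

test_that("kurtosis statistic and null calibration behave as designed", {
  # two-point symmetric weights attain the minimal kurtosis of 1
  k <- kurtosis_projection_test(c(1, -1, 1, -1) / 2, n_random = 200, seed = 1)
  expect_equal(k$kurtosis, 1)
  # constant weights are rejected
  expect_error(kurtosis_projection_test(rep(0.5, 4)), "undefined-kurtosis")
  expect_error(kurtosis_projection_test(c(1, 0, 0)), "4 units")
  # one-hot vector in dimension 50 is extreme under the spherical null
  w <- c(1, rep(0, 49))
  k2 <- kurtosis_projection_test(w, n_random = 2000, seed = 2)
  expect_lt(k2$p_value, 0.01)
  expect_true(k2$significant)
  # a draw from the null itself is unremarkable
  set.seed(3)
  k3 <- kurtosis_projection_test(rnorm(30), n_random = 2000, seed = 4)
  expect_gt(k3$p_value, 0.001)
})

test_that("trigger crossings interpolate exactly and handle absence", {
  # hand-built rate tensor: one unit, decision value is a linear ramp
  tt <- seq(0, 1, by = 0.01)
  ramp <- tt - 0.437                      # crosses zero at t = 0.437
  model <- structure(list(w = c(u1 = 1), b = 0), class = "trigger_model")
  rates <- structure(list(
    values = array(ramp, dim = c(1, length(tt), 1)),
    time = tt, alignment = "target_on",
    trials = tibble::tibble(trial_id = "t1", condition_id = "C1",
                            is_jump = FALSE, event_time = 0,
                            obs_lo = 0, obs_hi = 1),
    unit_ids = "u1", normalization = 1
  ), class = "rate_tensor")
  session <- list(trials = tibble::tibble(trial_id = "t1",
                                          go_cue_time = 0.2,
                                          jump_time = NA_real_))
  ev <- trigger_crossing_time(model, rates, session)
  expect_equal(ev$crossing_time, 0.437, tolerance = 1e-9)
  # crossing before the go cue is ignored; next crossing after go is used
  session$trials$go_cue_time <- 0.3
  rates2 <- rates
  # upward zero crossings at t = 0.005 (pre-go, ignored) and t = 0.505
  rates2$values[1, , 1] <- sin(4 * pi * (tt - 0.005))
  ev2 <- trigger_crossing_time(model, rates2, session)
  expect_equal(ev2$crossing_time, 0.505, tolerance = 0.005)
  # always-negative decision value: absence, not an error
  rates3 <- rates
  rates3$values[1, , 1] <- -1
  ev3 <- trigger_crossing_time(model, rates3, session)
  expect_true(is.na(ev3$crossing_time))
  # positive rescaling of (w, b) leaves the crossing unchanged
  model2 <- structure(list(w = c(u1 = 7.3), b = 0), class = "trigger_model")
  ev4 <- trigger_crossing_time(model2, rates, session)
  expect_equal(ev4$crossing_time, ev$crossing_time)
})

test_that("decoder enforces the unit-count exclusion rule", {
  tt <- seq(-0.5, 0.2, by = 0.01)
  vals <- array(rnorm(5 * length(tt) * 12), dim = c(5, length(tt), 12))
  rates <- structure(list(
    values = vals, time = tt, alignment = "move_onset",
    trials = tibble::tibble(trial_id = paste0("t", 1:12),
                            condition_id = "C1", is_jump = FALSE,
                            event_time = 1, obs_lo = -1, obs_hi = 1),
    unit_ids = paste0("u", 1:5), normalization = rep(1, 5)
  ), class = "rate_tensor")
  expect_error(train_trigger_svm(rates), "exclusion")
})

test_that("LOO prediction skips conditions without usable transitions", {
  set.seed(21)
  n <- 30
  events <- tibble::tibble(trial_id = paste0("t", 1:n),
                           offset_vs_jump = runif(n, -0.15, 0.15))
  behavior <- tibble::tibble(
    trial_id = paste0("t", 1:n),
    condition_id = rep(c("J1", "J2"), each = n / 2),
    # positive offset = trigger after jump = initiated toward the final
    # target (+1)
    angle_norm = c(ifelse(events$offset_vs_jump[1:(n / 2)] > 0, 1, -1) +
                     rnorm(n / 2, 0, 0.1),
                   rep(0.9, n / 2)))  # J2: no transition
  expect_warning(out <- predict_jump_behavior(events, behavior),
                 "skipping")
  expect_identical(out$condition_id, "J1")
  expect_gt(out$r2_loo, 0.5)
  expect_gt(out$accuracy, 0.9)
})
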