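mk_spike_session <- function(spikes_per_trial, t_end = 2,
                             go = 0.8, onset = 1.2) {
  n_tr <- length(spikes_per_trial)
  tt <- seq(0, t_end, by = 0.01)
  prog <- pmin(pmax((tt - onset) / 0.4, 0), 1)
  prog <- prog^2 * (3 - 2 * prog)
  trials <- tibble::tibble(
    trial_id = paste0("t", seq_len(n_tr)),
    condition_id = "C1",
    is_jump = FALSE,
    target_on_time = 0.3, go_cue_time = go,
    jump_time = NA_real_,
    first_target_x = 10, first_target_y = 0,
    final_target_x = 10, final_target_y = 0,
    move_onset_time = onset,
    kinematics = lapply(seq_len(n_tr), function(j) {
      cbind(time = tt, x = 10 * prog, y = 0 * prog)
    })
  )
  units <- tibble::tibble(unit_id = "u1", region = "M1",
                          spikes = list(spikes_per_trial))
  reach_session(units, trials)
}

test_that("a single spike yields the closed-form Gaussian peak rate", {
  s <- mk_spike_session(list(1.0), t_end = 2)
  r <- smooth_rates(s, align = "target_on", window = c(0.2, 1.6),
                    kernel_sd = 0.030, step = 0.010)
  # at the spike (well inside the window) the rate is the kernel peak
  peak <- r$values[1, which.min(abs(r$time - 0.7)), 1]  # aligned t = 1.0 - 0.3
  expect_equal(peak, 1 / (0.030 * sqrt(2 * pi)), tolerance = 1e-6)
  # no spikes -> all-zero rates
  s0 <- mk_spike_session(list(numeric(0)))
  r0 <- smooth_rates(s0, align = "target_on", window = c(0.2, 1.6))
  expect_true(all(r0$values[1, , 1] == 0, na.rm = TRUE))
})

test_that("smoothing conserves spike mass away from edges", {
  set.seed(7)
  sp <- sort(runif(40, 0.6, 1.4))
  s <- mk_spike_session(list(sp), t_end = 2)
  r <- smooth_rates(s, align = "target_on", window = c(0, 1.6),
                    step = 0.001)
  integral <- sum(r$values[1, , 1]) * 0.001
  expect_equal(integral, 40, tolerance = 40 * 1e-3)
})

test_that("homogeneous Poisson trains recover their rate", {
  set.seed(11)
  means <- replicate(50, {
    n <- rpois(1, 100 * 5)
    s <- mk_spike_session(list(sort(runif(n, 0, 5))), t_end = 5)
    r <- smooth_rates(s, align = "target_on", window = c(0.2, 4.2))
    mean(r$values[1, , 1], na.rm = TRUE)
  })
  expect_equal(mean(means), 100, tolerance = 0.05)
})

test_that("soft normalization floors divisors at 1 and is idempotent", {
  s <- mk_spike_session(list(sort(runif(200, 0, 2)), sort(runif(5, 0, 2))))
  r <- smooth_rates(s, align = "target_on", window = c(0, 1.6))
  rn <- normalize_rates(r)
  flat <- matrix(r$values, nrow = 1)
  sd_raw <- sd(flat[1, ], na.rm = TRUE)
  expect_equal(rn$normalization[1], max(sd_raw, 1))
  expect_equal(rn$values, r$values / rn$normalization[1])
  # explicit divisor arithmetic: s.d. 2 halves the values
  r2 <- r
  r2$values <- r$values / sd_raw * 2       # rescale to s.d. exactly 2
  rn2 <- normalize_rates(r2)
  expect_equal(rn2$values, r2$values / 2, tolerance = 1e-12)
  # unit with s.d. < 1 is left unchanged
  r3 <- r
  r3$values <- r$values / sd_raw * 0.5
  rn3 <- normalize_rates(r3)
  expect_equal(rn3$values, r3$values)
  # all-zero unit: no division error, unchanged
  r4 <- r
  r4$values[] <- 0
  expect_equal(normalize_rates(r4)$values, r4$values)
  # idempotence on a normalized tensor with per-unit s.d. <= 1
  rnn <- normalize_rates(rn)
  expect_equal(rnn$values, rn$values)
})

test_that("movement onset detection is accurate, relative and fails on flat input", {
  s <- mk_spike_session(list(numeric(0)), onset = 1.2)
  t_det <- detect_movement_onset(s$trials[1, ])
  expect_lt(abs(t_det - 1.2), 0.045)
  # scale invariance: doubling the trajectory leaves the onset unchanged
  s2 <- s
  s2$trials$kinematics[[1]][, 2:3] <- 2 * s2$trials$kinematics[[1]][, 2:3]
  expect_equal(detect_movement_onset(s2$trials[1, ]), t_det)
  # stationary hand -> detection error
  s3 <- s
  s3$trials$kinematics[[1]][, 2:3] <- 0
  expect_error(detect_movement_onset(s3$trials[1, ]), "stationary")
})

test_that("onset detection matches the generator within one kinematic sample of its bias", {
  cfg <- generator_config(n_units = 10, n_trials = 60, seed = 8, p_jump = 0)
  gs <- generate_session(cfg)
  s <- suppressWarnings(detect_all_onsets(gs$session))
  err <- s$trials$move_onset_time - gs$truth$trials$true_onset
  # the 5%-of-peak rule lags a smooth speed profile by a small fixed amount
  expect_true(all(abs(err) < 0.06, na.rm = TRUE))
  expect_lt(sd(err, na.rm = TRUE), 0.015)
})

test_that("alignment is shift-equivariant and averaging is linear", {
  set.seed(3)
  sp <- sort(runif(60, 0, 2))
  s <- mk_spike_session(list(sp, sp + 0))
  r <- smooth_rates(s, align = "go_cue", window = c(-0.3, 0.5))
  # shift every event and spike by delta: aligned tensors are unchanged
  delta <- 0.21
  s_shift <- s
  s_shift$trials$target_on_time <- s_shift$trials$target_on_time + delta
  s_shift$trials$go_cue_time <- s_shift$trials$go_cue_time + delta
  s_shift$trials$move_onset_time <- s_shift$trials$move_onset_time + delta
  s_shift$trials$kinematics <- lapply(s_shift$trials$kinematics, function(k) {
    k[, 1] <- k[, 1] + delta
    k
  })
  s_shift$units$spikes[[1]] <- lapply(s_shift$units$spikes[[1]],
                                      function(v) v + delta)
  r_shift <- smooth_rates(s_shift, align = "go_cue", window = c(-0.3, 0.5))
  expect_equal(r_shift$values, r$values, tolerance = 1e-10)
  # identical trials: average equals any single trial
  avg <- align_and_average(r)
  expect_equal(avg$values[, , 1], r$values[, , 1], tolerance = 1e-10)
  expect_equal(avg$groups$n_trials, 2L)
})
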