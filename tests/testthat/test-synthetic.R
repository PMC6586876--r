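test_that("ground-truth bases are exactly orthonormal and deterministic", {
  cfg <- generator_config(n_units = 10, d_prep = 3, d_move = 3, seed = 3)
  tr <- make_ground_truth(cfg)
  B <- cbind(tr$B_prep, tr$B_move, tr$b_trig)
  expect_equal(ncol(B), 7)
  expect_lt(max(abs(crossprod(B) - diag(7))), 1e-10)
  tr2 <- make_ground_truth(cfg)
  expect_identical(tr$B_prep, tr2$B_prep)
  expect_identical(tr$b_trig, tr2$b_trig)
  # capacity error
  expect_error(generator_config(n_units = 6, d_prep = 3, d_move = 3),
               "capacity")
})

test_that("trial simulation enforces the trigger-vs-jump behavioural rule", {
  cfg <- generator_config(n_units = 10, seed = 5)
  tr <- make_ground_truth(cfg)
  set.seed(1)
  # non-jump: no jump time, label is the cued target
  lt <- simulate_trial(tr, cfg, 2, 2, FALSE)
  expect_true(is.na(lt$events[["jump"]]))
  expect_identical(lt$label, "first")
  # rule holds with zero exceptions across many jump trials
  set.seed(2)
  for (i in 1:200) {
    lt <- simulate_trial(tr, cfg, 1, 5, TRUE)
    expect_identical(lt$label,
                     if (lt$events[["trigger"]] < lt$events[["jump"]])
                       "first" else "final")
  }
})

test_that("behavioural transition sits at the closed-form 50% point", {
  cfg <- generator_config(n_units = 10, seed = 9)
  tr <- make_ground_truth(cfg)
  set.seed(3)
  lat <- numeric(1000)
  toward_final <- logical(1000)
  for (i in seq_len(1000)) {
    lt <- simulate_trial(tr, cfg, 1, 5, TRUE)
    lat[i] <- (lt$events[["onset"]] - lt$events[["jump"]]) * 1000
    toward_final[i] <- lt$label == "final"
  }
  # fraction toward final rises with latency; 50% point ~ trigger_lead
  bins <- cut(lat, breaks = seq(0, 400, by = 40))
  frac <- tapply(toward_final, bins, mean)
  frac <- frac[!is.na(frac)]
  expect_lt(frac[1], 0.1)
  expect_gt(frac[length(frac)], 0.9)
  fit <- suppressWarnings(stats::glm(toward_final ~ lat,
                                     family = stats::binomial()))
  t50 <- -coef(fit)[1] / coef(fit)[2]
  expect_lt(abs(t50 - cfg$trigger_lead * 1000), 20)
})

test_that("spike emission matches Poisson moments and is reproducible", {
  cfg <- generator_config(n_units = 6, d_prep = 2, d_move = 2, seed = 7)
  tr <- make_ground_truth(cfg)
  tr$noise_sd <- 0
  # zero latents: counts are Poisson with mean softplus(baseline) * T
  tt <- seq(0, 2, by = cfg$dt)
  lat0 <- list(time = tt, Z = matrix(0, 5, length(tt)))
  set.seed(11)
  counts <- replicate(1000, lengths(emit_spikes(lat0, tr, cfg)))
  mu <- rowMeans(counts)
  v <- apply(counts, 1, var)
  expected <- log1p(exp(tr$baseline)) * 2
  expect_equal(mu, expected, tolerance = 0.05 * max(expected))
  # Poisson: variance ~ mean
  expect_true(all(abs(v / mu - 1) < 0.25))
  # determinism given the RNG state
  set.seed(42)
  a <- emit_spikes(lat0, tr, cfg)
  set.seed(42)
  b <- emit_spikes(lat0, tr, cfg)
  expect_identical(a, b)
})

test_that("snr scales cross-condition rate variance monotonically", {
  # higher snr -> condition structure stands out more in smoothed rates,
  # averaged over seeds to beat sampling fluctuations
  spread_at <- function(snr_val, seed) {
    cfg <- generator_config(n_units = 15, n_trials = 48, seed = seed,
                            p_jump = 0, snr = snr_val,
                            delay_range = c(0.4, 0.6))
    gs <- generate_session(cfg)
    r <- smooth_rates(gs$session, align = "target_on", window = c(0.1, 0.35))
    avg <- suppressWarnings(align_and_average(r))
    m <- apply(avg$values, c(1, 3), mean)
    mean(apply(m, 1, var)) / mean(apply(r$values, 1, var, na.rm = TRUE))
  }
  # doublings probed where the baseline-noise term is the dominant noise
  # source; at higher snr Poisson spiking noise takes over and the ratio
  # saturates
  spread <- vapply(c(0.2, 0.4, 0.8), function(s) {
    mean(vapply(13:17, function(sd_) spread_at(s, sd_), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("kinematics start at the origin, end on target and correct online", {
  cfg <- generator_config(n_units = 10, seed = 17)
  tr <- make_ground_truth(cfg)
  set.seed(5)
  ends <- matrix(NA, 200, 2)
  for (i in 1:200) {
    lt <- simulate_trial(tr, cfg, 1, 5, i %% 2 == 0)
    f_xy <- c(10, 0)
    l_xy <- if (i %% 2 == 0) c(-10, 0) else c(10, 0)
    k <- simulate_kinematics(lt$events, lt$label, f_xy, l_xy, cfg)
    expect_lt(sqrt(sum(k[1, 2:3]^2)), 0.1)
    ends[i, ] <- k[nrow(k), 2:3]
    if (i %% 2 == 0 && lt$label == "first") {
      # corrected 180-degree reach: x goes wrong-way positive first
      expect_gt(max(k[, 2]), 0.5)
      expect_lt(ends[i, 1], -9.5)
    }
    tgt <- if (i %% 2 == 0) l_xy else f_xy
    expect_lt(sqrt(sum((ends[i, ] - tgt)^2)), 0.5)
  }
})

test_that("generated sessions are deterministic with the configured mix", {
  cfg <- generator_config(n_units = 8, n_trials = 500, seed = 19)
  gs1 <- generate_session(cfg)
  gs2 <- generate_session(cfg)
  expect_identical(gs1$session$units$spikes, gs2$session$units$spikes)
  expect_equal(gs1$session$trials$go_cue_time, gs2$session$trials$go_cue_time)
  # binomial tolerance on the jump fraction
  expect_lt(abs(mean(gs1$session$trials$is_jump) - 0.2), 0.04)
  # p_jump = 0 -> no jump trials
  gs0 <- generate_session(generator_config(n_units = 8, n_trials = 30,
                                           p_jump = 0, seed = 19))
  expect_false(any(gs0$session$trials$is_jump))
  # label/rule consistency bookkeeping exported in the truth
  tt <- gs1$truth$trials
  jj <- tt[tt$is_jump, ]
  expect_identical(jj$true_label,
                   ifelse(jj$true_trigger < jj$jump_time, "first", "final"))
})

test_that("high-snr prep projections reproduce the prep latents", {
  cfg <- generator_config(n_units = 30, n_trials = 160, seed = 23,
                          p_jump = 0, snr = 1e6,
                          delay_range = c(0.5, 0.9))
  gs <- generate_session(cfg)
  r <- normalize_rates(smooth_rates(gs$session, align = "target_on",
                                    window = c(0, 0.5)))
  avg <- suppressWarnings(align_and_average(r))
  tn <- truth_in_normalized_space(gs$truth, r$normalization)
  # projected condition averages should reproduce the prep latents up to a
  # linear re-basis (the subspace is identified, not the basis): pooled
  # least-squares alignment of predicted latents to projections
  Qp <- qr.Q(qr(tn$B_prep))
  tt_g <- seq(0, 0.5, by = 0.01)
  xx <- pmin(pmax((tt_g - 0.06) / 0.08, 0), 1)
  engage <- xx^2 * (3 - 2 * xx)
  n_g <- dim(avg$values)[3]
  proj <- pred <- NULL
  for (g in seq_len(n_g)) {
    k <- as.integer(sub("T", "", avg$groups$condition_id[g]))
    p <- crossprod(Qp, avg$values[, , g])
    proj <- cbind(proj, p - p[, 1])
    pred <- cbind(pred, outer(gs$truth$prep_patterns[, k], engage))
  }
  fit <- lm.fit(x = t(pred), y = t(proj))
  r2 <- 1 - sum(fit$residuals^2) / sum(scale(t(proj), scale = FALSE)^2)
  expect_gt(r2, 0.95)
})
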