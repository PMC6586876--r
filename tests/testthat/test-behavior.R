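test_that("initial reach angle interpolates the 1 cm crossing", {
  straight <- function(tgt) {
    tt <- seq(0, 1, by = 0.01)
    cbind(time = tt, x = tgt[1] * tt, y = tgt[2] * tt)
  }
  expect_equal(initial_reach_angle(straight(c(10, 0))), 0, tolerance = 1e-9)
  expect_equal(initial_reach_angle(straight(c(0, 10))), 90, tolerance = 1e-9)
  expect_equal(initial_reach_angle(straight(c(-10, 0))), 180, tolerance = 1e-6)
  # trajectory that never reaches 1 cm
  short <- cbind(time = 0:10 / 10, x = rep(0.05, 11), y = rep(0, 11))
  expect_error(initial_reach_angle(short), "never reaches")
})

test_that("angle normalization maps the arc linearly and rotates freely", {
  # first at 0, final at 90: -1, +1, midpoint 0
  expect_equal(normalize_angle(0, 0, 90), -1)
  expect_equal(normalize_angle(90, 0, 90), 1)
  expect_equal(normalize_angle(45, 0, 90), 0)
  # overshoot exceeds +/-1
  expect_gt(normalize_angle(100, 0, 90), 1)
  expect_lt(normalize_angle(-10, 0, 90), -1)
  # 180-degree condition: cross-check against an independent projection
  # formula on a few angles (sin of the angle from first, scaled)
  for (a in c(10, 45, 90, 170, 185)) {
    direct <- 2 * a / 180 - 1
    expect_equal(normalize_angle(a, 0, 180), direct, tolerance = 1e-9)
  }
  # global rotation invariance
  set.seed(5)
  for (rot in runif(5, -180, 180)) {
    expect_equal(normalize_angle(30 + rot, 10 + rot, 130 + rot),
                 normalize_angle(30, 10, 130), tolerance = 1e-9)
  }
  # coincident directions are undefined
  expect_error(normalize_angle(10, 45, 45), "undefined-condition")
})

test_that("sigmoid fitting recovers noiseless logistic parameters", {
  lat <- seq(0, 220, by = 4)
  y <- -1 + 2 * plogis((lat - 100) / 18)
  f <- fit_behavior_sigmoid(lat, y, n_boot = 0)
  expect_equal(f$t50, 100, tolerance = 1)
  expect_equal(unname(f$crossings["f0.5"]), f$t50)
  expect_equal(f$lower, -1, tolerance = 0.02)
  expect_equal(f$upper, 1, tolerance = 0.02)
  expect_gt(f$goodness, 0.999)
  # crossings are monotone in the fraction
  expect_true(all(diff(f$crossings) > 0))
  # prediction at t50 is the asymptote midpoint
  expect_equal(predict(f, f$t50), (f$lower + f$upper) / 2, tolerance = 1e-9)
})

test_that("sigmoid fitting rejects degenerate inputs", {
  lat <- seq(0, 200, by = 10)
  expect_error(fit_behavior_sigmoid(lat[1:5], rep(c(-1, 1), 3)[1:5],
                                    n_boot = 0), "trials")
  expect_error(fit_behavior_sigmoid(lat, rep(0.95, length(lat)), n_boot = 0),
               "transition")
})

test_that("CI filter retains strictly below threshold", {
  fits <- tibble::tibble(condition_id = c("a", "b", "c", "d"),
                         ci50 = c(49, 50, 51, Inf))
  out <- suppressWarnings(filter_fits_by_ci(fits, max_ci = 50))
  expect_identical(out$condition_id, "a")
  expect_setequal(attr(out, "excluded"), c("b", "c", "d"))
})

test_that("crossing-time ANOVA handles degenerate and separated groups", {
  # identical values everywhere: F = 0, p = 1
  fits <- tibble::tibble(jump_angle = rep(c(45, 90), each = 3),
                         t50 = rep(5, 6), slope = rep(1, 6))
  a <- anova_crossing_times(fits, "t50")
  expect_equal(a$statistic, 0)
  expect_equal(a$p_value, 1)
  # zero within-group variance, distinct means: p -> 0
  fits2 <- tibble::tibble(jump_angle = rep(c(45, 90), each = 2),
                          t50 = c(0, 0, 1, 1), slope = 1)
  a2 <- anova_crossing_times(fits2, "t50")
  expect_lt(a2$p_value, 1e-10)
  # group with < 2 members errors
  fits3 <- tibble::tibble(jump_angle = c(45, 45, 90), t50 = 1:3, slope = 1)
  expect_error(anova_crossing_times(fits3), "degrees-of-freedom")
})

test_that("ANOVA p-values are calibrated under an angle-independent null", {
  set.seed(77)
  ps <- replicate(400, {
    fits <- tibble::tibble(jump_angle = rep(c(45, 90, 135, 180), each = 5),
                           t50 = rnorm(20, 150, 15), slope = 1)
    anova_crossing_times(fits, "t50")$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("reach probability curve is a calibrated binomial summary", {
  # all-final labels give a curve identically 1
  out <- reach_probability_curve(runif(50, 0, 100), rep("final", 50),
                                 bin_width = 25)
  expect_true(all(out$p_final == 1))
  # shuffled labels give a flat curve at the overall mean
  set.seed(9)
  lat <- runif(2000, 0, 300)
  lab <- sample(rep(c("first", "final"), 1000))
  out2 <- reach_probability_curve(lat, lab, bin_width = 50)
  expect_true(all(abs(out2$p_final - 0.5) < 0.12))
  expect_true(all(out2$ci_lo <= out2$p_final & out2$p_final <= out2$ci_hi))
  # generator rule: monotone non-decreasing transition at scale
  set.seed(10)
  lat3 <- runif(1000, 0, 300)
  lab3 <- ifelse(lat3 > 150 + rnorm(1000, 0, 20), "final", "first")
  out3 <- reach_probability_curve(lat3, lab3, bin_width = 30)
  expect_true(all(diff(out3$p_final) > -0.08))
  expect_lt(out3$p_final[1], 0.1)
  expect_gt(out3$p_final[nrow(out3)], 0.9)
})
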