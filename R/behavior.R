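#' Initial reach angle of a trial
#'
#' The hand heading at 1 cm from the start position: the angle (degrees,
#' `atan2` convention) of the first trajectory point at radius >= 1 cm,
#' linearly interpolated between the straddling samples.
#'
#' @param trial One-row tibble from a session's `trials` table, or a
#'   kinematics matrix.
#' @param radius Crossing radius (cm), default 1.
#' @return Angle in degrees in (-180, 180].
#' @export
initial_reach_angle <- function(trial, radius = 1) {
  k <- if (is.matrix(trial)) trial else trial$kinematics[[1]]
  if (is.null(k)) abort("behavior error: no trajectory")
  r <- sqrt(k[, 2]^2 + k[, 3]^2)
  i <- which(r >= radius)[1]
  if (is.na(i)) abort("behavior error: trajectory never reaches the radius")
  if (i == 1) {
    p <- k[1, 2:3]
  } else {
    f <- (radius - r[i - 1]) / (r[i] - r[i - 1])
    p <- k[i - 1, 2:3] + f * (k[i, 2:3] - k[i - 1, 2:3])
  }
  unname(atan2(p[2], p[1]) * 180 / pi)
}

wrap_deg <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' Normalize a reach angle onto the first-to-final target axis
#'
#' Maps reach angles linearly along the shorter arc from the first target's
#' direction (-1) to the final target's direction (+1); the arc midpoint
#' maps to 0 and overshoots beyond either target exceed +/-1. Invariant to
#' a global rotation of targets and trajectory.
#'
#' @param angle Reach angle(s), degrees.
#' @param first_dir,final_dir Directions of the first and final targets,
#'   degrees (e.g. `atan2(y, x)` of the target coordinates).
#' @return Normalized angle(s); -1 = first target, +1 = final target.
#' @export
normalize_angle <- function(angle, first_dir, final_dir) {
  delta <- wrap_deg(final_dir - first_dir)
  if (any(abs(delta) < 1e-9)) {
    abort("undefined-condition error: first and final directions coincide")
  }
  # wrap centered on the arc midpoint so overshoots past either target stay
  # continuous (no jump at the +/-180 boundary)
  u <- wrap_deg(angle - first_dir - delta / 2) + delta / 2
  2 * u / delta - 1
}

# bounded least squares for (lower, upper) given the logistic profile g;
# closed-form 2x2 normal equations with active-set enumeration of the box
asymptote_ls <- function(g, y, bounds_lower = c(-1.5, 0),
                         bounds_upper = c(0, 1.5)) {
  h <- 1 - g
  s11 <- sum(h * h)
  s22 <- sum(g * g)
  s12 <- sum(g * h)
  b1 <- sum(h * y)
  b2 <- sum(g * y)
  sy2 <- sum(y * y)
  det <- s11 * s22 - s12 * s12
  clamp <- function(v, b) min(max(v, b[1]), b[2])
  up_given_lo <- function(lo) {
    if (s22 < 1e-12) return(bounds_upper[1])
    clamp((b2 - lo * s12) / s22, bounds_upper)
  }
  lo_given_up <- function(up) {
    if (s11 < 1e-12) return(bounds_lower[2])
    clamp((b1 - up * s12) / s11, bounds_lower)
  }
  cand_lo <- numeric(0)
  cand_up <- numeric(0)
  if (det > 1e-12) {
    lo_u <- (b1 * s22 - b2 * s12) / det
    up_u <- (s11 * b2 - s12 * b1) / det
    if (lo_u >= bounds_lower[1] && lo_u <= bounds_lower[2] &&
        up_u >= bounds_upper[1] && up_u <= bounds_upper[2]) {
      cand_lo <- lo_u
      cand_up <- up_u
    }
  }
  for (lo in bounds_lower) {
    cand_lo <- c(cand_lo, lo)
    cand_up <- c(cand_up, up_given_lo(lo))
  }
  for (up in bounds_upper) {
    cand_lo <- c(cand_lo, lo_given_up(up))
    cand_up <- c(cand_up, up)
  }
  rss <- sy2 - 2 * cand_lo * b1 - 2 * cand_up * b2 +
    cand_lo^2 * s11 + cand_up^2 * s22 + 2 * cand_lo * cand_up * s12
  k <- which.min(rss)
  list(lower = cand_lo[k], upper = cand_up[k], rss = max(rss[k], 0))
}

sigmoid_rss <- function(par, lat, y) {
  t50 <- par[1]
  s <- exp(par[2])
  g <- stats::plogis((lat - t50) / s)
  asymptote_ls(g, y)$rss
}

fit_sigmoid_core <- function(lat, y, t50_starts = NULL, s_start = 20) {
  if (is.null(t50_starts)) {
    t50_starts <- unname(quantile(lat, c(0.1, 0.3, 0.5, 0.7, 0.9)))
  }
  best <- NULL
  for (t0 in t50_starts) {
    o <- stats::optim(c(t0, log(s_start)), sigmoid_rss, lat = lat, y = y,
                      method = "Nelder-Mead",
                      control = list(maxit = 250, reltol = 1e-9))
    if (is.null(best) || o$value < best$value) best <- o
  }
  t50 <- best$par[1]
  s <- exp(best$par[2])
  g <- stats::plogis((lat - t50) / s)
  asy <- asymptote_ls(g, y)
  list(t50 = t50, scale_ms = s, lower = asy$lower, upper = asy$upper,
       rss = asy$rss)
}

#' Fit a psychometric sigmoid of initial reach angle against latency
#'
#' Least-squares 4-parameter logistic
#' `y = lower + (upper - lower) / (1 + exp(-(t - t50)/s))` of normalized
#' initial reach angle against the jump-to-movement-onset latency (ms),
#' with asymptotes bounded in `[-1.5, 0]` and `[0, 1.5]` (angles may
#' overshoot +/-1). Fitting profiles the asymptotes out by linear least
#' squares and runs a deterministic multi-start Nelder-Mead over
#' `(t50, log s)`, since sparse transitions make the problem multimodal.
#' Crossing times at fractions f solve `fit = lower + f (upper - lower)`,
#' i.e. `t50 + s logit(f)`. The 95% CI on `t50` comes from a seeded
#' 1,000-resample trial bootstrap (percentile interval, reported as the
#' half-width `ci50`).
#'
#' @param latency_ms Jump-to-onset latency per trial (ms).
#' @param angle Normalized initial reach angle per trial.
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param seed Seed for the bootstrap.
#' @param min_trials Minimum trial count (default 8).
#' @param crossing_fractions Fractions at which crossing times are reported.
#' @param t50_starts,s_start Optional custom multi-start values for `t50`
#'   (ms) and the initial scale (ms), e.g. to warm-start repeated refits.
#' @return An object of class `sigmoid_fit` with fields `lower`, `upper`,
#'   `t50`, `scale_ms`, `slope` (max derivative, per ms), `crossings`,
#'   `ci50`, `n_trials`, `goodness` (in-sample variance explained).
#' @export
fit_behavior_sigmoid <- function(latency_ms, angle, n_boot = 1000,
                                 seed = 1L, min_trials = 8,
                                 crossing_fractions = c(0.05, 0.5, 0.95),
                                 t50_starts = NULL, s_start = 20) {
  ok <- is.finite(latency_ms) & is.finite(angle)
  lat <- latency_ms[ok]
  y <- angle[ok]
  n <- length(y)
  if (n < min_trials) {
    abort(paste0("fit error: ", n, " trials < required ", min_trials))
  }
  if (!any(y < 0) || !any(y > 0)) {
    abort("fit error: no behavioural transition (angles on one side)")
  }
  fit <- fit_sigmoid_core(lat, y, t50_starts = t50_starts,
                          s_start = s_start)
  if (!is.finite(fit$rss)) abort("fit error: non-convergence")
  crossings <- fit$t50 + fit$scale_ms * stats::qlogis(crossing_fractions)
  names(crossings) <- paste0("f", crossing_fractions)
  tss <- sum((y - mean(y))^2)
  boot_t50 <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    local_seed(derive_seed(seed, "sigmoid_boot"), {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- y[idx]
        if (!any(yb < 0) || !any(yb > 0)) next
        fb <- fit_sigmoid_core(lat[idx], yb,
                               t50_starts = c(fit$t50,
                                              mean(range(lat[idx]))),
                               s_start = fit$scale_ms)
        boot_t50[b] <- fb$t50
      }
    })
  }
  n_ok <- sum(is.finite(boot_t50))
  ci50 <- if (n_ok >= max(50, 0.5 * n_boot)) {
    q <- quantile(boot_t50, c(0.025, 0.975), na.rm = TRUE)
    unname(q[2] - q[1]) / 2
  } else {
    Inf
  }
  structure(list(
    lower = fit$lower, upper = fit$upper, t50 = fit$t50,
    scale_ms = fit$scale_ms,
    slope = (fit$upper - fit$lower) / (4 * fit$scale_ms),
    crossings = crossings, ci50 = ci50, n_trials = n,
    goodness = if (tss > 0) 1 - fit$rss / tss else NA_real_,
    boot_t50 = boot_t50,
    data = tibble::tibble(latency_ms = lat, angle = y)
  ), class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> n=%d  t50=%.1f ms (ci50 %.1f)  asymptotes [%.2f, %.2f]\n",
    x$n_trials, x$t50, x$ci50, x$lower, x$upper))
  invisible(x)
}

#' Predict normalized angle from a fitted sigmoid
#'
#' @param object A `sigmoid_fit`.
#' @param latency_ms Latencies (ms) at which to evaluate the fit.
#' @param ... Unused.
#' @return Predicted normalized angles.
#' @export
predict.sigmoid_fit <- function(object, latency_ms, ...) {
  g <- stats::plogis((latency_ms - object$t50) / object$scale_ms)
  object$lower + (object$upper - object$lower) * g
}

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lower", "upper", "t50", "scale_ms", "slope"),
    estimate = c(x$lower, x$upper, x$t50, x$scale_ms, x$slope)
  )
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(t50 = x$t50, ci50 = x$ci50, slope = x$slope,
                 lower = x$lower, upper = x$upper,
                 crossing_05 = unname(x$crossings[1]),
                 crossing_50 = unname(x$crossings[2]),
                 crossing_95 = unname(x$crossings[3]),
                 goodness = x$goodness, n_trials = x$n_trials)
}

#' Filter sigmoid fits by crossing-time confidence interval
#'
#' Retains conditions whose 95% CI half-width on the 50% crossing time is
#' strictly below `max_ci` ms; poorly constrained fits (typically
#' conditions with few reaches initiated toward one of the targets) are
#' excluded and listed in a warning.
#'
#' @param fits Tibble with at least `condition_id` and `ci50`.
#' @param max_ci CI half-width threshold in ms (default 50; strict `<`).
#' @return The retained rows; excluded condition ids in attribute
#'   `"excluded"`.
#' @export
filter_fits_by_ci <- function(fits, max_ci = 50) {
  keep <- is.finite(fits$ci50) & fits$ci50 < max_ci
  if (any(!keep)) {
    warn(paste0("excluding ", sum(!keep), " condition(s) with ci50 >= ",
                max_ci, " ms: ",
                paste(fits$condition_id[!keep], collapse = ", ")))
  }
  out <- fits[keep, ]
  attr(out, "excluded") <- fits$condition_id[!keep]
  out
}

#' One-way ANOVA of sigmoid parameters across jump angles
#'
#' Tests whether the behavioural transition differs across jump angles by a
#' one-way ANOVA on per-condition 50% crossing times (`value = "t50"`) or
#' on the fitted slopes (`value = "slope"`).
#'
#' @param fits Tibble with per-condition `t50`, `slope` and a grouping
#'   column `jump_angle`.
#' @param value Which parameter to test.
#' @return Tibble with `statistic` (F), `p_value`, `df_between`,
#'   `df_within`, and per-group counts in `group_n` (list column).
#' @export
anova_crossing_times <- function(fits, value = c("t50", "slope")) {
  value <- match.arg(value)
  g <- factor(fits$jump_angle)
  if (nlevels(g) < 2) abort("degrees-of-freedom error: need >= 2 groups")
  if (any(table(g) < 2)) {
    abort("degrees-of-freedom error: every group needs >= 2 conditions")
  }
  y <- fits[[value]]
  if (var(y) < 1e-20) {
    # constant outcome: no effect, by convention F = 0, p = 1
    return(tibble::tibble(statistic = 0, p_value = 1,
                          df_between = nlevels(g) - 1L,
                          df_within = length(y) - nlevels(g),
                          value = value, group_n = list(table(g))))
  }
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  f_stat <- s$`F value`[1]
  p <- s$`Pr(>F)`[1]
  if (!is.finite(f_stat)) {
    # zero within-group variance and zero between-group variance
    f_stat <- 0
    p <- 1
  }
  tibble::tibble(statistic = f_stat, p_value = p,
                 df_between = s$Df[1], df_within = s$Df[2],
                 value = value,
                 group_n = list(table(g)))
}

#' Empirical probability of reaching to the final target
#'
#' Model-free counterpart of the sigmoid fits: bins jump-to-onset latency
#' and reports the fraction of trials initiated toward the final target
#' with exact (Clopper-Pearson) binomial confidence intervals. Empty bins
#' are omitted.
#'
#' @param latency_ms Jump-to-onset latency (ms).
#' @param labels Initial-direction labels, `"first"` or `"final"`.
#' @param bin_width Bin width (ms).
#' @param conf_level Confidence level for the binomial CI.
#' @return Tibble with `latency_mid`, `n`, `p_final`, `ci_lo`, `ci_hi`.
#' @export
reach_probability_curve <- function(latency_ms, labels, bin_width = 20,
                                    conf_level = 0.95) {
  stopifnot(length(latency_ms) == length(labels))
  ok <- is.finite(latency_ms) & labels %in% c("first", "final")
  lat <- latency_ms[ok]
  lab <- labels[ok]
  if (!length(lat)) abort("no usable trials")
  lo <- floor(min(lat) / bin_width) * bin_width
  bins <- floor((lat - lo) / bin_width)
  out <- lapply(sort(unique(bins)), function(b) {
    idx <- bins == b
    n <- sum(idx)
    k <- sum(lab[idx] == "final")
    ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
    tibble::tibble(latency_mid = lo + (b + 0.5) * bin_width, n = n,
                   p_final = k / n, ci_lo = ci[1], ci_hi = ci[2])
  })
  dplyr::bind_rows(out)
}

#' Behavioural summary of the jump trials of a session
#'
#' Convenience wrapper: detects onsets where missing, computes initial and
#' normalized reach angles, jump-to-onset latencies and initial-direction
#' labels (`"first"` when the normalized angle is negative) for every valid
#' jump trial.
#'
#' @param session A `reach_session` (onsets detected or detectable).
#' @return Tibble with one row per valid jump trial: `trial_id`,
#'   `condition_id`, `latency_ms`, `angle_deg`, `angle_norm`, `label`,
#'   `jump_angle` (degrees between first and final target directions).
#' @export
jump_behavior <- function(session) {
  tr <- session$trials
  if (all(is.na(tr$move_onset_time))) {
    session <- detect_all_onsets(session)
    tr <- session$trials
  }
  jt <- tr[tr$is_jump & tr$valid & !is.na(tr$move_onset_time), ]
  if (nrow(jt) == 0) abort("no valid jump trials")
  out <- vector("list", nrow(jt))
  for (j in seq_len(nrow(jt))) {
    trial <- jt[j, ]
    ang <- tryCatch(initial_reach_angle(trial), error = function(e) NA_real_)
    fd <- atan2(trial$first_target_y, trial$first_target_x) * 180 / pi
    ld <- atan2(trial$final_target_y, trial$final_target_x) * 180 / pi
    an <- if (is.na(ang)) NA_real_ else normalize_angle(ang, fd, ld)
    out[[j]] <- tibble::tibble(
      trial_id = trial$trial_id,
      condition_id = trial$condition_id,
      latency_ms = (trial$move_onset_time - trial$jump_time) * 1000,
      angle_deg = ang,
      angle_norm = an,
      label = if (is.na(an)) NA_character_ else
        if (an < 0) "first" else "final",
      jump_angle = abs(wrap_deg(ld - fd))
    )
  }
  dplyr::bind_rows(out)
}
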