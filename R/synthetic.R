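#' Configuration for the synthetic session generator
#'
#' The generator emulates a delayed-reach task with occasional last-moment
#' target jumps: eight 10 cm reach targets on a ring, a variable delay
#' period, a go cue, and on a minority of trials a target jump between the
#' go cue and movement onset. Population spiking is driven by latent
#' preparatory, movement and trigger dimensions that are exactly orthogonal
#' in the generative weights, with inhomogeneous-Poisson emission through a
#' softplus rate link.
#'
#' Latent behavioural rule: the trigger latent crosses its threshold
#' `trigger_lead` seconds before movement onset (plus Gaussian jitter of
#' s.d. `trigger_jitter`), and a jump trial is initiated toward the first
#' target exactly when the true trigger crossing precedes the jump. The
#' probability of initiating toward the final target is therefore
#' `pnorm((latency - trigger_lead)/trigger_jitter)` at jump-to-onset
#' latency `latency`, so the closed-form 50% crossing point is
#' `trigger_lead`.
#'
#' @param n_units Number of simulated units.
#' @param n_conditions Number of non-jump reach targets, equally spaced on a
#'   ring.
#' @param jump_pairs Tibble with integer columns `first` and `final` (target
#'   indices). Defaults to eight ordered pairs spanning jump angles 45, 90,
#'   135 and 180 degrees.
#' @param p_jump Probability that a trial is a jump trial.
#' @param n_trials Number of trials in a session.
#' @param d_prep,d_move Latent preparatory / movement dimensionality.
#' @param trigger_lead Mean lead of the trigger crossing before movement
#'   onset (s).
#' @param trigger_jitter S.d. of the trigger-crossing jitter (s); sets the
#'   width of the behavioural transition.
#' @param trigger_amplitude Amplitude of the trigger latent relative to the
#'   direction-tuned patterns; with the same-signed loadings this makes
#'   the condition-invariant initiation signal the largest single
#'   component of population activity around movement onset.
#' @param delay_range Length-2 numeric, uniform delay period range (s).
#' @param rt_mean,rt_sd Reaction-time distribution on non-jump trials (s).
#' @param snr Ratio of latent-driven pre-softplus rate s.d. to the baseline
#'   noise s.d.
#' @param jump_max_lead Maximum lead of the jump before movement onset (s).
#'   Jump times are uniform between the go cue and movement onset, but no
#'   earlier than `onset - jump_max_lead`; finite values emulate sessions
#'   whose jump window was placed late so that most jump reaches are
#'   initiated toward the first target. Default `Inf` (whole go-to-onset
#'   interval).
#' @param correction_latency Latency from target jump to the neural
#'   correction (s).
#' @param motor_delay Additional latency from neural correction to the
#'   kinematic correction (s).
#' @param kin_angle_noise_deg S.d. (degrees) of the heading noise applied to
#'   each reach, the behavioural observation noise.
#' @param reach_distance Target eccentricity (cm).
#' @param mode `"always_prepare"` (preparatory latents re-engage after every
#'   jump; the structure the analysis is designed to detect) or
#'   `"direct_response"` (late jumps are corrected in movement latents only).
#' @param seed Master seed; all randomness derives from it via named streams.
#' @param dt Latent/rate resolution (s). @param kin_dt Hand sampling step (s).
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_units = 60,
                             n_conditions = 8,
                             jump_pairs = NULL,
                             p_jump = 0.2,
                             n_trials = 400,
                             d_prep = 3,
                             d_move = 3,
                             trigger_lead = 0.150,
                             trigger_jitter = 0.020,
                             trigger_amplitude = 1.25,
                             delay_range = c(0, 0.9),
                             rt_mean = 0.300,
                             rt_sd = 0.050,
                             snr = 2,
                             jump_max_lead = Inf,
                             correction_latency = 0.100,
                             motor_delay = 0.050,
                             kin_angle_noise_deg = 6,
                             reach_distance = 10,
                             mode = c("always_prepare", "direct_response"),
                             seed = 1L,
                             dt = 0.001,
                             kin_dt = 0.010) {
  mode <- match.arg(mode)
  if (is.null(jump_pairs)) {
    jump_pairs <- tibble::tibble(
      first = c(1L, 5L, 3L, 7L, 2L, 6L, 1L, 5L),
      final = c(5L, 1L, 6L, 2L, 4L, 8L, 2L, 6L)
    )
    jump_pairs <- jump_pairs[jump_pairs$first <= n_conditions &
                               jump_pairs$final <= n_conditions, ]
  }
  cfg <- list(n_units = n_units, n_conditions = n_conditions,
              jump_pairs = tibble::as_tibble(jump_pairs), p_jump = p_jump,
              n_trials = n_trials, d_prep = d_prep, d_move = d_move,
              trigger_lead = trigger_lead, trigger_jitter = trigger_jitter,
              trigger_amplitude = trigger_amplitude,
              delay_range = delay_range, rt_mean = rt_mean, rt_sd = rt_sd,
              snr = snr, jump_max_lead = jump_max_lead,
              correction_latency = correction_latency,
              motor_delay = motor_delay,
              kin_angle_noise_deg = kin_angle_noise_deg,
              reach_distance = reach_distance, mode = mode,
              seed = as.integer(seed), dt = dt, kin_dt = kin_dt)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$d_prep + cfg$d_move + 1 > cfg$n_units) {
    abort("capacity error: d_prep + d_move + 1 exceeds n_units")
  }
  if (cfg$p_jump < 0 || cfg$p_jump > 1) abort("p_jump must be in [0, 1]")
  durs <- c(cfg$trigger_lead, cfg$trigger_jitter, cfg$delay_range,
            cfg$rt_mean, cfg$rt_sd, cfg$correction_latency, cfg$motor_delay)
  if (any(durs < 0)) abort("durations must be nonnegative")
  if (nrow(cfg$jump_pairs) > 0 &&
      any(cfg$jump_pairs$first == cfg$jump_pairs$final)) {
    abort("jump pairs must have distinct first/final targets")
  }
  invisible(cfg)
}

# target direction (radians) of ring target k
target_theta <- function(k, n_conditions) 2 * pi * (k - 1) / n_conditions

target_xy <- function(k, cfg) {
  th <- target_theta(k, cfg$n_conditions)
  cfg$reach_distance * c(cos(th), sin(th))
}

# per-target latent pattern: low-order Fourier features of target angle, one
# per latent dimension, equal variance across a full ring of targets
ring_patterns <- function(d, n_conditions, phase = 0) {
  th <- target_theta(seq_len(n_conditions), n_conditions) + phase
  p <- matrix(0, d, n_conditions)
  for (k in seq_len(d)) {
    m <- ceiling(k / 2)
    p[k, ] <- if (k %% 2 == 1) cos(m * th) else sin(m * th)
  }
  p
}

#' Draw the latent ground truth of a synthetic session
#'
#' Draws an orthonormal set of `d_prep + d_move + 1` population dimensions
#' (preparatory basis, movement basis, trigger vector) by QR
#' orthogonalization of a seeded Gaussian matrix, per-target latent patterns
#' laid out on a ring, and per-unit baseline rates.
#'
#' @param config A [generator_config()].
#' @return List of class `ground_truth` with elements `B_prep`
#'   (`n_units x d_prep`), `B_move`, `b_trig` (unit vector), `prep_patterns`
#'   (`d_prep x n_conditions`), `move_patterns`, `baseline` (pre-softplus),
#'   `gain`, and `noise_sd`. `generate_session()` appends a per-trial tibble
#'   `trials` with true event times and initial-direction labels.
#' @export
make_ground_truth <- function(config) {
  validate_generator_config(config)
  n <- config$n_units
  L <- config$d_prep + config$d_move + 1
  local_seed(derive_seed(config$seed, "truth"), {
    V <- matrix(rnorm(n * L), n, L)
    # the initiation (trigger) component raises firing across the
    # population, so its loadings are same-signed; tuned bases are then
    # orthogonalized against it
    b_trig <- abs(V[, L])
    b_trig <- b_trig / sqrt(sum(b_trig^2))
    B <- orthonormalize(cbind(b_trig, V[, -L]))
    # active arm-area units: substantial baselines with deep direction
    # tuning, keeping peak movement-epoch rates below ~80 spikes/s
    baseline <- softplus_inv(runif(n, 10, 30))
  })
  # scales per-unit tuned modulation into the 20-40 spikes/s depth range
  # of strongly tuned reaching units
  gain <- 30 * sqrt(n / L)
  truth <- list(
    B_prep = B[, 1 + seq_len(config$d_prep), drop = FALSE],
    B_move = B[, 1 + config$d_prep + seq_len(config$d_move), drop = FALSE],
    b_trig = b_trig,
    prep_patterns = ring_patterns(config$d_prep, config$n_conditions),
    move_patterns = ring_patterns(config$d_move, config$n_conditions,
                                  phase = 0.7),
    baseline = baseline,
    gain = gain,
    noise_sd = NA_real_
  )
  class(truth) <- "ground_truth"
  truth
}

# Latent time courses for one trial. Returns list(time, Z) with Z of shape
# (d_prep + d_move + 1) x T. Uses the current RNG state.
simulate_trial_events <- function(config) {
  target_on <- runif(1, 0.5, 0.7)
  go <- target_on + runif(1, config$delay_range[1], config$delay_range[2])
  rt <- max(0.18, rnorm(1, config$rt_mean, config$rt_sd))
  onset <- go + rt
  trigger <- onset - config$trigger_lead + rnorm(1, 0, config$trigger_jitter)
  trigger <- max(trigger, go + 0.01)
  list(target_on = target_on, go = go, onset = onset, trigger = trigger,
       t_end = onset + 0.7)
}

#' Simulate the events and latent trajectory of one trial
#'
#' Samples the delay period, reaction time and (on jump trials) jump time,
#' applies the trigger-vs-jump behavioural rule, and constructs the
#' piecewise-smooth latent time courses: preparatory latents ramp to the
#' first target's pattern during the delay and decay after movement onset;
#' movement latents are active from just before movement onset; the trigger
#' latent ramps through its threshold at the true trigger time. After a
#' jump, preparatory latents re-target to the final pattern starting
#' `correction_latency` after the jump — always in `"always_prepare"` mode,
#' only while preparation is still engaged (early jumps) in
#' `"direct_response"` mode. Uses the current RNG state; seed upstream.
#'
#' @param truth A [make_ground_truth()] result.
#' @param config The matching [generator_config()].
#' @param first_target,final_target Ring target indices (equal on non-jump
#'   trials).
#' @param is_jump Logical.
#' @return List with `events` (times in s), `label` (`"first"` or
#'   `"final"`), `time` (latent grid) and `Z` (latent matrix).
#' @export
simulate_trial <- function(truth, config, first_target, final_target,
                           is_jump) {
  if (is_jump && first_target == final_target) {
    abort("jump trial needs distinct targets")
  }
  ev <- simulate_trial_events(config)
  jump <- NA_real_
  label <- "first"
  if (is_jump) {
    lo <- max(ev$go + 0.005, ev$onset - config$jump_max_lead)
    jump <- runif(1, min(lo, ev$onset - 0.011), ev$onset - 0.010)
    label <- if (ev$trigger < jump) "first" else "final"
  }
  tt <- seq(0, ev$t_end, by = config$dt)
  dp <- config$d_prep
  dm <- config$d_move

  p_first <- truth$prep_patterns[, first_target]
  p_final <- truth$prep_patterns[, final_target]
  m_first <- truth$move_patterns[, first_target]
  m_final <- truth$move_patterns[, final_target]

  engage <- smoothstep(tt, ev$target_on + 0.06, 0.08)
  t_corr <- if (is_jump) jump + config$correction_latency else Inf

  # preparation hands off to movement generation at the trigger event, so
  # by movement onset the prep latents have largely collapsed
  if (!is_jump) {
    env_p <- engage * (1 - smoothstep(tt, ev$trigger, 0.20))
    pat_p <- outer(p_first, rep(1, length(tt)))
  } else if (label == "final") {
    # early jump: correction while preparation is still engaged (both modes)
    decay_start <- max(ev$trigger, t_corr + 0.10)
    env_p <- engage * (1 - smoothstep(tt, decay_start, 0.20))
    w <- smoothstep(tt, t_corr, 0.08)
    pat_p <- outer(p_first, 1 - w) + outer(p_final, w)
  } else if (config$mode == "always_prepare") {
    # late jump: preparation re-engages around the corrective response
    base_env <- engage * (1 - smoothstep(tt, ev$trigger, 0.20))
    bump <- smoothstep(tt, t_corr, 0.08) *
      (1 - smoothstep(tt, t_corr + 0.25, 0.20))
    env_p <- pmin(base_env + bump, 1)
    w <- smoothstep(tt, t_corr, 0.08)
    pat_p <- outer(p_first, 1 - w) + outer(p_final, w)
  } else {
    # direct_response: late-jump correction bypasses preparatory dimensions
    env_p <- engage * (1 - smoothstep(tt, ev$trigger, 0.20))
    pat_p <- outer(p_first, rep(1, length(tt)))
  }
  Zp <- pat_p * rep(env_p, each = dp)

  env_m <- smoothstep(tt, ev$onset - 0.02, 0.10) *
    (1 - smoothstep(tt, ev$onset + 0.35, 0.25))
  if (is_jump && label == "first") {
    t_mc <- max(t_corr, ev$onset) + config$motor_delay
    wm <- smoothstep(tt, t_mc, 0.08)
    pat_m <- outer(m_first, 1 - wm) + outer(m_final, wm)
  } else {
    pat_m <- outer(m_final, rep(1, length(tt)))
  }
  Zm <- pat_m * rep(env_m, each = dm)

  z_t <- config$trigger_amplitude *
    smoothstep(tt, ev$trigger - 0.075, 0.15) *
    (1 - smoothstep(tt, ev$onset + 0.40, 0.20))

  list(events = c(target_on = ev$target_on, go = ev$go, jump = jump,
                  trigger = ev$trigger, onset = ev$onset, t_end = ev$t_end),
       label = label,
       time = tt,
       Z = rbind(Zp, Zm, matrix(z_t, 1)))
}

#' Emit spikes from a latent trajectory
#'
#' Per-unit rate is `softplus(baseline + gain * B %*% Z + noise)` (spikes/s),
#' where `B = [B_prep | B_move | b_trig]` and the noise is a slowly varying
#' per-unit Gaussian process with s.d. `truth$noise_sd` (linear
#' interpolation of 50 ms knots). Spikes are drawn by inhomogeneous-Poisson
#' thinning at the latent resolution. Uses the current RNG state.
#'
#' @param latents Result of [simulate_trial()] (`time` and `Z`).
#' @param truth Ground truth with `gain` and `noise_sd` set.
#' @param config The generator configuration.
#' @return List with one ascending numeric spike-time vector per unit.
#' @export
emit_spikes <- function(latents, truth, config) {
  B <- cbind(truth$B_prep, truth$B_move, truth$b_trig)
  tt <- latents$time
  nT <- length(tt)
  n <- config$n_units
  drive <- truth$gain * (B %*% latents$Z)
  if (!is.na(truth$noise_sd) && truth$noise_sd > 0) {
    knot_t <- seq(0, tt[nT] + 0.05, by = 0.05)
    knots <- matrix(rnorm(n * length(knot_t), 0, truth$noise_sd),
                    n, length(knot_t))
    idx <- pmin(findInterval(tt, knot_t), length(knot_t) - 1L)
    frac <- (tt - knot_t[idx]) / 0.05
    noise <- knots[, idx, drop = FALSE] * rep(1 - frac, each = n) +
      knots[, idx + 1L, drop = FALSE] * rep(frac, each = n)
    drive <- drive + noise
  }
  x <- drive + truth$baseline
  rate <- log1p(exp(x))  # softplus; pre-link drives stay far below overflow
  t_end <- tt[nT]
  rmax <- apply(rate, 1, max)
  n_cand <- rpois(n, rmax * t_end)
  tot <- sum(n_cand)
  out <- rep(list(numeric(0)), n)
  if (tot > 0) {
    unit <- rep.int(seq_len(n), n_cand)
    cand <- runif(tot, 0, t_end)
    ti <- pmin(floor(cand / config$dt) + 1L, nT)
    keep <- runif(tot) < rate[cbind(unit, ti)] / rmax[unit]
    kept <- split(cand[keep], factor(unit[keep], levels = seq_len(n)))
    out <- lapply(kept, sort)
    names(out) <- NULL
  }
  out
}

# minimum-jerk progress profile on [0, 1]
min_jerk <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  10 * x^3 - 15 * x^4 + 6 * x^5
}

rotate_xy <- function(m, ang) {
  cbind(m[, 1] * cos(ang) - m[, 2] * sin(ang),
        m[, 1] * sin(ang) + m[, 2] * cos(ang))
}

#' Simulate the hand trajectory of one trial
#'
#' Bell-shaped (minimum-jerk) reach toward the initially selected target;
#' on corrected trials a second minimum-jerk submovement toward the final
#' target starts `correction_latency + motor_delay` after the jump, so the
#' path first heads toward the first target and then bends (or reverses)
#' toward the final one. Heading noise of s.d. `kin_angle_noise_deg` is
#' applied as an initial rotation that decays over the reach, leaving the
#' endpoint on the final target. Uses the current RNG state.
#'
#' @param events Named event vector from [simulate_trial()].
#' @param label Initial-direction label (`"first"` or `"final"`).
#' @param first_xy,final_xy Target coordinates (cm).
#' @param config Generator configuration.
#' @return T x 3 matrix with columns `time`, `x`, `y`.
#' @export
simulate_kinematics <- function(events, label, first_xy, final_xy, config) {
  tt <- seq(0, events[["t_end"]], by = config$kin_dt)
  onset <- events[["onset"]]
  dur <- 0.45
  prog <- min_jerk((tt - onset) / dur)
  aim <- if (label == "first") first_xy else final_xy
  path <- outer(prog, aim)
  eps <- rnorm(1, 0, config$kin_angle_noise_deg) * pi / 180
  path <- rotate_xy(path, eps * (1 - prog))
  if (label == "first" && is.finite(events[["jump"]])) {
    # the corrective submovement never starts before the hand clears the
    # 1 cm radius (~85 ms into the reach), so the initial angle reflects
    # the initially selected plan
    t_kc <- max(events[["jump"]] + config$correction_latency +
                  config$motor_delay, onset + 0.10)
    prog2 <- min_jerk((tt - t_kc) / 0.35)
    path <- path + outer(prog2, final_xy - first_xy)
  }
  path <- path + matrix(rnorm(2 * length(tt), 0, 0.005), ncol = 2)
  cbind(time = tt, x = path[, 1], y = path[, 2])
}

#' Generate a full synthetic session with ground truth
#'
#' Composes [make_ground_truth()], [simulate_trial()], [emit_spikes()] and
#' [simulate_kinematics()] into a validated [reach_session()] plus the
#' generating ground truth. The trial mix follows `p_jump`; non-jump targets
#' and jump pairs are drawn uniformly. Fully deterministic given
#' `config$seed` (independent named RNG streams for events, spikes and
#' kinematics).
#'
#' @param config A [generator_config()].
#' @return List with `session` (a `reach_session`) and `truth` (a
#'   `ground_truth` whose `trials` tibble holds per-trial true trigger
#'   times, movement onsets and initial-direction labels).
#' @export
generate_session <- function(config) {
  validate_generator_config(config)
  truth <- make_ground_truth(config)
  n_tr <- config$n_trials

  local_seed(derive_seed(config$seed, "conditions"), {
    is_jump <- runif(n_tr) < config$p_jump
    if (nrow(config$jump_pairs) == 0) is_jump[] <- FALSE
    nj_target <- sample.int(config$n_conditions, n_tr, replace = TRUE)
    pair_idx <- sample.int(max(nrow(config$jump_pairs), 1L), n_tr,
                           replace = TRUE)
  })
  first <- ifelse(is_jump, config$jump_pairs$first[pair_idx], nj_target)
  final <- ifelse(is_jump, config$jump_pairs$final[pair_idx], nj_target)

  # direction-tuned drive scale -> baseline noise s.d. at the configured
  # snr: deterministic reference pass over one trial per target. The
  # trigger latent is excluded so snr measures the tuned (condition-
  # separating) signal against the noise, independent of the large
  # condition-invariant initiation component.
  ref_sd <- {
    B_tuned <- cbind(truth$B_prep, truth$B_move)
    tuned_rows <- seq_len(config$d_prep + config$d_move)
    local_seed(derive_seed(config$seed, "snr_ref"), {
      sds <- vapply(seq_len(config$n_conditions), function(k) {
        lt <- simulate_trial(truth, config, k, k, FALSE)
        sd(truth$gain * (B_tuned %*% lt$Z[tuned_rows, , drop = FALSE]))
      }, numeric(1))
    })
    mean(sds)
  }
  truth$noise_sd <- if (config$snr > 0) ref_sd / config$snr else 0

  trials <- vector("list", n_tr)
  spikes <- vector("list", n_tr)
  kin <- vector("list", n_tr)
  local_seed(derive_seed(config$seed, "trials"), {
    for (j in seq_len(n_tr)) {
      lt <- simulate_trial(truth, config, first[j], final[j], is_jump[j])
      spikes[[j]] <- emit_spikes(lt, truth, config)
      f_xy <- target_xy(first[j], config)
      l_xy <- target_xy(final[j], config)
      kin[[j]] <- simulate_kinematics(lt$events, lt$label, f_xy, l_xy, config)
      cond <- if (is_jump[j]) {
        paste0("J", first[j], "-", final[j])
      } else {
        paste0("T", first[j])
      }
      trials[[j]] <- tibble::tibble(
        trial_id = sprintf("tr%04d", j),
        condition_id = cond,
        is_jump = is_jump[j],
        target_on_time = lt$events[["target_on"]],
        go_cue_time = lt$events[["go"]],
        jump_time = lt$events[["jump"]],
        first_target_x = f_xy[1], first_target_y = f_xy[2],
        final_target_x = l_xy[1], final_target_y = l_xy[2],
        move_onset_time = NA_real_,
        true_onset = lt$events[["onset"]],
        true_trigger = lt$events[["trigger"]],
        true_label = lt$label
      )
    }
  })
  trials <- dplyr::bind_rows(trials)
  truth$trials <- trials[, c("trial_id", "condition_id", "is_jump",
                             "jump_time", "true_onset", "true_trigger",
                             "true_label")]

  tr <- trials[, setdiff(names(trials),
                         c("true_onset", "true_trigger", "true_label"))]
  tr$kinematics <- kin
  units <- tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(config$n_units)),
    region = rep(c("M1", "PMd"), length.out = config$n_units),
    spikes = lapply(seq_len(config$n_units),
                    function(i) lapply(spikes, `[[`, i))
  )
  session <- reach_session(units, tr,
                           meta = list(session_id = paste0("synth-",
                                                           config$seed)))
  list(session = session, truth = truth)
}

#' Ground-truth dimensions in soft-normalized rate space
#'
#' The analysis operates on soft-normalized firing rates, so generative
#' dimensions must be mapped through the same per-unit divisors before
#' being compared with recovered dimensions: a generative basis `B` becomes
#' `diag(1/normalization) %*% B` in normalized-rate space.
#'
#' @param truth A `ground_truth`.
#' @param normalization Per-unit divisors from [normalize_rates()].
#' @return List with `B_prep`, `B_move` (columns not re-orthonormalized;
#'   compare via [principal_angles()]) and unit-norm `b_trig`.
#' @export
truth_in_normalized_space <- function(truth, normalization) {
  stopifnot(length(normalization) == nrow(truth$B_prep))
  sc <- 1 / normalization
  bt <- truth$b_trig * sc
  list(B_prep = truth$B_prep * sc,
       B_move = truth$B_move * sc,
       b_trig = bt / sqrt(sum(bt^2)))
}
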