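#' Pipeline configuration
#'
#' Bundles every stage parameter with its default: rate estimation (30 ms
#' Gaussian kernel, 10 ms grid), decoder epochs and held-out fraction,
#' sigmoid bootstrap and CI filter, the 70% PCA dimension rule, optimizer
#' settings and the movement-epoch distance window. A run embeds its
#' config (and a hash of it) in the report.
#'
#' @param kernel_sd Gaussian kernel s.d. (s). @param step Rate grid step (s).
#' @param delay_window Delay epoch after target onset (s).
#' @param move_window Movement epoch after movement onset (s).
#' @param dim_threshold PCA cumulative-variance threshold for subspace
#'   sizes.
#' @param max_dims Cap on each subspace dimensionality.
#' @param epoch_pre,epoch_peri Decoder training epochs relative to movement
#'   onset (s).
#' @param heldout_fraction Held-out fraction of non-jump trials.
#' @param svm_cost Decoder soft-margin constant.
#' @param n_boot Bootstrap resamples for sigmoid CIs.
#' @param max_ci CI half-width filter threshold (ms).
#' @param min_sigmoid_trials Minimum jump trials per fitted condition.
#' @param n_starts Optimizer multi-starts.
#' @param n_kurtosis_draws Null draws for the weight-concentration test.
#' @param distance_window Movement-epoch averaging window (s).
#' @param min_units Minimum simultaneously recorded units; smaller sessions
#'   are excluded (an outcome, not an error).
#' @param seed Master seed for all stage randomness.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(kernel_sd = 0.030, step = 0.010,
                            delay_window = c(0, 0.3),
                            move_window = c(0, 0.3),
                            dim_threshold = 0.70,
                            max_dims = 8L,
                            epoch_pre = c(-0.360, -0.180),
                            epoch_peri = c(-0.120, 0.060),
                            heldout_fraction = 0.1,
                            svm_cost = 0.001,
                            n_boot = 1000,
                            max_ci = 50,
                            min_sigmoid_trials = 8,
                            n_starts = 10,
                            n_kurtosis_draws = 10000,
                            distance_window = c(0, 0.2),
                            min_units = 10L,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full per-session analysis
#'
#' Orchestrates the complete analysis of one session: movement-onset
#' detection, firing-rate estimation and soft normalization, behavioural
#' sigmoid fits with CI filtering and cross-angle ANOVAs, trigger-decoder
#' training, per-trial trigger events and leave-one-out behavioural
#' prediction, weight-concentration test, preparatory/movement subspace
#' optimization in the trigger null space, cross-condition variance
#' traces, jump-distance panels and the movement-epoch rank-sum test.
#' Sessions with fewer than `config$min_units` units yield an exclusion
#' outcome rather than an error, mirroring standard dataset screening.
#' Deterministic given `config$seed`.
#'
#' @param session A `reach_session` (or a [generator_config()], which is
#'   generated first).
#' @param config A [pipeline_config()].
#' @return A `pipeline_run` report: stage outputs (`behavior`, `trigger`,
#'   `subspaces`, `variance`, `distance`), per-stage summaries, exclusion
#'   table, config and config hash. For excluded sessions, a stub with
#'   `excluded = TRUE` and the reason.
#' @export
run_pipeline <- function(session, config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    now <- proc.time()[["elapsed"]]
    timings[[name]] <<- now - t0
    t0 <<- now
  }
  if (inherits(session, "generator_config")) {
    session <- generate_session(session)$session
  }
  validate_session(session)
  exclusions <- tibble::tibble(scope = character(), id = character(),
                               reason = character())
  note_excl <- function(scope, id, reason) {
    exclusions <<- dplyr::bind_rows(
      exclusions, tibble::tibble(scope = scope, id = id, reason = reason))
  }
  if (nrow(session$units) < config$min_units) {
    return(structure(list(
      excluded = TRUE, reason = "min_units",
      n_units = nrow(session$units), config = config,
      config_hash = rlang::hash(config)
    ), class = "pipeline_run"))
  }

  session <- suppressWarnings(detect_all_onsets(session))
  bad <- !session$trials$valid
  if (any(bad)) {
    note_excl("trial", paste(session$trials$trial_id[bad], collapse = ","),
              "onset_detection")
  }
  tick("onsets")

  # ---- behavior -----------------------------------------------------------
  behav <- tryCatch(suppressWarnings(jump_behavior(session)),
                    error = function(e) NULL)
  has_jumps <- !is.null(behav)
  fits <- list()
  for (cond in if (has_jumps) unique(behav$condition_id) else character()) {
    bc <- behav[behav$condition_id == cond & is.finite(behav$angle_norm), ]
    f <- tryCatch(
      fit_behavior_sigmoid(bc$latency_ms, bc$angle_norm,
                           n_boot = config$n_boot,
                           seed = derive_seed(config$seed, cond),
                           min_trials = config$min_sigmoid_trials),
      error = function(e) e)
    if (inherits(f, "error")) {
      note_excl("condition", cond, paste0("sigmoid: ", conditionMessage(f)))
    } else {
      fits[[cond]] <- dplyr::bind_cols(
        tibble::tibble(condition_id = cond,
                       jump_angle = bc$jump_angle[1]),
        glance(f))
    }
  }
  fit_tbl <- if (length(fits)) dplyr::bind_rows(fits) else NULL
  retained <- if (!is.null(fit_tbl)) {
    suppressWarnings(filter_fits_by_ci(fit_tbl, config$max_ci))
  } else {
    NULL
  }
  if (!is.null(retained)) {
    for (ex in attr(retained, "excluded")) note_excl("condition", ex, "ci50")
  }
  anova_t50 <- tryCatch(anova_crossing_times(retained, "t50"),
                        error = function(e) NULL)
  anova_slope <- tryCatch(anova_crossing_times(retained, "slope"),
                          error = function(e) NULL)
  tick("behavior")

  # ---- rates --------------------------------------------------------------
  # soft-normalization divisors come from the full trial span on a coarse
  # grid (the concatenated s.d. of a 30 ms-smoothed rate is insensitive to
  # the sampling step); analysis tensors then share those divisors
  max_t <- max(vapply(session$trials$kinematics,
                      function(k) max(k[, 1]), numeric(1)))
  div_tensor <- smooth_rates(session, align = "target_on",
                             window = c(0, max_t),
                             kernel_sd = config$kernel_sd,
                             step = max(config$step, 0.02))
  divisors <- normalize_rates(div_tensor)$normalization
  wide <- smooth_rates(session, align = "target_on", window = c(-0.1, 1.0),
                       kernel_sd = config$kernel_sd, step = config$step)
  wide <- normalize_rates(wide, divisors = divisors)
  go_rates <- smooth_rates(session, align = "go_cue", window = c(-0.3, 0.7),
                           kernel_sd = config$kernel_sd, step = config$step)
  go_rates <- normalize_rates(go_rates, divisors = divisors)
  mov <- smooth_rates(session, align = "move_onset",
                      window = c(-0.6, 0.45),
                      kernel_sd = config$kernel_sd, step = config$step)
  mov <- normalize_rates(mov, divisors = divisors)
  tick("rates")

  # ---- trigger ------------------------------------------------------------
  trig <- train_trigger_svm(mov, seed = config$seed,
                            epoch_pre = config$epoch_pre,
                            epoch_peri = config$epoch_peri,
                            heldout_fraction = config$heldout_fraction,
                            cost = config$svm_cost)
  events <- trigger_crossing_time(trig, go_rates, session)
  prediction <- if (has_jumps) {
    tryCatch(
      suppressWarnings(predict_jump_behavior(
        events, behav, min_trials = config$min_sigmoid_trials)),
      error = function(e) NULL)
  } else {
    NULL
  }
  kurt <- kurtosis_projection_test(trig$w,
                                   n_random = config$n_kurtosis_draws,
                                   seed = config$seed)
  tick("trigger")

  # ---- subspaces ----------------------------------------------------------
  labels <- if (has_jumps) behav[, c("trial_id", "label")] else NULL
  avg_target <- suppressWarnings(align_and_average(wide, labels = labels))
  avg_move <- suppressWarnings(align_and_average(mov, labels = labels))
  # delay-epoch data: only non-jump trials whose delay covers the window,
  # otherwise short-delay trials are already moving inside it
  min_delay <- config$delay_window[2]
  sess_delay <- select_trials(session, !.data$is_jump &
                                (.data$go_cue_time - .data$target_on_time) >=
                                  min_delay)
  del <- smooth_rates(sess_delay, align = "target_on",
                      window = config$delay_window + c(-0.1, 0.1),
                      kernel_sd = config$kernel_sd, step = config$step)
  del <- normalize_rates(del, divisors = divisors)
  avg_delay <- suppressWarnings(align_and_average(del))
  d_prep <- min(choose_dims(avg_delay, config$delay_window,
                            config$dim_threshold), config$max_dims)
  d_move <- min(choose_dims(avg_move, config$move_window,
                            config$dim_threshold), config$max_dims)
  epochs <- make_epoch_data(avg_delay, avg_move, unname(trig$w),
                            delay_window = config$delay_window,
                            move_window = config$move_window)
  subspaces <- optimize_subspaces(epochs, d_prep, d_move,
                                  n_starts = config$n_starts,
                                  seed = config$seed)
  var_delay <- cross_condition_variance(
    project_trigger_null(avg_target, unname(trig$w)), subspaces)
  var_move <- cross_condition_variance(
    project_trigger_null(avg_move, unname(trig$w)), subspaces)
  tick("subspaces")

  # ---- distances ----------------------------------------------------------
  panel <- NULL
  dist_test <- NULL
  if (has_jumps) {
    panel <- tryCatch(suppressWarnings(jump_distance_panel(
      list(target_on = wide, go_cue = go_rates, move_onset = mov),
      labels, subspaces, session, seed = config$seed)),
      error = function(e) NULL)
    dist_test <- if (!is.null(panel)) {
      tryCatch(
        movement_epoch_distance_test(panel, window = config$distance_window),
        error = function(e) NULL)
    } else {
      NULL
    }
  }
  tick("distances")

  structure(list(
    excluded = FALSE,
    session_id = session$meta$session_id,
    n_units = nrow(session$units),
    n_trials = nrow(session$trials),
    behavior = list(trials = behav, fits = fit_tbl, retained = retained,
                    anova_t50 = anova_t50, anova_slope = anova_slope),
    trigger = list(model = trig, events = events, prediction = prediction,
                   kurtosis = kurt),
    subspaces = subspaces,
    dims = c(prep = d_prep, move = d_move),
    variance = list(delay = var_delay, move = var_move),
    distance = list(panel = panel, test = dist_test),
    normalization = divisors,
    exclusions = exclusions,
    timings = timings,
    config = config,
    config_hash = rlang::hash(config)
  ), class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    cat("<pipeline_run> EXCLUDED (", x$reason, "), ", x$n_units,
        " units\n", sep = "")
    return(invisible(x))
  }
  cat("<pipeline_run> ", x$session_id, ": ", x$n_units, " units, ",
      x$n_trials, " trials\n", sep = "")
  cat(sprintf("  trigger: held-out accuracy %.3f, kurtosis p %.3f\n",
              x$trigger$model$heldout_accuracy, x$trigger$kurtosis$p_value))
  if (!is.null(x$trigger$prediction)) {
    cat(sprintf("  LOO R2 median %.3f, accuracy median %.3f (%d conditions)\n",
                stats::median(x$trigger$prediction$r2_loo),
                stats::median(x$trigger$prediction$accuracy),
                nrow(x$trigger$prediction)))
  }
  cat(sprintf("  subspaces: d_prep=%d d_move=%d objective %.3f\n",
              x$dims[["prep"]], x$dims[["move"]], x$subspaces$objective))
  if (!is.null(x$distance$test)) {
    cat(sprintf("  movement-epoch prep distance test: p = %.2g\n",
                x$distance$test$p_value))
  }
  invisible(x)
}

#' @export
glance.pipeline_run <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    return(tibble::tibble(excluded = TRUE, reason = x$reason,
                          n_units = x$n_units))
  }
  tibble::tibble(
    excluded = FALSE,
    n_units = x$n_units, n_trials = x$n_trials,
    heldout_accuracy = x$trigger$model$heldout_accuracy,
    kurtosis_p = x$trigger$kurtosis$p_value,
    median_r2_loo = if (!is.null(x$trigger$prediction)) {
      stats::median(x$trigger$prediction$r2_loo)
    } else {
      NA_real_
    },
    d_prep = unname(x$dims["prep"]), d_move = unname(x$dims["move"]),
    objective = x$subspaces$objective,
    distance_p = if (!is.null(x$distance$test)) {
      x$distance$test$p_value
    } else {
      NA_real_
    }
  )
}
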