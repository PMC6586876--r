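#' Train the movement-initiation decoder (trigger dimension)
#'
#' Trains a linear soft-margin support-vector machine to separate
#' single-timepoint population rate vectors drawn from a pre-movement epoch
#' (default 360-180 ms before movement onset) from vectors around movement
#' onset (default 120 ms before to 60 ms after), pooling all non-jump
#' trials and reach directions; the hyperplane normal is the trigger
#' dimension. Accuracy is assessed on a randomly held-out 10% of non-jump
#' trials that never enter training. The returned weights are
#' unit-normalized with the sign convention that decision values are
#' negative in the pre epoch and positive in the peri epoch.
#'
#' @param rates A normalized `rate_tensor` aligned to `move_onset`.
#' @param seed Seed for the held-out trial split.
#' @param epoch_pre,epoch_peri Epoch windows relative to movement onset (s).
#' @param heldout_fraction Fraction of non-jump trials held out.
#' @param cost Soft-margin regularization constant.
#' @param shuffle_labels Permute the epoch labels of the training points
#'   (seeded); a null control whose held-out accuracy should sit at chance.
#' @param max_train_trials Cap on the number of training trials (seeded
#'   subsample after the held-out split). Decoder weights saturate well
#'   below typical session sizes, and quadratic-programming time grows
#'   steeply with the training set, so the default caps training at 300
#'   trials; held-out evaluation always uses the full held-out set.
#' @return An object of class `trigger_model`: unit-norm weights `w` (named
#'   by unit), offset `b` (same scaling), epochs, `heldout_accuracy`,
#'   `heldout_trials`, and the raw classifier scale `scale`.
#' @export
train_trigger_svm <- function(rates, seed = 1L,
                              epoch_pre = c(-0.360, -0.180),
                              epoch_peri = c(-0.120, 0.060),
                              heldout_fraction = 0.1,
                              cost = 0.001,
                              shuffle_labels = FALSE,
                              max_train_trials = 300) {
  stopifnot(inherits(rates, "rate_tensor"))
  if (rates$alignment != "move_onset") {
    abort("rates must be aligned to move_onset")
  }
  if (is.null(rates$normalization)) {
    abort("rates must be soft-normalized before decoding")
  }
  n_units <- dim(rates$values)[1]
  if (n_units < 10) {
    abort("dataset-exclusion error: < 10 simultaneously recorded units")
  }
  nj <- which(!rates$trials$is_jump)
  if (length(nj) < 10) abort("too few non-jump trials")
  tt <- rates$time
  idx_pre <- which(tt >= epoch_pre[1] & tt <= epoch_pre[2])
  idx_peri <- which(tt >= epoch_peri[1] & tt <= epoch_peri[2])
  if (!length(idx_pre) || !length(idx_peri)) {
    abort("tensor window does not cover the training epochs")
  }
  n_hold <- max(1L, round(heldout_fraction * length(nj)))
  hold <- local_seed(derive_seed(seed, "svm_split"),
                     sort(sample(nj, n_hold)))
  train <- setdiff(nj, hold)
  if (length(train) > max_train_trials) {
    train <- local_seed(derive_seed(seed, "svm_cap"),
                        sort(sample(train, max_train_trials)))
  }

  build <- function(trial_idx) {
    x_pre <- rates$values[, idx_pre, trial_idx, drop = FALSE]
    x_peri <- rates$values[, idx_peri, trial_idx, drop = FALSE]
    X <- cbind(matrix(x_pre, nrow = n_units),
               matrix(x_peri, nrow = n_units))
    y <- c(rep(-1, length(idx_pre) * length(trial_idx)),
           rep(1, length(idx_peri) * length(trial_idx)))
    ok <- stats::complete.cases(t(X))
    list(x = t(X)[ok, , drop = FALSE], y = y[ok])
  }
  trn <- build(train)
  if (length(unique(trn$y)) < 2) abort("training error: single-class data")
  if (shuffle_labels) {
    trn$y <- local_seed(derive_seed(seed, "label_shuffle"), sample(trn$y))
  }
  m <- e1071::svm(trn$x, factor(trn$y), kernel = "linear", cost = cost,
                  scale = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # canonical sign: peri-epoch decision values positive on training data
  d_trn <- drop(trn$x %*% w) + b
  if (!shuffle_labels &&
      mean(d_trn[trn$y == 1]) < mean(d_trn[trn$y == -1])) {
    w <- -w
    b <- -b
  }
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-12) abort("training error: degenerate weight vector")
  held <- build(hold)
  d_h <- drop(held$x %*% w) + b
  acc <- mean((d_h > 0) == (held$y == 1))
  structure(list(
    w = stats::setNames(w / nrm, rates$unit_ids),
    b = b / nrm,
    scale = nrm,
    epoch_pre = epoch_pre, epoch_peri = epoch_peri,
    heldout_fraction = heldout_fraction,
    heldout_accuracy = acc,
    heldout_trials = rates$trials$trial_id[hold],
    n_train_points = nrow(trn$x),
    cost = cost
  ), class = "trigger_model")
}

#' @export
print.trigger_model <- function(x, ...) {
  cat(sprintf(
    "<trigger_model> %d units, held-out accuracy %.3f (%d train points)\n",
    length(x$w), x$heldout_accuracy, x$n_train_points))
  invisible(x)
}

#' @export
tidy.trigger_model <- function(x, regions = NULL, ...) {
  out <- tibble::tibble(unit_id = names(x$w), weight = unname(x$w))
  if (!is.null(regions)) out$region <- regions[match(out$unit_id,
                                                     names(regions))]
  out
}

#' @export
glance.trigger_model <- function(x, ...) {
  tibble::tibble(heldout_accuracy = x$heldout_accuracy,
                 n_units = length(x$w),
                 n_train_points = x$n_train_points,
                 b = x$b, scale = x$scale)
}

#' Per-trial neural trigger events
#'
#' Projects each trial's population rate onto the trigger dimension and
#' finds the first time after the go cue at which the decision value
#' `w . x(t) + b` crosses zero from below, linearly interpolated between
#' grid points. The zero location is decoder-dependent: it marks when the
#' decoder deems the trial close to movement initiation. Absence of a
#' crossing is a valid outcome (`NA`).
#'
#' @param model A `trigger_model`.
#' @param rates A normalized `rate_tensor` on a grid covering go cue
#'   through movement onset in each trial's aligned time (typically aligned
#'   to `target_on` with a wide window).
#' @param session The `reach_session` (for go-cue and jump times).
#' @return Tibble with `trial_id`, `crossing_time` (absolute trial time, s)
#'   and `offset_vs_jump` (crossing - jump, s; `NA` on non-jump trials).
#' @export
trigger_crossing_time <- function(model, rates, session) {
  stopifnot(inherits(model, "trigger_model"))
  w <- unname(model$w)
  stopifnot(length(w) == dim(rates$values)[1])
  tr <- rates$trials
  m <- match(tr$trial_id, session$trials$trial_id)
  go <- session$trials$go_cue_time[m]
  jump <- session$trials$jump_time[m]
  tt <- rates$time
  out <- vector("list", nrow(tr))
  for (j in seq_len(nrow(tr))) {
    x <- rates$values[, , j]
    d <- drop(w %*% x) + model$b
    # aligned time of this trial's go cue
    go_rel <- go[j] - tr$event_time[j]
    crossing <- NA_real_
    ok <- which(!is.na(d))
    if (length(ok) > 1) {
      # consecutive valid grid pairs with an upward zero crossing
      pairs <- ok[which(diff(ok) == 1L)]
      for (i0 in pairs) {
        i1 <- i0 + 1L
        if (d[i0] < 0 && d[i1] >= 0) {
          f <- -d[i0] / (d[i1] - d[i0])
          t_star <- tt[i0] + f * (tt[i1] - tt[i0])
          if (t_star >= go_rel) {
            crossing <- t_star + tr$event_time[j]
            break
          }
        }
      }
    }
    out[[j]] <- tibble::tibble(
      trial_id = tr$trial_id[j],
      crossing_time = crossing,
      offset_vs_jump = if (!is.na(jump[j])) crossing - jump[j] else NA_real_
    )
  }
  dplyr::bind_rows(out)
}

#' Predict jump behaviour from trigger-event timing
#'
#' For each jump condition, fits the behavioural sigmoid to (neural trigger
#' minus jump time) against the normalized initial reach angle, and
#' assesses single-trial predictive power by leave-one-out
#' cross-validation: each trial's angle is predicted from the sigmoid fit
#' on the remaining trials. The coefficient of determination on the
#' left-out predictions is `R^2 = 1 - SS_res / SS_tot` with
#' `SS_res = sum((y_pred - y)^2)` and `SS_tot = sum((mean(y) - y)^2)`; it
#' can be negative when generalization underperforms the mean.
#' Classification accuracy is the fraction of trials whose predicted angle
#' falls on the same side of 0 (nearer -1 vs nearer +1) as the observed
#' angle. Conditions with fewer than `min_trials` usable trials are
#' skipped with a warning.
#'
#' @param events Tibble from [trigger_crossing_time()] (needs
#'   `offset_vs_jump`).
#' @param behavior Tibble from [jump_behavior()] (needs `trial_id`,
#'   `condition_id`, `angle_norm`).
#' @param min_trials Minimum usable trials per condition (default 8).
#' @return Tibble per condition: `condition_id`, `n_trials`, `r2_loo`,
#'   `accuracy`, `t50`, `slope` (from the all-trial fit).
#' @export
predict_jump_behavior <- function(events, behavior, min_trials = 8) {
  d <- dplyr::inner_join(behavior, events, by = "trial_id")
  d <- d[is.finite(d$offset_vs_jump) & is.finite(d$angle_norm), ]
  out <- list()
  for (cond in unique(d$condition_id)) {
    dc <- d[d$condition_id == cond, ]
    n <- nrow(dc)
    if (n < min_trials || !any(dc$angle_norm < 0) ||
        !any(dc$angle_norm > 0)) {
      warn(paste0("skipping condition ", cond,
                  ": insufficient usable trials for prediction"))
      next
    }
    x <- dc$offset_vs_jump * 1000
    y <- dc$angle_norm
    full <- tryCatch(
      fit_behavior_sigmoid(x, y, n_boot = 0, min_trials = min_trials),
      error = function(e) NULL)
    if (is.null(full)) {
      warn(paste0("skipping condition ", cond, ": sigmoid fit failed"))
      next
    }
    pred <- vapply(seq_len(n), function(i) {
      # warm-started at the all-trial fit: leaving one trial out moves the
      # optimum little, so two starts suffice
      fi <- tryCatch(
        fit_behavior_sigmoid(x[-i], y[-i], n_boot = 0,
                             min_trials = min_trials - 1,
                             t50_starts = c(full$t50, stats::median(x[-i])),
                             s_start = full$scale_ms),
        error = function(e) NULL)
      if (is.null(fi)) mean(y[-i]) else predict(fi, x[i])
    }, numeric(1))
    r2 <- loo_r_squared(y, pred)
    acc <- mean((pred > 0) == (y > 0))
    out[[length(out) + 1]] <- tibble::tibble(
      condition_id = cond, n_trials = n, r2_loo = r2, accuracy = acc,
      t50 = full$t50, slope = full$slope)
  }
  if (!length(out)) abort("no condition had enough usable trials")
  dplyr::bind_rows(out)
}

#' Coefficient of determination of held-out predictions
#'
#' `R^2 = 1 - SS_res / SS_tot`, `SS_res = sum((y_pred - y)^2)`,
#' `SS_tot = sum((mean(y) - y)^2)`. Negative values indicate predictions
#' worse than the observed mean (possible because the predictions are
#' cross-validated).
#'
#' @param y Observed values. @param y_pred Predictions.
#' @return R-squared (scalar).
#' @export
loo_r_squared <- function(y, y_pred) {
  ss_res <- sum((y_pred - y)^2)
  ss_tot <- sum((mean(y) - y)^2)
  1 - ss_res / ss_tot
}

#' Kurtosis concentration test of decoder weights
#'
#' Tests whether the trigger-dimension weights are more concentrated on a
#' subset of units than expected by chance: the sample kurtosis (fourth
#' standardized moment about the mean, non-excess) of the weight entries is
#' compared with the kurtoses of `n_random` random unit vectors drawn
#' uniformly on the sphere in the same dimension. The weight profile is
#' significantly concentrated when its kurtosis exceeds the 95th percentile
#' of this null.
#'
#' @param w Weight vector (at least 4 entries, nonconstant).
#' @param n_random Null draws (default 10000).
#' @param seed Seed for the null draws.
#' @return Tibble with `kurtosis`, `p_value` (fraction of null >= observed),
#'   `significant` (exceeds the null 95th percentile), `n_units`,
#'   `n_random`.
#' @export
kurtosis_projection_test <- function(w, n_random = 10000, seed = 1L) {
  w <- as.numeric(w)
  d <- length(w)
  if (d < 4) abort("need at least 4 units")
  if (var(w) < 1e-24) abort("undefined-kurtosis error: constant weights")
  obs <- moment_kurtosis(w)
  null_k <- local_seed(derive_seed(seed, "kurtosis_null"), {
    Z <- matrix(rnorm(n_random * d), n_random, d)
    Z <- Z / sqrt(rowSums(Z^2))
    Zc <- Z - rowMeans(Z)
    m2 <- rowMeans(Zc^2)
    rowMeans(Zc^4) / m2^2
  })
  p <- mean(null_k >= obs)
  tibble::tibble(kurtosis = obs, p_value = p,
                 significant = obs > quantile(null_k, 0.95),
                 n_units = d, n_random = n_random)
}

# Pearson (non-excess) kurtosis with population moments
moment_kurtosis <- function(x) {
  xc <- x - mean(x)
  mean(xc^4) / mean(xc^2)^2
}
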