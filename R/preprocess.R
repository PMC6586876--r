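#' Estimate aligned single-trial firing rates
#'
#' Convolves each unit's spike train with a Gaussian kernel (s.d.
#' `kernel_sd`, evaluated in continuous time so the output grid does not
#' alias the kernel) and samples the result on a uniform grid aligned to a
#' per-trial task event. Edge effects are handled by renormalizing the
#' kernel mass to the observed trial window, so a constant-rate train keeps
#' its rate up to the trial boundaries. Rates are in spikes/s
#' (unnormalized; see [normalize_rates()]).
#'
#' Grid points that fall outside a trial's recorded window are set to `NA`
#' and the per-trial observed bounds are kept in the `trials` table of the
#' result.
#'
#' @param session A `reach_session`.
#' @param align One of `"target_on"`, `"go_cue"`, `"jump"`, `"move_onset"`.
#'   Trials lacking the event (e.g. non-jump trials for `"jump"`, or missing
#'   `move_onset_time`) are excluded.
#' @param window Length-2 numeric, grid limits relative to the event (s).
#' @param kernel_sd Gaussian kernel s.d. (s), default from session metadata.
#' @param step Grid step (s), default from session metadata.
#' @return A `rate_tensor`: list with `values` (units x timepoints x trials
#'   array), `time`, `alignment`, `trials` (tibble with per-trial event time
#'   and observed bounds), `unit_ids`, `normalization` (`NULL` until
#'   normalized).
#' @export
smooth_rates <- function(session, align = "target_on",
                         window = c(-0.5, 1.0),
                         kernel_sd = NULL, step = NULL) {
  kernel_sd <- kernel_sd %||% session$meta$kernel_sd
  step <- step %||% session$meta$rate_step
  if (!is.numeric(step) || step <= 0) abort("step must be > 0")
  if (!is.numeric(kernel_sd) || kernel_sd <= 0) abort("kernel_sd must be > 0")
  ev <- alignment_times(session$trials, align)
  keep <- which(!is.na(ev))
  if (!length(keep)) abort(paste0("no trial has alignment event ", align))
  ev <- ev[keep]
  trials <- session$trials[keep, ]
  tt <- seq(window[1], window[2], by = step)
  n_units <- nrow(session$units)
  n_t <- length(tt)
  n_tr <- length(keep)
  # per-trial observed window in aligned time
  t_end <- vapply(trials$kinematics, function(k) {
    if (is.null(k)) NA_real_ else max(k[, 1])
  }, numeric(1))
  sp_end <- vapply(seq_len(n_tr), function(j) {
    m <- vapply(session$units$spikes, function(sp) {
      s <- sp[[keep[j]]]
      if (length(s)) max(s) else NA_real_
    }, numeric(1))
    suppressWarnings(max(m, na.rm = TRUE))
  }, numeric(1))
  obs_hi <- ifelse(is.na(t_end), sp_end, pmax(t_end, sp_end, na.rm = TRUE)) - ev
  obs_hi[!is.finite(obs_hi)] <- window[2]
  obs_lo <- -ev

  vals <- array(NA_real_, dim = c(n_units, n_t, n_tr))
  kconst <- 1 / (kernel_sd * sqrt(2 * pi))
  reach <- 5 * kernel_sd            # kernel support truncated at 5 s.d.
  n_off <- ceiling(reach / step)
  offs <- seq(-n_off, n_off)
  for (i in seq_len(n_units)) {
    sp <- session$units$spikes[[i]]
    rel <- vector("list", n_tr)
    for (j in seq_len(n_tr)) {
      s <- sp[[keep[j]]] - ev[j]
      rel[[j]] <- s[s >= window[1] - reach & s <= window[2] + reach]
    }
    lens <- lengths(rel)
    all_s <- unlist(rel, use.names = FALSE)
    raw <- matrix(0, n_t, n_tr)
    if (length(all_s)) {
      grp <- rep.int(seq_len(n_tr), lens)
      # each spike only reaches grid points within the kernel support:
      # accumulate exact continuous-time kernel values at those points
      near <- round((all_s - window[1]) / step) + 1
      S <- length(all_s)
      gi <- rep(near, each = length(offs)) + offs
      si <- rep.int(seq_len(S), rep(length(offs), S))
      ok <- gi >= 1L & gi <= n_t
      gi <- gi[ok]
      si <- si[ok]
      d <- tt[gi] - all_s[si]
      kv <- kconst * exp(-d * d / (2 * kernel_sd^2))
      raw <- as.matrix(Matrix::sparseMatrix(
        i = gi, j = grp[si], x = kv, dims = c(n_t, n_tr)))
    }
    vals[i, , ] <- raw
  }
  # kernel-mass renormalization over each trial's observed window
  for (j in seq_len(n_tr)) {
    wmass <- stats::pnorm((obs_hi[j] - tt) / kernel_sd) -
      stats::pnorm((obs_lo[j] - tt) / kernel_sd)
    ok <- tt >= obs_lo[j] & tt <= obs_hi[j] & wmass > 1e-6
    vals[, ok, j] <- sweep(vals[, ok, j, drop = FALSE], 2, wmass[ok], `/`)
    vals[, !ok, j] <- NA_real_
  }
  structure(list(
    values = vals,
    time = tt,
    alignment = align,
    trials = tibble::tibble(trial_id = trials$trial_id,
                            condition_id = trials$condition_id,
                            is_jump = trials$is_jump,
                            event_time = ev,
                            obs_lo = obs_lo, obs_hi = obs_hi),
    unit_ids = session$units$unit_id,
    kernel_sd = kernel_sd, step = step,
    normalization = NULL
  ), class = "rate_tensor")
}

alignment_times <- function(trials, align) {
  switch(align,
    target_on = trials$target_on_time,
    go_cue = trials$go_cue_time,
    jump = trials$jump_time,
    move_onset = trials$move_onset_time,
    abort(paste0("unknown alignment: ", align))
  )
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<rate_tensor> ", d[1], " units x ", d[2], " timepoints x ", d[3],
      " trials, aligned to ", x$alignment,
      if (is.null(x$normalization)) " (unnormalized)" else " (normalized)",
      "\n", sep = "")
  invisible(x)
}

#' Soft-normalize a rate tensor
#'
#' For each unit, the firing rate is concatenated across all trials and its
#' standard deviation computed; the unit's rates are then divided by
#' `max(sd, 1)`. The floor at 1 prevents very low-rate units from being
#' inflated. Pass precomputed `divisors` to apply one session-wide
#' normalization to tensors built on other alignments or windows.
#'
#' @param rates A `rate_tensor`.
#' @param divisors Optional per-unit divisors (e.g. taken from another
#'   normalized tensor's `normalization` field).
#' @return The tensor with normalized `values` and `normalization` set.
#' @export
normalize_rates <- function(rates, divisors = NULL) {
  stopifnot(inherits(rates, "rate_tensor"))
  n_units <- dim(rates$values)[1]
  if (is.null(divisors)) {
    flat <- matrix(rates$values, nrow = n_units)
    s <- apply(flat, 1, sd, na.rm = TRUE)
    s[is.na(s)] <- 0
    divisors <- pmax(s, 1)
  }
  stopifnot(length(divisors) == n_units, all(divisors >= 1))
  rates$values <- rates$values / divisors
  rates$normalization <- divisors
  rates
}

#' Detect movement onset from the hand trajectory
#'
#' Hand speed is computed by central differences, lightly smoothed (3-sample
#' running mean, ~10 ms at the default sampling), and the time of peak speed
#' located; tracing backward from the peak, onset is the first time speed
#' falls below 5% of the maximum. The threshold is relative, so the result
#' is invariant to speed scaling. Reaction time on non-jump trials is
#' `onset - go_cue_time`.
#'
#' @param trial One-row tibble from a session's `trials` table (or any list
#'   with a `kinematics` matrix).
#' @param threshold Fraction of peak speed, default 0.05.
#' @return Onset time (s, trial-relative).
#' @export
detect_movement_onset <- function(trial, threshold = 0.05) {
  k <- if (is.matrix(trial)) trial else trial$kinematics[[1]]
  if (is.null(k) || nrow(k) < 5) abort("detection error: no usable trajectory")
  tt <- k[, 1]
  n <- nrow(k)
  vx <- (k[3:n, 2] - k[1:(n - 2), 2]) / (tt[3:n] - tt[1:(n - 2)])
  vy <- (k[3:n, 3] - k[1:(n - 2), 3]) / (tt[3:n] - tt[1:(n - 2)])
  sp <- sqrt(vx^2 + vy^2)
  sp <- stats::filter(sp, rep(1 / 3, 3), sides = 2)
  sp[is.na(sp)] <- 0
  sp <- as.numeric(sp)
  ts <- tt[2:(n - 1)]
  vmax <- max(sp)
  if (vmax < 1) abort("detection error: hand is stationary")
  ipk <- which.max(sp)
  below <- which(sp[seq_len(ipk)] < threshold * vmax)
  if (!length(below)) {
    abort("detection error: speed never below threshold before peak")
  }
  ts[max(below)]
}

#' Fill movement onsets for every trial of a session
#'
#' Runs [detect_movement_onset()] on each trial. Jump trials whose detected
#' onset does not follow the jump are flagged `valid = FALSE` (the task
#' requires the jump to precede movement, so such trials indicate an onset
#' detection failure) rather than dropped.
#'
#' @param session A `reach_session`.
#' @return The session with `move_onset_time` (and `valid`) updated.
#' @export
detect_all_onsets <- function(session) {
  n <- nrow(session$trials)
  onsets <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    onsets[j] <- tryCatch(detect_movement_onset(session$trials[j, ]),
                          error = function(e) NA_real_)
  }
  session$trials$move_onset_time <- onsets
  bad <- session$trials$is_jump & !is.na(onsets) &
    session$trials$jump_time >= onsets
  if (any(bad)) {
    warn(paste0(sum(bad), " jump trial(s) with jump at/after detected onset",
                " flagged invalid"))
    session$trials$valid[bad] <- FALSE
    session$trials$move_onset_time[bad] <- NA_real_
  }
  session
}

#' Average aligned rates by condition (and initial direction)
#'
#' Computes per-group mean firing-rate trajectories on the aligned grid.
#' Non-jump trials group by `condition_id`; jump trials additionally split
#' by the behavioural initial-direction label (`"first"` / `"final"`) when
#' `labels` is supplied, since jump trials initiated toward the two targets
#' follow different neural trajectories. Groups with no trials are omitted
#' with a warning.
#'
#' @param rates A `rate_tensor` (typically normalized).
#' @param labels Optional tibble with `trial_id` and `label` for jump
#'   trials; jump trials without a label are dropped from averaging.
#' @param min_trials Minimum trials per retained group.
#' @return A `condition_average`: list with `values` (units x timepoints x
#'   groups), `time`, `alignment`, `groups` tibble (`group_id`,
#'   `condition_id`, `is_jump`, `label`, `n_trials`).
#' @export
align_and_average <- function(rates, labels = NULL, min_trials = 1L) {
  stopifnot(inherits(rates, "rate_tensor"))
  tr <- rates$trials
  tr$label <- NA_character_
  if (!is.null(labels)) {
    m <- match(tr$trial_id, labels$trial_id)
    tr$label <- labels$label[m]
  }
  grp_key <- ifelse(tr$is_jump,
                    paste0(tr$condition_id, "/", tr$label),
                    tr$condition_id)
  usable <- !tr$is_jump | !is.na(tr$label)
  if (!is.null(labels) && any(!usable)) {
    warn(paste0(sum(!usable), " jump trial(s) without direction label dropped",
                " from averaging"))
  }
  if (is.null(labels)) usable <- usable & !tr$is_jump
  keys <- sort(unique(grp_key[usable]))
  n_units <- dim(rates$values)[1]
  n_t <- dim(rates$values)[2]
  vals <- array(NA_real_, dim = c(n_units, n_t, length(keys)))
  info <- vector("list", length(keys))
  for (g in seq_along(keys)) {
    idx <- which(usable & grp_key == keys[g])
    flat <- matrix(rates$values[, , idx, drop = FALSE], n_units * n_t,
                   length(idx))
    vals[, , g] <- matrix(rowMeans(flat, na.rm = TRUE), n_units, n_t)
    info[[g]] <- tibble::tibble(
      group_id = keys[g],
      condition_id = tr$condition_id[idx[1]],
      is_jump = tr$is_jump[idx[1]],
      label = tr$label[idx[1]],
      n_trials = length(idx)
    )
  }
  info <- dplyr::bind_rows(info)
  small <- info$n_trials < min_trials
  if (any(small)) {
    warn(paste0("omitting ", sum(small), " group(s) with < ", min_trials,
                " trials: ", paste(info$group_id[small], collapse = ", ")))
    vals <- vals[, , !small, drop = FALSE]
    info <- info[!small, ]
  }
  structure(list(values = vals, time = rates$time,
                 alignment = rates$alignment, groups = info,
                 normalization = rates$normalization),
            class = "condition_average")
}

#' @export
print.condition_average <- function(x, ...) {
  d <- dim(x$values)
  cat("<condition_average> ", d[1], " units x ", d[2], " timepoints x ",
      d[3], " groups, aligned to ", x$alignment, "\n", sep = "")
  invisible(x)
}

#' Split a rate tensor into two balanced trial halves
#'
#' Seeded split of the trials into two disjoint halves, balanced within
#' each condition (and jump status), for cross-validated estimators:
#' averaging each half separately gives two replicates whose noise is
#' independent.
#'
#' @param rates A `rate_tensor`.
#' @param seed Seed for the within-condition shuffle.
#' @return List of two `rate_tensor`s with disjoint trials.
#' @export
halve_trials <- function(rates, seed = 1L) {
  stopifnot(inherits(rates, "rate_tensor"))
  tr <- rates$trials
  grp <- paste0(tr$condition_id, "/", tr$is_jump)
  half <- integer(nrow(tr))
  local_seed(derive_seed(seed, "halve_trials"), {
    for (g in unique(grp)) {
      idx <- sample(which(grp == g))
      half[idx] <- rep_len(1:2, length(idx))
    }
  })
  subset_tensor <- function(keep) {
    out <- rates
    out$values <- rates$values[, , keep, drop = FALSE]
    out$trials <- tr[keep, ]
    out
  }
  list(subset_tensor(half == 1L), subset_tensor(half == 2L))
}

#' Tidy a rate tensor or condition average into long format
#'
#' @param x A `rate_tensor` or `condition_average`.
#' @param ... Unused.
#' @return A long tibble (`unit_id`, `time`, trial or group id, `rate`).
#' @export
tidy.rate_tensor <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    unit_id = rep(x$unit_ids, times = d[2] * d[3]),
    time = rep(rep(x$time, each = d[1]), times = d[3]),
    trial_id = rep(x$trials$trial_id, each = d[1] * d[2]),
    rate = as.vector(x$values)
  )
}

#' @rdname tidy.rate_tensor
#' @export
tidy.condition_average <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    unit_id = rep(seq_len(d[1]), times = d[2] * d[3]),
    time = rep(rep(x$time, each = d[1]), times = d[3]),
    group_id = rep(x$groups$group_id, each = d[1] * d[2]),
    rate = as.vector(x$values)
  )
}
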