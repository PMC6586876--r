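#' Build a reach session container
#'
#' A session bundles simultaneously recorded units and the trials of one
#' recording day: per-unit spike times (trial-relative, seconds), per-trial
#' task events (target onset, go cue, optional target jump), target
#' coordinates (cm, origin at the central hold target) and 2D hand
#' trajectories. All analyses in the package operate on one session at a
#' time, mirroring the per-day structure of simultaneous recordings.
#'
#' @param units Tibble with columns `unit_id` (character), `region` (one of
#'   `"M1"`, `"PMd"`, `"unknown"`) and `spikes`, a list column holding, per
#'   unit, a list with one ascending numeric vector of spike times per trial.
#' @param trials Tibble with columns `trial_id`, `condition_id`, `is_jump`,
#'   `target_on_time`, `go_cue_time`, `jump_time` (`NA` on non-jump trials),
#'   `first_target_x/y`, `final_target_x/y`, `move_onset_time` (`NA` allowed;
#'   computable with [detect_movement_onset()]), optional logical `valid`,
#'   and `kinematics`, a list column of T x 3 matrices (`time`, `x`, `y`).
#' @param meta List of session metadata; `session_id`, `rate_step` (s) and
#'   `kernel_sd` (s) are filled with defaults when missing.
#'
#' @return An object of class `reach_session`.
#' @export
reach_session <- function(units, trials, meta = list()) {
  units <- tibble::as_tibble(units)
  trials <- tibble::as_tibble(trials)
  if (!"valid" %in% names(trials)) trials$valid <- TRUE
  meta$session_id <- meta$session_id %||% "session"
  meta$rate_step <- meta$rate_step %||% 0.010
  meta$kernel_sd <- meta$kernel_sd %||% 0.030
  s <- structure(list(units = units, trials = trials, meta = meta),
                 class = "reach_session")
  validate_session(s)
  s
}

#' Validate a reach session
#'
#' Checks the structural invariants of the container: one spike array per
#' trial per unit, ascending spike times, ordered task events
#' (`target_on < go_cue`, and on jump trials `go_cue <= jump < move_onset`
#' when onset is known), distinct first/final targets on jump trials only,
#' and time-ordered hand samples.
#'
#' @param session A `reach_session`.
#' @return `session`, invisibly. Errors describe the offending field,
#'   unit or trial.
#' @export
validate_session <- function(session) {
  if (!inherits(session, "reach_session")) abort("not a reach_session")
  units <- session$units
  trials <- session$trials
  req_u <- c("unit_id", "region", "spikes")
  req_t <- c("trial_id", "condition_id", "is_jump", "target_on_time",
             "go_cue_time", "jump_time", "first_target_x", "first_target_y",
             "final_target_x", "final_target_y", "move_onset_time",
             "kinematics")
  miss <- setdiff(req_u, names(units))
  if (length(miss)) abort(paste0("schema error: units missing field ", miss[1]))
  miss <- setdiff(req_t, names(trials))
  if (length(miss)) abort(paste0("schema error: trials missing field ", miss[1]))
  if (nrow(trials) < 1L) abort("session must contain at least one trial")
  if (anyDuplicated(units$unit_id)) abort("duplicate unit_id")
  if (anyDuplicated(trials$trial_id)) abort("duplicate trial_id")
  if (!all(units$region %in% c("M1", "PMd", "unknown"))) {
    abort("schema error: region must be M1, PMd or unknown")
  }
  n_tr <- nrow(trials)
  for (i in seq_len(nrow(units))) {
    sp <- units$spikes[[i]]
    if (length(sp) != n_tr) {
      abort(paste0("unit ", units$unit_id[i], " has ", length(sp),
                   " spike arrays for ", n_tr, " trials"))
    }
    for (j in seq_along(sp)) {
      if (is.unsorted(sp[[j]], strictly = FALSE)) {
        abort(paste0("validation error: non-monotone spike array, unit ",
                     units$unit_id[i], ", trial ", trials$trial_id[j]))
      }
    }
  }
  with(trials, {
    if (any(!(target_on_time < go_cue_time))) {
      abort("validation error: target_on_time must precede go_cue_time")
    }
  })
  for (j in seq_len(n_tr)) {
    tr <- trials[j, ]
    same_target <- isTRUE(all.equal(
      c(tr$first_target_x, tr$first_target_y),
      c(tr$final_target_x, tr$final_target_y)
    ))
    if (tr$is_jump) {
      if (is.na(tr$jump_time)) {
        abort(paste0("validation error: jump trial ", tr$trial_id,
                     " lacks jump_time"))
      }
      if (tr$jump_time < tr$go_cue_time) {
        abort(paste0("validation error: jump before go cue on trial ",
                     tr$trial_id))
      }
      if (!is.na(tr$move_onset_time) && tr$jump_time >= tr$move_onset_time) {
        abort(paste0("validation error: jump at/after movement onset on trial ",
                     tr$trial_id, " (flag the trial invalid instead)"))
      }
      if (same_target) {
        abort(paste0("validation error: jump trial ", tr$trial_id,
                     " has identical first/final targets"))
      }
    } else {
      if (!is.na(tr$jump_time)) {
        abort(paste0("validation error: non-jump trial ", tr$trial_id,
                     " carries a jump_time"))
      }
      if (!same_target) {
        abort(paste0("validation error: non-jump trial ", tr$trial_id,
                     " has distinct first/final targets"))
      }
    }
    k <- tr$kinematics[[1]]
    if (!is.null(k) && nrow(k) > 1 && is.unsorted(k[, 1], strictly = TRUE)) {
      abort(paste0("validation error: hand samples not time-ordered, trial ",
                   tr$trial_id))
    }
  }
  invisible(session)
}

#' @export
print.reach_session <- function(x, ...) {
  cat("<reach_session> ", x$meta$session_id, "\n", sep = "")
  cat("  units:  ", nrow(x$units), " (",
      paste(names(table(x$units$region)), table(x$units$region),
            sep = ":", collapse = ", "), ")\n", sep = "")
  cat("  trials: ", nrow(x$trials), " (", sum(x$trials$is_jump),
      " jump), conditions: ",
      length(unique(x$trials$condition_id)), "\n", sep = "")
  invisible(x)
}

#' Write a session bundle to disk
#'
#' Serializes the full session (metadata, units table with ragged spike
#' arrays, trials table, kinematics) to a single JSON file. Doubles are
#' written with 17 significant digits so that `read_session(write_session(s))`
#' reproduces every field exactly, and field ordering is fixed so two writes
#' of the same session are byte-identical.
#'
#' @param session A validated `reach_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  tr <- session$trials
  bundle <- list(
    meta = session$meta,
    units = list(unit_id = session$units$unit_id,
                 region = session$units$region),
    spikes = lapply(session$units$spikes, function(sp) {
      lapply(sp, function(v) as.numeric(v))
    }),
    trials = tr[, setdiff(names(tr), "kinematics")],
    kinematics = lapply(tr$kinematics, function(k) {
      if (is.null(k)) NULL else unclass(as.matrix(k))
    })
  )
  json <- jsonlite::toJSON(bundle, digits = I(17), null = "null",
                           na = "null", auto_unbox = FALSE,
                           matrix = "rowmajor", dataframe = "columns")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(as.character(json)), con)
  invisible(path)
}

#' Read a session bundle
#'
#' Inverse of [write_session()]. The returned session is validated; schema
#' errors name the missing field, and structural violations (non-monotone
#' spike arrays, mis-ordered events) name the unit and trial.
#'
#' @param path Path to a session bundle written by [write_session()].
#' @return A `reach_session`.
#' @export
read_session <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                          simplifyDataFrame = FALSE)
  for (f in c("meta", "units", "spikes", "trials", "kinematics")) {
    if (is.null(b[[f]])) abort(paste0("schema error: bundle missing field ", f))
  }
  trials <- tibble::as_tibble(lapply(b$trials, function(col) {
    if (is.list(col)) unlist(lapply(col, function(v) if (is.null(v)) NA else v))
    else col
  }))
  # all-NA numeric columns parse as logical; restore declared types
  num_cols <- c("target_on_time", "go_cue_time", "jump_time",
                "first_target_x", "first_target_y", "final_target_x",
                "final_target_y", "move_onset_time")
  for (cc in intersect(num_cols, names(trials))) {
    trials[[cc]] <- as.numeric(trials[[cc]])
  }
  for (cc in intersect(c("is_jump", "valid"), names(trials))) {
    trials[[cc]] <- as.logical(trials[[cc]])
  }
  for (cc in intersect(c("trial_id", "condition_id"), names(trials))) {
    trials[[cc]] <- as.character(trials[[cc]])
  }
  kin_raw <- b$kinematics
  if (is.array(kin_raw) && length(dim(kin_raw)) == 3) {
    # uniform trial lengths let the JSON parser collapse the list of
    # T x 3 matrices into one trials x T x 3 array; split it back
    kin_raw <- lapply(seq_len(dim(kin_raw)[1]),
                      function(j) kin_raw[j, , ])
  }
  trials$kinematics <- lapply(kin_raw, function(k) {
    if (is.null(k)) return(NULL)
    m <- if (is.matrix(k)) k else matrix(as.numeric(k), ncol = 3, byrow = TRUE)
    colnames(m) <- c("time", "x", "y")
    m
  })
  units <- tibble::tibble(
    unit_id = as.character(b$units$unit_id),
    region = as.character(b$units$region),
    spikes = lapply(b$spikes, function(sp) {
      if (is.matrix(sp)) {
        # equal per-trial spike counts let the parser collapse the ragged
        # list into a trials x spikes matrix; split it back
        sp <- lapply(seq_len(nrow(sp)), function(j) sp[j, ])
      }
      lapply(sp, as.numeric)
    })
  )
  meta <- b$meta
  meta$session_id <- as.character(meta$session_id)
  meta$rate_step <- as.numeric(meta$rate_step)
  meta$kernel_sd <- as.numeric(meta$kernel_sd)
  reach_session(units, trials, meta)
}

#' Subsample the units of a session
#'
#' Uniformly samples `n_keep` units without replacement, leaving all trial
#' content untouched. Used to match unit counts across recording
#' preparations (e.g. comparing array datasets against smaller acute probe
#' datasets).
#'
#' @param session A `reach_session`.
#' @param n_keep Number of units to retain, between 1 and the unit count.
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @return A `reach_session` with `n_keep` units, in original unit order.
#' @export
subsample_units <- function(session, n_keep, seed = 1L) {
  n <- nrow(session$units)
  if (!is.numeric(n_keep) || n_keep < 1 || n_keep > n) {
    abort(paste0("n_keep must be in [1, ", n, "]"))
  }
  keep <- local_seed(derive_seed(seed, "subsample_units"),
                     sort(sample.int(n, n_keep)))
  session$units <- session$units[keep, ]
  validate_session(session)
  session
}

#' Filter the trials of a session
#'
#' Keeps trials for which `predicate` evaluates to `TRUE`, dropping the
#' matching per-unit spike arrays so the unit/trial correspondence is
#' preserved. Typical uses: all non-jump trials, a single jump condition,
#' trials with a minimum delay period.
#'
#' @param session A `reach_session`.
#' @param predicate Expression on trial columns (tidy evaluation), e.g.
#'   `!is_jump` or `condition_id == "C1"`.
#' @return The filtered `reach_session`.
#' @export
select_trials <- function(session, predicate) {
  keep <- rlang::eval_tidy(rlang::enquo(predicate), data = session$trials)
  keep <- !is.na(keep) & keep
  if (!any(keep)) abort("empty selection: predicate removed all trials")
  session$trials <- session$trials[keep, ]
  session$units$spikes <- lapply(session$units$spikes, function(sp) sp[keep])
  session
}

#' Per-condition trial counts
#'
#' @param session A `reach_session`.
#' @return Tibble with `condition_id`, `is_jump` and `n_trials`.
#' @export
condition_counts <- function(session) {
  dplyr::count(session$trials, .data$condition_id, .data$is_jump,
               name = "n_trials")
}
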