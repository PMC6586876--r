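#' Euclidean distance between two trajectories within a subspace
#'
#' At each timepoint, `||Q' (a(t) - b(t))||`, the distance between two
#' population trajectories after projection onto the subspace spanned by
#' `Q`. Basis-free: any orthonormal basis of the same subspace gives the
#' same distances.
#'
#' @param traj_a,traj_b Matrices (`dims x timepoints`) on a shared aligned
#'   grid.
#' @param Q Orthonormal subspace basis (`dims x d`).
#' @return Numeric vector of distances per timepoint (`NA` where either
#'   trajectory is unobserved).
#' @export
neural_distance <- function(traj_a, traj_b, Q) {
  if (!all(dim(traj_a) == dim(traj_b))) {
    abort("alignment error: trajectory grids differ")
  }
  d <- traj_a - traj_b
  p <- crossprod(Q, d)
  out <- sqrt(colSums(p^2))
  out[apply(is.na(d), 2, any)] <- NA_real_
  out
}

# map jump conditions to the non-jump conditions of their two targets
condition_map <- function(session, tol = 1e-6) {
  tr <- session$trials
  nj <- unique(tr[!tr$is_jump,
                  c("condition_id", "final_target_x", "final_target_y")])
  find_nj <- function(x, y) {
    hit <- which(abs(nj$final_target_x - x) < tol &
                   abs(nj$final_target_y - y) < tol)
    if (length(hit)) nj$condition_id[hit[1]] else NA_character_
  }
  jc <- unique(tr[tr$is_jump, c("condition_id", "first_target_x",
                                "first_target_y", "final_target_x",
                                "final_target_y")])
  if (nrow(jc) == 0) abort("session has no jump conditions")
  out <- vector("list", nrow(jc))
  for (i in seq_len(nrow(jc))) {
    fd <- atan2(jc$first_target_y[i], jc$first_target_x[i]) * 180 / pi
    ld <- atan2(jc$final_target_y[i], jc$final_target_x[i]) * 180 / pi
    out[[i]] <- tibble::tibble(
      condition_id = jc$condition_id[i],
      first_cond = find_nj(jc$first_target_x[i], jc$first_target_y[i]),
      final_cond = find_nj(jc$final_target_x[i], jc$final_target_y[i]),
      jump_angle = abs(wrap_deg(ld - fd))
    )
  }
  dplyr::bind_rows(out)
}

#' Subspace distance traces for every jump condition
#'
#' For each jump condition and alignment, computes the three pairwise
#' distance traces to the non-jump trajectory toward the final target, in
#' both the preparatory and movement subspaces: jump trials initiated
#' toward the first target, jump trials initiated toward the final target,
#' and the non-jump trajectory toward the first target (the scale
#' reference). Jump groups are defined by the behavioural initial-direction
#' label; conditions missing a counterpart non-jump condition or a jump
#' group are skipped with a warning.
#'
#' Because an average over few jump trials is noisier than one over many
#' non-jump trials, Euclidean distances between noisy means carry a
#' trial-count-dependent upward bias. With `match_trials = TRUE` (default)
#' the non-jump-first baseline average of each jump condition is computed
#' from a seeded subsample of non-jump trials matched in count to the
#' jump-initiated-first group, so the jump and baseline distance
#' distributions share the same sampling noise and the rank-sum comparison
#' is calibrated.
#'
#' @param tensors Named list of normalized `rate_tensor` objects, one per
#'   alignment (e.g. `target_on`, `go_cue`, `move_onset`), covering all
#'   trials.
#' @param labels Tibble with `trial_id` and initial-direction `label` for
#'   jump trials (from [jump_behavior()]).
#' @param subspaces A `subspace_pair` with `trigger_basis` (data are
#'   projected into the trigger null space internally).
#' @param session The `reach_session` (for target geometry).
#' @param match_trials Match baseline trial counts to the jump group.
#' @param seed Seed for the matching subsample.
#' @return Tibble: `alignment`, `condition_id`, `jump_angle`, `pair`
#'   (`"jump_first_vs_final"`, `"jump_final_vs_final"`,
#'   `"nonjump_first_vs_final"`), `space` (`"prep"`/`"move"`), `time`,
#'   `distance`, `n_trials_a` (trial count behind the first trajectory of
#'   the pair).
#' @export
jump_distance_panel <- function(tensors, labels, subspaces, session,
                                match_trials = TRUE, seed = 1L) {
  cmap <- condition_map(session)
  w <- trigger_from_basis(subspaces)
  out <- list()
  for (aln in names(tensors)) {
    rt <- tensors[[aln]]
    tr <- rt$trials
    lab <- labels$label[match(tr$trial_id, labels$trial_id)]
    n_units <- dim(rt$values)[1]
    n_t <- dim(rt$values)[2]
    avg_of <- function(idx) {
      if (!length(idx)) return(NULL)
      flat <- matrix(rt$values[, , idx, drop = FALSE], n_units * n_t,
                     length(idx))
      m <- matrix(rowMeans(flat, na.rm = TRUE), n_units, n_t)
      crossprod(subspaces$trigger_basis, m)
    }
    for (i in seq_len(nrow(cmap))) {
      ci <- cmap$condition_id[i]
      if (is.na(cmap$first_cond[i]) || is.na(cmap$final_cond[i])) {
        warn(paste0("skipping ", ci, ": no matching non-jump condition"))
        next
      }
      idx_jf <- which(tr$condition_id == ci & !is.na(lab) & lab == "first")
      idx_jl <- which(tr$condition_id == ci & !is.na(lab) & lab == "final")
      idx_bf <- which(tr$condition_id == cmap$first_cond[i] & !tr$is_jump)
      idx_bl <- which(tr$condition_id == cmap$final_cond[i] & !tr$is_jump)
      if (!length(idx_bf) || !length(idx_bl)) {
        warn(paste0("skipping ", ci, ": non-jump average unavailable"))
        next
      }
      idx_bf_m <- idx_bf
      if (match_trials && length(idx_jf) &&
          length(idx_bf) > length(idx_jf)) {
        idx_bf_m <- local_seed(derive_seed(seed, paste0(aln, ci)),
                               sample(idx_bf, length(idx_jf)))
      }
      b_final <- avg_of(idx_bl)
      pairs <- list(jump_first_vs_final = idx_jf,
                    jump_final_vs_final = idx_jl,
                    nonjump_first_vs_final = idx_bf_m)
      for (pn in names(pairs)) {
        a <- avg_of(pairs[[pn]])
        if (is.null(a)) next
        for (sp_name in c("prep", "move")) {
          Q <- if (sp_name == "prep") subspaces$Q_prep else subspaces$Q_move
          out[[length(out) + 1]] <- tibble::tibble(
            alignment = aln, condition_id = ci,
            jump_angle = cmap$jump_angle[i],
            pair = pn, space = sp_name,
            time = rt$time,
            distance = neural_distance(a, b_final, Q),
            n_trials_a = length(pairs[[pn]]))
        }
      }
    }
  }
  if (!length(out)) abort("dimension error: no distance trace computed")
  dplyr::bind_rows(out)
}

# reconstruct the unit-space trigger vector orthogonal to a stored null basis
trigger_from_basis <- function(subspaces) {
  N <- subspaces$trigger_basis
  if (is.null(N)) abort("subspace pair lacks a trigger basis")
  n <- nrow(N)
  # unit vector orthogonal to all columns of N
  P <- diag(n) - tcrossprod(N)
  v <- P[, which.max(diag(P))]
  v / sqrt(sum(v^2))
}

#' Rank-sum test of the movement-epoch preparatory-space jump response
#'
#' Per jump condition, averages the preparatory-space distance over a
#' window after movement onset (default 0-200 ms) for (i) jump trials
#' initiated toward the first target vs the non-jump final-target
#' trajectory and (ii) the non-jump first-target trajectory vs the
#' non-jump final-target trajectory (the scale of ordinary cross-condition
#' separation). A two-sided Wilcoxon rank-sum test across conditions
#' compares the two distributions; elevation of (i) over (ii) is the
#' signature of preparatory re-engagement after late jumps.
#'
#' @param panel Output of [jump_distance_panel()] (needs the `move_onset`
#'   alignment).
#' @param window Averaging window after movement onset (s).
#' @param min_conditions Minimum jump conditions (default 3).
#' @return Tibble with `statistic` (rank-sum W), `p_value`, `n_jump`,
#'   `n_baseline`, `median_jump`, `median_baseline`, `method`.
#' @export
movement_epoch_distance_test <- function(panel, window = c(0, 0.2),
                                         min_conditions = 3) {
  d <- panel[panel$alignment == "move_onset" & panel$space == "prep" &
               panel$time >= window[1] & panel$time <= window[2], ]
  per_cond <- d |>
    dplyr::group_by(.data$condition_id, .data$pair) |>
    dplyr::summarise(mean_dist = mean(.data$distance, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "mean_dist")
  if (!all(c("jump_first_vs_final", "nonjump_first_vs_final") %in%
             names(per_cond))) {
    abort("test error: required distance pairs missing")
  }
  per_cond <- per_cond[
    is.finite(per_cond$jump_first_vs_final) &
      is.finite(per_cond$nonjump_first_vs_final), ]
  if (nrow(per_cond) < min_conditions) {
    abort(paste0("test error: only ", nrow(per_cond),
                 " jump conditions contribute"))
  }
  x <- per_cond$jump_first_vs_final
  y <- per_cond$nonjump_first_vs_final
  exact <- length(x) <= 25 && length(y) <= 25 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_jump = length(x), n_baseline = length(y),
                 median_jump = stats::median(x),
                 median_baseline = stats::median(y),
                 method = if (exact) "exact" else "normal approximation")
}
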