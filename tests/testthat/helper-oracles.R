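# Independent oracles used across test files.

# Exhaustive grid-search oracle for the two-subspace trace-ratio objective
# in ambient dimension 4 with d_prep = d_move = 1. The feasible set (two
# orthonormal vectors q1 perp q2) is parameterized by 5 angles: q1 by 3
# spherical angles, q2 by 2 angles within an orthonormal basis of q1's
# complement. A full coarse grid is followed by local grid refinement
# (step/3 per level) down to < 0.1 degrees, entirely independent of the
# package's manifold-gradient optimizer.
grid_oracle_dim4 <- function(Cp, Cm, coarse_deg = 18, levels = 7) {
  sp <- max(eigen(Cp, symmetric = TRUE, only.values = TRUE)$values)
  sm <- max(eigen(Cm, symmetric = TRUE, only.values = TRUE)$values)
  q1_of <- function(a, b, c) {
    c(cos(a), sin(a) * cos(b), sin(a) * sin(b) * cos(c),
      sin(a) * sin(b) * sin(c))
  }
  eval_at <- function(par) {
    q1 <- q1_of(par[1], par[2], par[3])
    # orthonormal complement of q1 via Householder reflection
    v <- q1 - c(1, 0, 0, 0)
    H <- if (sum(v^2) < 1e-18) diag(4) else diag(4) -
      2 * tcrossprod(v) / sum(v^2)
    N <- H[, 2:4]
    q2 <- N %*% c(cos(par[4]), sin(par[4]) * cos(par[5]),
                  sin(par[4]) * sin(par[5]))
    0.5 * (sum(q1 * (Cp %*% q1)) / sp + sum(q2 * (Cm %*% q2)) / sm)
  }
  step <- coarse_deg * pi / 180
  g_half <- seq(0, pi, by = step)
  g_full <- seq(0, 2 * pi - step / 2, by = step)
  # coarse stage, vectorized over the two q2 angles for each q1
  de <- as.matrix(expand.grid(d = g_half, e = g_full))
  P <- rbind(cos(de[, 1]), sin(de[, 1]) * cos(de[, 2]),
             sin(de[, 1]) * sin(de[, 2]))
  best <- NULL
  best_f <- -Inf
  for (a in g_half) for (b in g_half) for (cc in g_full) {
    q1 <- q1_of(a, b, cc)
    f1 <- sum(q1 * (Cp %*% q1)) / sp
    v <- q1 - c(1, 0, 0, 0)
    H <- if (sum(v^2) < 1e-18) diag(4) else diag(4) -
      2 * tcrossprod(v) / sum(v^2)
    Q2 <- H[, 2:4] %*% P
    f2 <- colSums(Q2 * (Cm %*% Q2)) / sm
    k <- which.max(f2)
    f <- 0.5 * (f1 + f2[k])
    if (f > best_f) {
      best_f <- f
      best <- c(a, b, cc, de[k, 1], de[k, 2])
    }
  }
  for (lv in seq_len(levels)) {
    step <- step / 3
    offs <- c(-2, -1, 0, 1, 2) * step
    cand <- as.matrix(expand.grid(best[1] + offs, best[2] + offs,
                                  best[3] + offs, best[4] + offs,
                                  best[5] + offs))
    fs <- apply(cand, 1, eval_at)
    k <- which.max(fs)
    if (fs[k] > best_f) {
      best_f <- fs[k]
      best <- cand[k, ]
    }
  }
  best_f
}

# random symmetric PSD matrix
random_psd <- function(n, rank = n) {
  A <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(A) / rank
}

# random orthonormal frame
random_frame <- function(n, d) {
  qr.Q(qr(matrix(rnorm(n * d), n, d)))
}

# tiny deterministic session for structural tests: ring targets, straight
# minimum-jerk-style reaches, hand-built spike trains
toy_session <- function(n_units = 3, n_trials = 4, with_jump = TRUE) {
  mk_kin <- function(onset, tgt, t_end) {
    tt <- seq(0, t_end, by = 0.01)
    prog <- pmin(pmax((tt - onset) / 0.4, 0), 1)
    prog <- prog^2 * (3 - 2 * prog)
    cbind(time = tt, x = tgt[1] * prog, y = tgt[2] * prog)
  }
  trials <- list()
  kin <- list()
  for (j in seq_len(n_trials)) {
    is_j <- with_jump && j == n_trials
    onset <- 1.0 + 0.02 * j
    tgt1 <- if (is_j) c(10, 0) else c(0, 10)
    tgt2 <- if (is_j) c(0, 10) else tgt1
    trials[[j]] <- tibble::tibble(
      trial_id = paste0("t", j),
      condition_id = if (is_j) "J1" else "C1",
      is_jump = is_j,
      target_on_time = 0.3,
      go_cue_time = 0.8,
      jump_time = if (is_j) 0.9 else NA_real_,
      first_target_x = tgt1[1], first_target_y = tgt1[2],
      final_target_x = tgt2[1], final_target_y = tgt2[2],
      move_onset_time = NA_real_)
    kin[[j]] <- mk_kin(onset, tgt2, 1.8)
  }
  trials <- dplyr::bind_rows(trials)
  trials$kinematics <- kin
  units <- tibble::tibble(
    unit_id = paste0("u", seq_len(n_units)),
    region = rep(c("M1", "PMd"), length.out = n_units),
    spikes = lapply(seq_len(n_units), function(i) {
      lapply(seq_len(n_trials), function(j) {
        sort(runif(20 + 5 * i, 0, 1.8))
      })
    })
  )
  reach_session(units, trials, meta = list(session_id = "toy"))
}
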