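#' Number of dimensions needed to explain a variance fraction
#'
#' Applies PCA to the mean-centered epoch data of the condition averages
#' (units x (condition, time) columns within `window`) and returns the
#' smallest dimensionality whose cumulative explained variance is strictly
#' greater than `threshold`. Used with the delay and movement epochs to set
#' the preparatory and movement subspace sizes.
#'
#' @param avg A `condition_average` (non-jump conditions).
#' @param window Epoch window in aligned time (s).
#' @param threshold Variance fraction (default 0.70; "over" is strict).
#' @param center Centering convention, as in [make_epoch_data()].
#' @return Integer dimension count.
#' @export
choose_dims <- function(avg, window, threshold = 0.70,
                        center = c("condition", "pooled")) {
  center <- match.arg(center)
  nj <- which(!avg$groups$is_jump)
  sel_t <- which(avg$time >= window[1] & avg$time <= window[2])
  if (!length(sel_t)) abort("epoch window outside the averaged grid")
  v <- avg$values[, sel_t, nj, drop = FALSE]
  if (anyNA(v)) abort("epoch window contains unobserved (NA) samples")
  if (length(nj) < 2) abort("dimension error: need >= 2 conditions")
  if (center == "condition") {
    v <- v - rep(apply(v, c(1, 2), mean), times = dim(v)[3])
  }
  X <- matrix(v, nrow = dim(v)[1])
  if (ncol(X) < 2) abort("dimension error: need >= 2 (condition, time) columns")
  X <- X - rowMeans(X)
  sv <- svd(X, nu = 0, nv = 0)$d
  ev <- sv^2
  tot <- sum(ev)
  if (tot <= 0) abort("dimension error: no variance in epoch")
  cum <- cumsum(ev) / tot
  d <- which(cum > threshold + 1e-12)[1]
  if (is.na(d)) abort("dimension error: threshold unreachable")
  as.integer(d)
}

# stack the within-window columns of a condition_average into units x (c, t)
epoch_matrix <- function(avg, window, groups = NULL) {
  stopifnot(inherits(avg, "condition_average"))
  sel_t <- which(avg$time >= window[1] & avg$time <= window[2])
  if (!length(sel_t)) abort("epoch window outside the averaged grid")
  sel_g <- groups %||% seq_len(dim(avg$values)[3])
  v <- avg$values[, sel_t, sel_g, drop = FALSE]
  if (anyNA(v)) abort("epoch window contains unobserved (NA) samples")
  matrix(v, nrow = dim(avg$values)[1])
}

#' Project population data into the null space of the trigger dimension
#'
#' Expresses `n`-dimensional population data in an orthonormal basis of the
#' orthogonal complement of the trigger vector, reducing dimensionality by
#' exactly one. The mapping is an isometry on the complement, and
#' reconstruction from (null-space coordinates, trigger coordinate) is
#' lossless: `||x||^2 = ||N' x||^2 + (w . x)^2`.
#'
#' @param x Matrix with `length(w)` rows (columns are samples), or a
#'   `condition_average` whose values are projected group-wise.
#' @param w Unit-norm trigger vector.
#' @return For a matrix: list with `coords` (`(n-1) x cols`) and `basis`
#'   (`n x (n-1)`, orthonormal, orthogonal to `w`). For a
#'   `condition_average`: the projected average with attribute
#'   `trigger_basis`.
#' @export
project_trigger_null <- function(x, w) {
  w <- as.numeric(w)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) abort("argument error: zero trigger vector")
  w <- w / nw
  n <- length(w)
  Qfull <- qr.Q(qr(cbind(w, diag(n)[, -which.max(abs(w))])), complete = FALSE)
  N <- Qfull[, 2:n, drop = FALSE]
  if (inherits(x, "condition_average")) {
    d <- dim(x$values)
    flat <- matrix(x$values, nrow = d[1])
    coords <- crossprod(N, flat)
    x$values <- array(coords, dim = c(n - 1, d[2], d[3]))
    x$trigger_basis <- N
    return(x)
  }
  stopifnot(is.matrix(x), nrow(x) == n)
  list(coords = crossprod(N, x), basis = N)
}

#' Delay- and movement-epoch data matrices and covariances
#'
#' Builds the inputs of the subspace optimization: the non-jump condition
#' averages restricted to the delay epoch (aligned to target onset) and the
#' movement epoch (aligned to movement onset), projected into the trigger
#' null space, row-centered over the (condition, time) columns, with their
#' covariance matrices and singular values.
#'
#' @param avg_delay `condition_average` aligned to `target_on` (non-jump).
#' @param avg_move `condition_average` aligned to `move_onset` (non-jump).
#' @param w Unit-norm trigger vector (length = unit count).
#' @param delay_window,move_window Epoch windows (s), default 0-300 ms.
#' @param center `"condition"` (default) removes the cross-condition mean
#'   at each timepoint, so the covariances describe only
#'   condition-separating structure (any residual condition-invariant
#'   signal, e.g. imperfectly removed initiation activity, would otherwise
#'   claim dimensions); `"pooled"` removes only the overall row mean.
#' @param avg_delay2,avg_move2 Optional second set of condition averages
#'   built from an independent half of the trials. When supplied, each
#'   epoch covariance is estimated by the symmetrized cross-product of the
#'   two half-averages, `C = (X1 X2' + X2 X1') / (2 (cols - 1))`. Because
#'   trial noise is independent between halves, this estimator has no
#'   noise floor: its eigen-structure reflects only the reproducible
#'   (signal) covariance, which substantially sharpens the recovered
#'   subspaces at a given trial budget. The estimator is symmetric but
#'   indefinite; small negative eigenvalues are clipped to zero for the
#'   normalizing singular values. `X_prep`/`X_move` hold the matrices of
#'   the first average set.
#' @return List of class `epoch_data`: `X_prep`, `X_move`, `C_prep`,
#'   `C_move`, `sv_prep`, `sv_move`, `trigger_basis`, windows.
#' @export
make_epoch_data <- function(avg_delay, avg_move, w,
                            delay_window = c(0, 0.3),
                            move_window = c(0, 0.3),
                            center = c("condition", "pooled"),
                            avg_delay2 = NULL, avg_move2 = NULL) {
  center <- match.arg(center)
  epoch_coords <- function(avg, window) {
    nj <- which(!avg$groups$is_jump)
    if (length(nj) < 2) abort("need >= 2 non-jump conditions")
    sel_t <- which(avg$time >= window[1] & avg$time <= window[2])
    if (!length(sel_t)) abort("epoch window outside the averaged grid")
    v <- avg$values[, sel_t, nj, drop = FALSE]
    if (anyNA(v)) abort("epoch window contains unobserved (NA) samples")
    if (center == "condition") {
      v <- v - rep(apply(v, c(1, 2), mean), times = dim(v)[3])
    }
    X <- project_trigger_null(matrix(v, nrow = dim(v)[1]), w)$coords
    X - rowMeans(X)
  }
  cross_cov <- function(X1, X2) {
    (tcrossprod(X1, X2) + tcrossprod(X2, X1)) / (2 * (ncol(X1) - 1))
  }
  Xp <- epoch_coords(avg_delay, delay_window)
  Xm <- epoch_coords(avg_move, move_window)
  if (!is.null(avg_delay2) && !is.null(avg_move2)) {
    Cp <- cross_cov(epoch_coords(avg_delay, delay_window),
                    epoch_coords(avg_delay2, delay_window))
    Cm <- cross_cov(epoch_coords(avg_move, move_window),
                    epoch_coords(avg_move2, move_window))
  } else {
    Cp <- tcrossprod(Xp) / (ncol(Xp) - 1)
    Cm <- tcrossprod(Xm) / (ncol(Xm) - 1)
  }
  sv <- function(C) pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
  pn <- project_trigger_null(diag(length(w)), w)
  structure(list(
    X_prep = Xp, X_move = Xm,
    C_prep = Cp, C_move = Cm,
    sv_prep = sv(Cp),
    sv_move = sv(Cm),
    estimator = if (is.null(avg_delay2)) "sample" else "split_half",
    trigger_basis = pn$basis,
    delay_window = delay_window, move_window = move_window
  ), class = "epoch_data")
}

subspace_objective <- function(Q, Cp, Cm, dp, sp, sm) {
  Qp <- Q[, seq_len(dp), drop = FALSE]
  Qm <- Q[, -seq_len(dp), drop = FALSE]
  0.5 * (sum(Qp * (Cp %*% Qp)) / sp + sum(Qm * (Cm %*% Qm)) / sm)
}

#' Jointly optimize orthogonal preparatory and movement subspaces
#'
#' Maximizes the symmetric trace-ratio objective
#' \deqn{\frac{1}{2}\left(\frac{Tr(Q_{prep}' C_{prep} Q_{prep})}
#'   {\sum_{i=1}^{d_{prep}} \sigma_{prep}(i)} +
#'   \frac{Tr(Q_{move}' C_{move} Q_{move})}
#'   {\sum_{i=1}^{d_{move}} \sigma_{move}(i)}\right)}
#' subject to \eqn{Q_{prep}' Q_{move} = 0} and both bases orthonormal,
#' i.e. over the Stiefel manifold of orthonormal
#' `(d_prep + d_move)`-frames with a fixed block split. Each denominator is
#' the best variance any subspace of that size could capture, so the
#' objective is at most 1, with equality only when each block spans its
#' covariance's top eigenspace. Optimization is projected gradient ascent
#' with QR retraction and backtracking line search (monotone by
#' construction), from `n_starts` deterministic starts (one spectral, the
#' rest seeded random frames); the best is kept.
#'
#' @param epochs An `epoch_data` (or a list with `C_prep`, `C_move`).
#' @param d_prep,d_move Subspace dimensions.
#' @param n_starts Number of starts (default 10).
#' @param seed Seed for the random starts.
#' @param tol Convergence tolerance on the objective (default 1e-9).
#' @param max_iter Iteration cap per start.
#' @return Object of class `subspace_pair`: `Q_prep`, `Q_move` (in the
#'   trigger null space), `objective`, per-term captured-variance ratios
#'   `prep_ratio` / `move_ratio`, `trigger_basis` (for lifting back to unit
#'   space, when present in `epochs`), and per-start convergence info.
#' @export
optimize_subspaces <- function(epochs, d_prep, d_move, n_starts = 10,
                               seed = 1L, tol = 1e-9, max_iter = 2000) {
  Cp <- epochs$C_prep
  Cm <- epochs$C_move
  n <- nrow(Cp)
  if (d_prep + d_move > n) abort("d_prep + d_move exceeds ambient dimension")
  sym_err <- max(abs(Cp - t(Cp)), abs(Cm - t(Cm)))
  if (sym_err > 1e-8) abort("numerical error: covariance not symmetric")
  ep <- eigen(Cp, symmetric = TRUE)
  em <- eigen(Cm, symmetric = TRUE)
  # the split-half cross-product estimator is symmetric but indefinite by
  # construction; only the plain sample covariance must be PSD
  if (!identical(epochs$estimator, "split_half") &&
      (min(ep$values) < -1e-8 * max(abs(ep$values)) ||
         min(em$values) < -1e-8 * max(abs(em$values)))) {
    abort("numerical error: covariance not positive semidefinite")
  }
  sp <- sum(sort(ep$values, decreasing = TRUE)[seq_len(d_prep)])
  sm <- sum(sort(em$values, decreasing = TRUE)[seq_len(d_move)])
  if (sp <= 0 || sm <= 0) abort("numerical error: degenerate covariance")

  ascend <- function(Q0) {
    Q <- Q0
    f <- subspace_objective(Q, Cp, Cm, d_prep, sp, sm)
    alpha <- 1
    for (it in seq_len(max_iter)) {
      G <- cbind(Cp %*% Q[, seq_len(d_prep), drop = FALSE] / sp,
                 Cm %*% Q[, -seq_len(d_prep), drop = FALSE] / sm)
      A <- crossprod(Q, G)
      Gt <- G - Q %*% ((A + t(A)) / 2)
      gn <- sum(Gt^2)
      if (gn < 1e-18) break
      improved <- FALSE
      while (alpha > 1e-14) {
        Q_new <- orthonormalize(Q + alpha * Gt)
        f_new <- subspace_objective(Q_new, Cp, Cm, d_prep, sp, sm)
        if (f_new > f) {
          improved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!improved) break
      delta <- f_new - f
      Q <- Q_new
      f <- f_new
      alpha <- min(alpha * 2, 1e3)
      if (delta < tol) break
    }
    list(Q = Q, objective = f, iterations = it)
  }

  starts <- vector("list", n_starts)
  # spectral start: top eigenvectors, movement block orthogonalized against
  # the preparatory block
  starts[[1]] <- orthonormalize(cbind(
    ep$vectors[, seq_len(d_prep), drop = FALSE],
    em$vectors[, seq_len(d_move), drop = FALSE]))
  if (n_starts > 1) {
    local_seed(derive_seed(seed, "subspace_starts"), {
      for (k in 2:n_starts) {
        starts[[k]] <- orthonormalize(
          matrix(rnorm(n * (d_prep + d_move)), n))
      }
    })
  }
  runs <- lapply(starts, ascend)
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  if (all(!is.finite(objs))) {
    abort("optimization error: no start converged to a finite objective")
  }
  best <- runs[[which.max(objs)]]
  Qp <- best$Q[, seq_len(d_prep), drop = FALSE]
  Qm <- best$Q[, -seq_len(d_prep), drop = FALSE]
  res <- structure(list(
    Q_prep = Qp, Q_move = Qm,
    d_prep = d_prep, d_move = d_move,
    objective = best$objective,
    prep_ratio = sum(Qp * (Cp %*% Qp)) / sp,
    move_ratio = sum(Qm * (Cm %*% Qm)) / sm,
    trigger_basis = epochs$trigger_basis %||% NULL,
    start_objectives = objs,
    iterations = vapply(runs, `[[`, numeric(1), "iterations")
  ), class = "subspace_pair")
  check_subspace_pair(res)
  res
}

check_subspace_pair <- function(x, tol = 1e-8) {
  Q <- cbind(x$Q_prep, x$Q_move)
  err <- max(abs(crossprod(Q) - diag(ncol(Q))))
  if (err > tol) abort("subspace bases lost orthonormality")
  invisible(x)
}

#' @export
print.subspace_pair <- function(x, ...) {
  cat(sprintf(
    "<subspace_pair> d_prep=%d d_move=%d  objective=%.4f (prep %.3f, move %.3f)\n",
    x$d_prep, x$d_move, x$objective, x$prep_ratio, x$move_ratio))
  invisible(x)
}

#' @export
glance.subspace_pair <- function(x, ...) {
  tibble::tibble(objective = x$objective, prep_ratio = x$prep_ratio,
                 move_ratio = x$move_ratio, d_prep = x$d_prep,
                 d_move = x$d_move,
                 n_starts = length(x$start_objectives))
}

#' Lift a null-space basis back to unit space
#'
#' @param subspaces A `subspace_pair` with `trigger_basis` set.
#' @param which `"prep"` or `"move"`.
#' @return `n_units x d` basis in (normalized-rate) unit space.
#' @export
lift_to_unit_space <- function(subspaces, which = c("prep", "move")) {
  which <- match.arg(which)
  if (is.null(subspaces$trigger_basis)) abort("no trigger basis stored")
  subspaces$trigger_basis %*%
    (if (which == "prep") subspaces$Q_prep else subspaces$Q_move)
}

#' Principal angles between two subspaces
#'
#' Canonical angles between the column spans of `A` and `B` via the
#' singular values of the product of their orthonormalized bases; 0 means
#' identical subspaces, 90 means orthogonal directions.
#'
#' @param A,B Matrices whose columns span the subspaces.
#' @return Angles in degrees, ascending, length `min(ncol(A), ncol(B))`.
#' @export
principal_angles <- function(A, B) {
  qa <- orthonormalize(as.matrix(A))
  qb <- orthonormalize(as.matrix(B))
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  sort(acos(pmin(pmax(s, -1), 1)) * 180 / pi)
}

#' Cross-condition variance time course within subspaces
#'
#' At each timepoint, the variance across condition means is computed for
#' each dimension of a subspace and summed over its dimensions; the
#' normalized variant divides by the total cross-condition variance over
#' the full ambient space at that timepoint. High preparatory share during
#' the delay and high movement share during movement is the signature of
#' the epoch separation.
#'
#' @param avg A `condition_average` in the same space as the bases
#'   (project with [project_trigger_null()] first when the subspaces live
#'   in the trigger null space). Only non-jump groups are used.
#' @param subspaces A `subspace_pair`.
#' @return Tibble with `time`, `var_prep`, `var_move`, `var_total`,
#'   `share_prep`, `share_move`.
#' @export
cross_condition_variance <- function(avg, subspaces) {
  nj <- which(!avg$groups$is_jump)
  if (length(nj) < 2) abort("variance undefined: < 2 conditions")
  vals <- avg$values[, , nj, drop = FALSE]
  n_t <- dim(vals)[2]
  C <- length(nj)
  Qp <- subspaces$Q_prep
  Qm <- subspaces$Q_move
  out <- matrix(NA_real_, n_t, 3)
  for (ti in seq_len(n_t)) {
    M <- vals[, ti, ]
    if (anyNA(M)) next
    M <- M - rowMeans(M)
    out[ti, 1] <- sum(crossprod(Qp, M)^2) / (C - 1)
    out[ti, 2] <- sum(crossprod(Qm, M)^2) / (C - 1)
    out[ti, 3] <- sum(M^2) / (C - 1)
  }
  tibble::tibble(
    time = avg$time,
    var_prep = out[, 1], var_move = out[, 2], var_total = out[, 3],
    share_prep = out[, 1] / out[, 3],
    share_move = out[, 2] / out[, 3]
  )
}
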