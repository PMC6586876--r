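#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_ribbon labs
#'   facet_wrap facet_grid theme_minimal autoplot
NULL

#' Plot a behavioural sigmoid fit
#'
#' Trial dots (normalized initial reach angle vs jump-to-onset latency)
#' with the fitted logistic curve.
#'
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- tibble::tibble(
    latency_ms = seq(min(object$data$latency_ms),
                     max(object$data$latency_ms), length.out = 200))
  grid$angle <- predict(object, grid$latency_ms)
  ggplot(object$data, aes(x = .data$latency_ms, y = .data$angle)) +
    geom_point(alpha = 0.6) +
    geom_line(data = grid, colour = "red") +
    labs(x = "jump to movement onset (ms)",
         y = "normalized initial reach angle") +
    theme_minimal()
}

#' Plot cross-condition variance time courses
#'
#' @param variance Tibble from [cross_condition_variance()].
#' @param normalized Plot variance shares instead of raw variance.
#' @return A ggplot.
#' @export
plot_variance_trace <- function(variance, normalized = FALSE) {
  cols <- if (normalized) c("share_prep", "share_move") else
    c("var_prep", "var_move")
  long <- tidyr::pivot_longer(variance[, c("time", cols)],
                              dplyr::all_of(cols),
                              names_to = "space", values_to = "value")
  long$space <- sub("^(var|share)_", "", long$space)
  ggplot(long, aes(x = .data$time, y = .data$value,
                   colour = .data$space)) +
    geom_line() +
    labs(x = "time (s)",
         y = if (normalized) "cross-condition variance share" else
           "cross-condition variance") +
    theme_minimal()
}

#' Plot jump-distance traces
#'
#' Mean +/- s.e.m. across jump conditions of the subspace distances to the
#' non-jump final-target trajectory, per alignment, pair and subspace.
#'
#' @param panel Tibble from [jump_distance_panel()].
#' @param alignment Which alignment to show (default `"move_onset"`).
#' @return A ggplot.
#' @export
plot_distance_panel <- function(panel, alignment = "move_onset") {
  d <- panel[panel$alignment == alignment, ] |>
    dplyr::group_by(.data$space, .data$pair, .data$time) |>
    dplyr::summarise(
      mean = mean(.data$distance, na.rm = TRUE),
      sem = stats::sd(.data$distance, na.rm = TRUE) /
        sqrt(sum(is.finite(.data$distance))),
      .groups = "drop")
  ggplot(d, aes(x = .data$time, y = .data$mean, colour = .data$pair,
                fill = .data$pair)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem),
                alpha = 0.2, colour = NA) +
    geom_line() +
    facet_wrap(~space, scales = "free_y") +
    labs(x = paste0("time from ", alignment, " (s)"),
         y = "distance to non-jump final-target trajectory") +
    theme_minimal()
}

#' Plot the trigger-dimension weight profile
#'
#' Absolute weights ordered by magnitude, against the average profile of
#' random unit vectors in the same dimension.
#'
#' @param object A `trigger_model`.
#' @param n_random Random profiles to average for the reference line.
#' @param seed Seed for the reference draws.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trigger_model <- function(object, n_random = 1000, seed = 1L, ...) {
  d <- length(object$w)
  obs <- sort(abs(object$w), decreasing = TRUE)
  ref <- local_seed(derive_seed(seed, "weight_plot"), {
    Z <- matrix(rnorm(n_random * d), n_random, d)
    Z <- abs(Z / sqrt(rowSums(Z^2)))
    colMeans(t(apply(Z, 1, sort, decreasing = TRUE)))
  })
  dd <- tibble::tibble(rank = rep(seq_len(d), 2),
                       weight = c(obs, ref),
                       which = rep(c("trigger dimension", "random"),
                                   each = d))
  ggplot(dd, aes(x = .data$rank, y = .data$weight,
                 colour = .data$which)) +
    geom_line() +
    labs(x = "unit (ordered by |weight|)", y = "|weight|") +
    theme_minimal()
}
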