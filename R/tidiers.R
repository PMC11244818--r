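#' Tidy a simulation session into its spike table
#'
#' @param x A `plastnet_session`.
#' @param ... Unused.
#' @return Tibble `time` (ms), `neuron` (1-based), `type` (`"E"`/`"I"`).
#' @export
tidy.plastnet_session <- function(x, ...) {
  dplyr::mutate(x$spikes,
                type = ifelse(.data$neuron <= x$network$cfg$N_E, "E", "I"))
}

#' One-row summary of a session
#'
#' @inheritParams tidy.plastnet_session
#' @return Tibble: duration, spike counts, mean population rates (spikes/s)
#'   and final `w0`/`w1`.
#' @export
glance.plastnet_session <- function(x, ...) {
  cfg <- x$network$cfg
  dur_s <- (x$t_end - x$t0) / 1000
  nE <- sum(x$spikes$neuron <= cfg$N_E)
  wc <- mean_weights_by_class(x$network)
  tibble::tibble(
    t0 = x$t0, t_end = x$t_end, plasticity = x$plasticity_on,
    n_spikes = nrow(x$spikes),
    rate_E = nE / dur_s / cfg$N_E,
    rate_I = (nrow(x$spikes) - nE) / dur_s / cfg$N_I,
    w0 = wc$w0, w1 = wc$w1)
}

#' @export
tidy.plastnet_rates <- function(x, ...) {
  tibble::tibble(time = rep(x$times, each = nrow(x$rates)),
                 neuron = rep(seq_len(nrow(x$rates)), length(x$times)),
                 rate = as.vector(x$rates))
}

#' Tidy a mean-field rate solution
#'
#' @param x A `plastnet_rate_solution`.
#' @param ... Unused.
#' @return Tibble per population: rate and input moments.
#' @export
tidy.plastnet_rate_solution <- function(x, ...) {
  tibble::tibble(population = names(x$nu), nu = unname(x$nu),
                 mu = x$moments$mu, s = x$moments$s)
}

#' @export
glance.plastnet_rate_solution <- function(x, ...) {
  tibble::tibble(ansatz = x$ansatz, converged = x$converged,
                 residual = x$residual, iterations = x$iterations)
}

#' @export
glance.plastnet_states <- function(x, ...) duration_stats(x)

#' Raster plot of a session with cluster overlaps
#'
#' Excitatory spikes coloured by (first) cluster membership, with the
#' overlap traces of all clusters on top.
#'
#' @param object A `plastnet_session`.
#' @param t_start,t_end Window to draw, ms (default: whole session).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plastnet_session <- function(object, t_start = object$t0,
                                      t_end = object$t_end, ...) {
  cl <- object$network$clusters
  first_cluster <- apply(cl$eta, 2, function(col) {
    w <- which(col == 1L); if (length(w)) w[1] else NA_integer_
  })
  sp <- tidy(object) |>
    dplyr::filter(.data$time >= t_start, .data$time <= t_end,
                  .data$type == "E") |>
    dplyr::mutate(cluster = factor(first_cluster[.data$neuron]))
  ov <- overlap_series(object$spikes, cl, t_start, t_end)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = sp,
                        ggplot2::aes(x = .data$time, y = .data$neuron,
                                     colour = .data$cluster),
                        shape = ".", na.rm = TRUE) +
    ggplot2::geom_line(data = ov,
                       ggplot2::aes(x = .data$time,
                                    y = .data$m * max(sp$neuron),
                                    group = .data$cluster),
                       linewidth = 0.2, alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = "neuron / scaled overlap") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Weight-class trajectories of a session
#'
#' @param object A `plastnet_session`.
#' @param ... Unused.
#' @return A ggplot object with the `w0(t)` and `w1(t)` curves.
#' @export
plot_weight_classes <- function(object, ...) {
  object$class_series |>
    tidyr::pivot_longer(c("w0", "w1"), names_to = "class",
                        values_to = "w") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time / 1000, y = .data$w,
                                 colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean weight (mV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mean-field landscape heat map
#'
#' Active-cluster firing rate over the intra-cluster weight moments, with
#' the forbidden region masked and an optional weight trajectory (e.g. from
#' [weight_moments()]) overlaid.
#'
#' @param object A `plastnet_landscape`.
#' @param trajectory Optional tibble with `mean_w1`, `sd_w1` columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plastnet_landscape <- function(object, trajectory = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$mu, y = .data$sigma)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$active_rate)) +
    ggplot2::geom_tile(data = dplyr::filter(object, .data$forbidden),
                       fill = "firebrick", alpha = 0.5) +
    ggplot2::labs(x = expression(mu ~ "(mV)"), y = expression(sigma ~ "(mV)"),
                  fill = "active rate (spikes/s)") +
    ggplot2::theme_minimal()
  if (!is.null(trajectory))
    p <- p + ggplot2::geom_path(
      data = trajectory,
      ggplot2::aes(x = .data$mean_w1, y = .data$sd_w1),
      colour = "black", linewidth = 0.8)
  p
}

#' Histogram of state durations
#'
#' @param object A `plastnet_states` tibble.
#' @param binwidth Bin width, ms.
#' @param ... Unused.
#' @return A ggplot object (complete segments only).
#' @export
autoplot.plastnet_states <- function(object, binwidth = 50, ...) {
  dplyr::filter(object, .data$complete) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$duration)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey40") +
    ggplot2::labs(x = "state duration (ms)", y = "pdf") +
    ggplot2::theme_minimal()
}
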