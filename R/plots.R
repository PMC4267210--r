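# ggplot2 displays for the result objects

#' Plot a pairing experiment
#'
#' Shows a few example trajectories of the active-switch count together
#' with the run-average and the stationary binomial predictions per phase.
#'
#' @param object A [pairing_experiment()] result.
#' @param n_examples Number of individual runs to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pairing_experiment <- function(object, n_examples = 2, ...) {
  avg <- tidy(object)
  ex <- tidy(object, runs = TRUE)
  ex <- dplyr::filter(ex, .data$run <= n_examples)
  pred <- glance(object)
  pred$event_end <- cumsum(pred$n_events)
  pred$event_start <- pred$event_end - pred$n_events + 1
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$event)) +
    ggplot2::geom_line(data = ex,
                       ggplot2::aes(y = .data$m, group = .data$run),
                       alpha = 0.3, linewidth = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_m), linewidth = 0.8,
                       color = "firebrick") +
    ggplot2::geom_segment(
      data = pred,
      ggplot2::aes(x = .data$event_start, xend = .data$event_end,
                   y = .data$predicted_m, yend = .data$predicted_m),
      linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "plasticity event",
                  y = "active switches m",
                  title = "STDP pairing experiment") +
    ggplot2::ylim(0, object$M) +
    ggplot2::theme_minimal()
}

#' Plot the monitored log-likelihood of a training run
#'
#' @param object A [train_wta()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wta_training <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$time_s, y = .data$loglik)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$loglik - 2 * .data$loglik_se,
                   ymax = .data$loglik + 2 * .data$loglik_se),
      fill = "firebrick", alpha = 0.2) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_point(color = "firebrick") +
    ggplot2::labs(x = "training time (s)",
                  y = "log-likelihood per sample (nats)",
                  title = "Refinement of the implicit generative model") +
    ggplot2::theme_minimal()
}

#' Heatmap of active-switch counts
#'
#' Displays the `K x N` matrix of active-switch counts `m_ki` (the learned
#' likelihood means, up to the factor `1/M`) as neuron-by-input tiles.
#'
#' @param m A `K x N` count matrix, a synapse array, or a network state.
#' @param M Switches per synapse (for the fill limits); inferred when `m`
#'   is a synapse array or network state.
#' @return A ggplot object.
#' @export
plot_weight_counts <- function(m, M = NULL) {
  if (inherits(m, "network_state")) m <- m$synapses
  if (inherits(m, "compound_synapse_array")) {
    M <- m$M
    m <- active_counts(m)
  }
  df <- tibble::tibble(neuron = as.integer(row(m)),
                       input = as.integer(col(m)),
                       m = as.numeric(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$input, y = .data$neuron,
                                        fill = .data$m)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "input", y = "neuron", fill = "m") +
    ggplot2::theme_minimal()
  if (!is.null(M)) {
    p <- p + ggplot2::scale_fill_viridis_c(limits = c(0, M))
  } else {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  p
}

#' Plot the equilibrium encoding curve
#'
#' Shows how the stationary weight fraction encodes the expected input for
#' one or more imbalance values.
#'
#' @param deltas Imbalance values to draw.
#' @return A ggplot object.
#' @export
plot_equilibrium_encoding <- function(deltas = c(0.5, 0, -0.5)) {
  y <- seq(0, 1, length.out = 201)
  df <- dplyr::bind_rows(lapply(deltas, function(d) {
    tibble::tibble(y_bar = y, delta = d,
                   weight_fraction = equilibrium_encoding(y, d))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y_bar,
                                   y = .data$weight_fraction,
                                   color = factor(.data$delta))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "expected input", y = "W / Wmax",
                  color = "delta") +
    ggplot2::theme_minimal()
}
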