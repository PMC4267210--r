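# broom-style tidiers for the result objects

#' Tidy a pairing experiment into the run-average trajectory
#'
#' @param x A [pairing_experiment()] result.
#' @param runs If `TRUE`, return one row per (event, run) instead of the
#'   run-average.
#' @param ... Unused.
#' @return A tibble: `event`, `q`, and `mean_m` (or `run`, `m`).
#' @exportS3Method generics::tidy
tidy.pairing_experiment <- function(x, runs = FALSE, ...) {
  q_seq <- rep(x$schedule$q, x$schedule$n_events)
  if (runs) {
    out <- tibble::as_tibble(x$m, .name_repair = ~ paste0("run", seq_along(.x)))
    out$event <- seq_len(nrow(x$m))
    out$q <- q_seq
    return(tidyr::pivot_longer(out, dplyr::starts_with("run"),
                               names_to = "run", names_prefix = "run",
                               names_transform = as.integer,
                               values_to = "m"))
  }
  tibble::tibble(event = seq_len(nrow(x$m)), q = q_seq,
                 mean_m = rowMeans(x$m))
}

#' Summarize a pairing experiment
#'
#' One row per schedule phase with the stationary prediction
#' `M * p*` from [stationary_activation_prob()] and the run-average at the
#' end of the phase.
#'
#' @param x A [pairing_experiment()] result.
#' @param ... Unused.
#' @return A tibble: `q`, `n_events`, `predicted_m`, `observed_m`.
#' @exportS3Method generics::glance
glance.pairing_experiment <- function(x, ...) {
  ends <- cumsum(x$schedule$n_events)
  tibble::tibble(
    q = x$schedule$q,
    n_events = x$schedule$n_events,
    predicted_m = x$M * vapply(x$schedule$q, function(q)
      stationary_activation_prob(x$params, q), numeric(1)),
    observed_m = rowMeans(x$m)[ends]
  )
}

#' Tidy a training run into its monitoring history
#'
#' @param x A [train_wta()] result.
#' @param ... Unused.
#' @return The history tibble: `time_s`, `loglik`, `loglik_se`.
#' @exportS3Method generics::tidy
tidy.wta_training <- function(x, ...) {
  x$history
}

#' One-row summary of a training run
#'
#' @param x A [train_wta()] result.
#' @param ... Unused.
#' @return A tibble with the run dimensions, spike count, and initial and
#'   final log-likelihood.
#' @exportS3Method generics::glance
glance.wta_training <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    K = x$config$K, n_inputs = x$config$n_inputs, M = x$config$M,
    train_s = x$config$train_s, n_spikes = x$n_spikes,
    initial_loglik = h$loglik[1], final_loglik = h$loglik[nrow(h)]
  )
}

#' Tidy a prototype set into long format
#'
#' @param x A [make_prototypes()] object.
#' @param ... Unused.
#' @return A tibble: `class`, `input`, `intensity`.
#' @exportS3Method generics::tidy
tidy.prototype_set <- function(x, ...) {
  tibble::tibble(
    class = as.integer(row(x$x)),
    input = as.integer(col(x$x)),
    intensity = as.numeric(x$x)
  )
}

#' Tidy a classification result
#'
#' @param x A [classification_error()] result.
#' @param ... Unused.
#' @return The per-class error tibble.
#' @exportS3Method generics::tidy
tidy.classification_result <- function(x, ...) {
  x$per_class
}
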