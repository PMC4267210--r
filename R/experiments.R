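# Experiment protocols: STDP pairing experiments on a single synapse,
# unsupervised training with log-likelihood monitoring, neuron labeling and
# classification, and parameter-recovery analysis.

#' STDP pairing experiment on a single compound synapse
#'
#' Applies a schedule of plasticity events to one synapse with `M`
#' switches: each event is potentiating (presynaptic pulse present) with
#' the scheduled probability `q` and depressing otherwise. Runs `n_runs`
#' independent repetitions and records the active-switch count after every
#' event. The run-average converges to the stationary binomial mean
#' `M * p*` (see [stationary_activation_prob()]).
#'
#' @param M Switches per synapse.
#' @param params A [switching_params()] object.
#' @param schedule A data frame with columns `q` (LTP probability) and
#'   `n_events`, applied in order. Default: the classic pairing protocol,
#'   5000 events at `q = 0.8` followed by 5000 at `q = 0.2`.
#' @param n_runs Number of independent runs.
#' @param init_m Initial active-switch count.
#' @return An object of class `pairing_experiment` with the
#'   `n_events x n_runs` trajectory matrix `m` and the protocol settings.
#'   Use [tidy()] for the run-average trajectory.
#' @examples
#' set.seed(1)
#' pe <- pairing_experiment(M = 10, params = switching_params(0.01),
#'                          schedule = data.frame(q = 0.8, n_events = 500),
#'                          n_runs = 20)
#' tail(tidy(pe)$mean_m, 1) # near 8
#' @export
pairing_experiment <- function(M = 10, params = switching_params(),
                               schedule = data.frame(q = c(0.8, 0.2),
                                                     n_events = c(5000, 5000)),
                               n_runs = 100, init_m = round(M / 2)) {
  M <- .check_count(M, "M")
  stopifnot(inherits(params, "switching_params"),
            all(c("q", "n_events") %in% names(schedule)))
  n_runs <- .check_count(n_runs, "n_runs")
  init_m <- .check_count(init_m, "init_m", min = 0L)
  stopifnot(init_m <= M)
  total <- sum(schedule$n_events)
  q_seq <- rep(schedule$q, schedule$n_events)
  traj <- matrix(0L, total, n_runs)
  m <- rep(init_m, n_runs)
  pu <- params$pi_up; pd <- params$pi_down
  for (t in seq_len(total)) {
    ltp <- runif(n_runs) < q_seq[t]
    up <- rbinom(n_runs, M - m, pu)
    dn <- rbinom(n_runs, m, pd)
    m <- m + ifelse(ltp, up, -dn)
    traj[t, ] <- m
  }
  structure(list(m = traj, schedule = tibble::as_tibble(schedule),
                 M = M, params = params, n_runs = n_runs, init_m = init_m),
            class = "pairing_experiment")
}

#' Configuration of a network learning experiment
#'
#' Bundles all parameters of an unsupervised learning run. Defaults follow
#' the reference simulation conditions (1 ms steps, 10 ms pulses, 100 Hz
#' network rate, M = 10 switches of weight 0.1, switching probabilities
#' 1e-3, uniform target activation, homeostatic rate 20x the synaptic
#' learning rate, a new pattern every 100 ms) at desk scale: 100 inputs,
#' 5 synthetic prototype classes, 500 s of training.
#'
#' @param K Network neurons.
#' @param n_inputs,n_classes,on_fraction,off_level,on_level Synthetic
#'   pattern generator settings, see [make_prototypes()].
#' @param M,omega,pi_up,pi_down,noise,init_active_frac Synapse settings,
#'   see [build_synapse_array()].
#' @param r_net,dt,tau Network rate (Hz) and time constants (ms).
#' @param eta_b Homeostatic learning rate; default `20 * pi_up * omega * M`.
#' @param target Homeostatic target activations (default uniform).
#' @param train_s Training duration in seconds.
#' @param presentation_ms Pattern presentation duration in ms.
#' @param monitor_s Monitoring interval in seconds.
#' @param n_loglik_samples Size of the fixed snapshot dataset used for the
#'   log-likelihood estimate.
#' @param label_presentations,test_presentations Presentations per class
#'   used for labeling and for classification.
#' @param eval_present_ms Presentation duration during evaluation in ms.
#' @param seed Seed used by [run_experiment()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(K = 10, n_inputs = 100, n_classes = 5,
                              on_fraction = 0.3, off_level = 0.05,
                              on_level = 0.9,
                              M = 10, omega = 0.1, pi_up = 1e-3,
                              pi_down = 1e-3, noise = device_noise(),
                              init_active_frac = 0.5,
                              r_net = 100, dt = 1, tau = 10,
                              eta_b = NULL, target = NULL,
                              train_s = 500, presentation_ms = 100,
                              monitor_s = 100, n_loglik_samples = 5000,
                              label_presentations = 20,
                              test_presentations = 100,
                              eval_present_ms = 500, seed = 1L) {
  if (is.null(eta_b)) eta_b <- 20 * pi_up * omega * M
  if (is.null(target)) target <- rep(1 / K, K)
  cfg <- list(K = K, n_inputs = n_inputs, n_classes = n_classes,
              on_fraction = on_fraction, off_level = off_level,
              on_level = on_level, M = M, omega = omega, pi_up = pi_up,
              pi_down = pi_down, noise = noise,
              init_active_frac = init_active_frac, r_net = r_net, dt = dt,
              tau = tau, eta_b = eta_b, target = target, train_s = train_s,
              presentation_ms = presentation_ms, monitor_s = monitor_s,
              n_loglik_samples = n_loglik_samples,
              label_presentations = label_presentations,
              test_presentations = test_presentations,
              eval_present_ms = eval_present_ms, seed = seed)
  class(cfg) <- "experiment_config"
  # delegate validation to the constructors
  invisible(network_params(K, n_inputs, r_net, dt, tau, target, eta_b))
  stopifnot(train_s > 0, monitor_s > 0, presentation_ms >= dt)
  cfg
}

.cfg_network_params <- function(cfg) {
  network_params(cfg$K, cfg$n_inputs, cfg$r_net, cfg$dt, cfg$tau,
                 cfg$target, cfg$eta_b)
}

.cfg_synapses <- function(cfg) {
  build_synapse_array(cfg$K, cfg$n_inputs, cfg$M, cfg$omega,
                      switching_params(cfg$pi_up, cfg$pi_down),
                      cfg$noise, cfg$init_active_frac)
}

#' Unsupervised training of the winner-take-all network
#'
#' Runs the full online learning loop: a continuous Poisson-encoded stream
#' of prototype presentations drives the network; every network spike
#' triggers compound-synapse plasticity for the winner and every step
#' applies the homeostatic drift. At `monitor_s` intervals the
#' log-likelihood of a fixed snapshot dataset under the current implicit
#' generative model is recorded, together with a weight-matrix snapshot.
#' Fully deterministic given the RNG state on entry.
#'
#' @param config An [experiment_config()].
#' @param protos Optional [make_prototypes()] object; generated from the
#'   config when omitted.
#' @return An object of class `wta_training`: final `state`
#'   ([network_state()]), `params`, `config`, `protos`, monitoring
#'   `history` tibble (`time_s`, `loglik`, `loglik_se`), list of `m`
#'   `snapshots`, the total spike count `n_spikes`, and the per-neuron
#'   training spike counts `spike_counts`.
#' @export
train_wta <- function(config, protos = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(protos)) {
    protos <- make_prototypes(config$n_classes, config$n_inputs,
                              config$on_fraction, config$off_level,
                              config$on_level)
  }
  params <- .cfg_network_params(config)
  arr <- .cfg_synapses(config)
  snap <- snapshot_dataset(protos, config$n_loglik_samples, config$dt,
                           config$tau)
  total_ms <- config$train_s * 1000
  stream <- sample_stream(protos, total_ms, config$presentation_ms)
  present_steps <- as.integer(round(config$presentation_ms / config$dt))
  monitor_steps <- as.integer(round(config$monitor_s * 1000 / config$dt))
  res <- .engine(arr, numeric(config$K), params, protos, stream$class,
                 present_steps, freeze = FALSE,
                 monitor_steps = monitor_steps, monitor_Y = snap$y)
  structure(list(
    state = network_state(res$arr, res$b, res$t_ms),
    params = params, config = config, protos = protos,
    history = res$history, snapshots = res$snapshots,
    n_spikes = res$n_spikes, spike_counts = res$spike_counts
  ), class = "wta_training")
}

#' Spike counts of a frozen network over a presentation stream
#'
#' Presents `protos$x[classes[slot], ]` for each slot with plasticity and
#' homeostasis frozen, and returns how often each neuron spiked per
#' presentation. This is the measurement primitive behind
#' [label_neurons()] and [classification_error()].
#'
#' @param state A [network_state()].
#' @param params A [network_params()].
#' @param protos A [make_prototypes()] object (rows may also be individual
#'   images rather than class prototypes).
#' @param classes Integer vector of row indices into `protos$x`, one per
#'   presentation slot.
#' @param present_ms Presentation duration in ms.
#' @return An integer `length(classes) x K` matrix of spike counts.
#' @export
evaluate_spike_counts <- function(state, params, protos, classes,
                                  present_ms) {
  stopifnot(inherits(state, "network_state"),
            inherits(params, "network_params"))
  present_steps <- as.integer(round(present_ms / params$dt))
  res <- .engine(state$synapses, state$b, params, protos, classes,
                 present_steps, freeze = TRUE, record_counts = TRUE,
                 t0_ms = state$t_ms)
  res$counts
}

.evaluate_counts <- evaluate_spike_counts

# argmax with seeded uniform tie-breaking
.argmax_tiebreak <- function(x) {
  mx <- max(x)
  idx <- which(x == mx)
  if (length(idx) == 1L) return(idx)
  idx[.sample_winner(rep(1, length(idx)))]
}

#' Label network neurons by their preferred class
#'
#' Presents each class repeatedly with frozen plasticity and labels every
#' neuron with the class it spiked most for. Ties are broken by a seeded
#' uniform choice (recorded in the `tied` column); neurons that never spike
#' remain unlabeled (`NA`).
#'
#' @param training A [train_wta()] result (or a list with `state`,
#'   `params`, `protos`).
#' @param presentations_per_class Number of presentations per class.
#' @param present_ms Presentation duration in ms.
#' @return A tibble with columns `neuron`, `label`, `n_spikes`, `tied`;
#'   the full `K x n_classes` spike-count matrix is attached as attribute
#'   `"counts"`.
#' @export
label_neurons <- function(training, presentations_per_class = NULL,
                          present_ms = NULL) {
  cfg <- training$config
  if (is.null(presentations_per_class)) {
    presentations_per_class <- cfg$label_presentations
  }
  if (is.null(present_ms)) present_ms <- cfg$eval_present_ms
  protos <- training$protos
  K <- training$params$K
  counts <- matrix(0L, K, protos$n_classes)
  for (cl in seq_len(protos$n_classes)) {
    cc <- .evaluate_counts(training$state, training$params, protos,
                           rep(cl, presentations_per_class), present_ms)
    counts[, cl] <- colSums(cc)
  }
  label <- integer(K)
  tied <- logical(K)
  for (k in seq_len(K)) {
    if (sum(counts[k, ]) == 0L) {
      label[k] <- NA_integer_
    } else {
      tied[k] <- sum(counts[k, ] == max(counts[k, ])) > 1L
      label[k] <- .argmax_tiebreak(counts[k, ])
    }
  }
  out <- tibble::tibble(neuron = seq_len(K), label = label,
                        n_spikes = rowSums(counts), tied = tied)
  attr(out, "counts") <- counts
  out
}

#' Classification error of a labeled network
#'
#' Presents test patterns with frozen plasticity; each presentation is
#' classified as the label of the neuron that spiked most during the
#' presentation (ties broken by a seeded uniform choice). Presentations
#' with no network spike, or won by an unlabeled neuron, count as errors.
#'
#' @param training A [train_wta()] result.
#' @param labels A labeling from [label_neurons()].
#' @param presentations_per_class Test presentations per class.
#' @param present_ms Presentation duration in ms.
#' @param protos Optional test prototype set (defaults to the training
#'   prototypes).
#' @return A list of class `classification_result` with `error` (fraction
#'   wrong), `n`, and a `per_class` tibble.
#' @export
classification_error <- function(training, labels,
                                 presentations_per_class = NULL,
                                 present_ms = NULL, protos = NULL) {
  cfg <- training$config
  if (is.null(presentations_per_class)) {
    presentations_per_class <- cfg$test_presentations
  }
  if (is.null(present_ms)) present_ms <- cfg$eval_present_ms
  if (is.null(protos)) protos <- training$protos
  lab <- labels$label
  n_classes <- protos$n_classes
  wrong <- integer(n_classes)
  for (cl in seq_len(n_classes)) {
    cc <- .evaluate_counts(training$state, training$params, protos,
                           rep(cl, presentations_per_class), present_ms)
    for (s in seq_len(nrow(cc))) {
      if (sum(cc[s, ]) == 0L) {
        wrong[cl] <- wrong[cl] + 1L
      } else {
        pred <- lab[.argmax_tiebreak(cc[s, ])]
        if (is.na(pred) || pred != cl) wrong[cl] <- wrong[cl] + 1L
      }
    }
  }
  n <- n_classes * presentations_per_class
  structure(list(
    error = sum(wrong) / n, n = n,
    per_class = tibble::tibble(class = seq_len(n_classes),
                               n = presentations_per_class, wrong = wrong,
                               error = wrong / presentations_per_class)
  ), class = "classification_result")
}

#' Parameter recovery of the learned generative model
#'
#' Compares each labeled neuron's learned likelihood means `mu_ki = m_ki/M`
#' against its prototype's intensities (mapped through
#' [equilibrium_encoding()] when the switching probabilities are
#' systematically unbalanced) and reports the fraction of channels within
#' a tolerance.
#'
#' @param training A [train_wta()] result.
#' @param labels A labeling from [label_neurons()].
#' @param tolerance Per-channel absolute tolerance on `mu`.
#' @param delta Imbalance used to transform the prototype intensities
#'   (default taken from the training config's noise spec).
#' @return A tibble with one row per labeled neuron: `neuron`, `label`,
#'   `frac_within` and `max_abs_dev`.
#' @export
parameter_recovery <- function(training, labels, tolerance = 0.1,
                               delta = NULL) {
  cfg <- training$config
  if (is.null(delta)) {
    delta <- if (cfg$noise$mode == "systematic_imbalance")
      cfg$noise$delta else 0
  }
  mu <- active_counts(training$state$synapses) / cfg$M
  keep <- which(!is.na(labels$label))
  rows <- lapply(keep, function(k) {
    targ <- equilibrium_encoding(training$protos$x[labels$label[k], ], delta)
    dev <- abs(mu[k, ] - targ)
    # 1e-9 guard so e.g. |0.2 - 0.05| <= 0.15 holds in double arithmetic
    tibble::tibble(neuron = k, label = labels$label[k],
                   frac_within = mean(dev <= tolerance + 1e-9),
                   max_abs_dev = max(dev))
  })
  dplyr::bind_rows(rows)
}

#' Run a full experiment and write its artifacts
#'
#' Seeds the RNG from the config, generates prototypes, trains the network,
#' labels the neurons and measures the classification error, then writes
#' `history.csv` (monitoring checkpoints), `weights.csv` (final active
#' counts `m_ki` in long format), `labels.csv` and `summary.json` into
#' `out_dir`. Identical configs produce byte-identical summaries.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  training <- train_wta(config)
  labels <- label_neurons(training)
  cls <- classification_error(training, labels)

  write.csv(training$history, file.path(out_dir, "history.csv"),
            row.names = FALSE)
  m <- active_counts(training$state$synapses)
  long <- tibble::tibble(neuron = as.integer(row(m)),
                         input = as.integer(col(m)),
                         m = as.integer(m))
  write.csv(long, file.path(out_dir, "weights.csv"), row.names = FALSE)
  write.csv(labels[, c("neuron", "label", "n_spikes", "tied")],
            file.path(out_dir, "labels.csv"), row.names = FALSE)

  summary <- list(
    seed = config$seed,
    K = config$K, n_inputs = config$n_inputs, M = config$M,
    noise_mode = config$noise$mode,
    train_s = config$train_s,
    n_spikes = training$n_spikes,
    final_loglik = training$history$loglik[nrow(training$history)],
    classification_error = cls$error,
    labels = labels$label
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Sweep experiment conditions
#'
#' Convenience wrappers that rerun the training + evaluation pipeline under
#' varied conditions, reseeding identically per condition so conditions
#' differ only in the parameter under study. `sweep_resolution()` varies
#' the number of switches `M` at fixed maximum weight `W_max = omega * M`;
#' `sweep_noise()` varies the conductance-noise mode at a given noise
#' level; `sweep_delta()` varies the systematic switching imbalance.
#'
#' @param config Base [experiment_config()].
#' @param M_values Switch counts for the resolution sweep.
#' @param modes Noise modes for the noise sweep.
#' @param omega_sd Conductance noise level for the noise sweep.
#' @param deltas Imbalance values for the delta sweep.
#' @return A tibble with one row per condition: the condition value,
#'   `error` (classification error) and `final_loglik`.
#' @export
sweep_resolution <- function(config, M_values = c(1, 2, 4, 10, 100)) {
  w_max <- config$omega * config$M
  rows <- lapply(M_values, function(M) {
    cfg <- config
    cfg$M <- as.integer(M)
    cfg$omega <- w_max / M
    res <- .sweep_run(cfg)
    tibble::tibble(M = M, error = res$error,
                   final_loglik = res$final_loglik)
  })
  dplyr::bind_rows(rows)
}

#' @rdname sweep_resolution
#' @export
sweep_noise <- function(config,
                        modes = c("none", "spatial", "temporal",
                                  "spatial_temporal"),
                        omega_sd = 0.5 * config$omega) {
  rows <- lapply(modes, function(mode) {
    cfg <- config
    cfg$noise <- if (mode == "none") device_noise() else
      device_noise(mode, omega_sd = omega_sd)
    res <- .sweep_run(cfg)
    tibble::tibble(mode = mode, error = res$error,
                   final_loglik = res$final_loglik)
  })
  dplyr::bind_rows(rows)
}

#' @rdname sweep_resolution
#' @export
sweep_delta <- function(config, deltas = c(0.5, 0, -0.5)) {
  rows <- lapply(deltas, function(d) {
    cfg <- config
    cfg$noise <- if (d == 0) device_noise() else
      device_noise("systematic_imbalance", delta = d)
    res <- .sweep_run(cfg)
    tibble::tibble(delta = d, error = res$error,
                   final_loglik = res$final_loglik,
                   mean_active_fraction = res$mean_active_fraction)
  })
  dplyr::bind_rows(rows)
}

.sweep_run <- function(cfg) {
  set.seed(cfg$seed)
  training <- train_wta(cfg)
  labels <- label_neurons(training)
  cls <- classification_error(training, labels)
  list(error = cls$error,
       final_loglik = training$history$loglik[nrow(training$history)],
       mean_active_fraction =
         mean(active_counts(training$state$synapses)) / cfg$M,
       training = training, labels = labels)
}

#' @export
print.wta_training <- function(x, ...) {
  cat(sprintf("<wta_training> %g s trained, %d network spikes\n",
              x$config$train_s, x$n_spikes))
  cat(sprintf("  log-likelihood: %.2f -> %.2f (per sample)\n",
              x$history$loglik[1], x$history$loglik[nrow(x$history)]))
  invisible(x)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> error %.3f on %d presentations\n",
              x$error, x$n))
  invisible(x)
}

#' @export
print.pairing_experiment <- function(x, ...) {
  cat(sprintf(
    "<pairing_experiment> M=%d, %d events x %d runs, init m=%d\n",
    x$M, nrow(x$m), x$n_runs, x$init_m))
  invisible(x)
}
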