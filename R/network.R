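# Stochastic winner-take-all spiking network. Neurons integrate binary input
# pulses linearly, compete through softmax lateral inhibition, and spike as a
# Poisson process of constant total rate r_net whose winner marginal is the
# softmax of the membrane potentials.

#' Parameters of the winner-take-all network
#'
#' @param K,N Number of network neurons and inputs.
#' @param r_net Total network firing rate in Hz. The sum of instantaneous
#'   rates over neurons equals `r_net` identically, so the network spikes as
#'   a Poisson process of rate `r_net`.
#' @param dt Simulation time step in ms.
#' @param tau Presynaptic pulse duration in ms (must be >= `dt`).
#' @param target Homeostatic target activation vector `c_k` (length `K`,
#'   sums to 1). Default uniform `1/K`.
#' @param eta_b Homeostatic learning rate for the intrinsic excitabilities.
#'   By convention set to 20 times the synaptic learning rate
#'   `eta_W = pi_up * W_max`; the default 0.02 corresponds to
#'   `pi_up = 1e-3`, `W_max = 1`.
#' @return An object of class `network_params`.
#' @export
network_params <- function(K, N, r_net = 100, dt = 1, tau = 10,
                           target = rep(1 / K, K), eta_b = 0.02) {
  K <- .check_count(K, "K"); N <- .check_count(N, "N")
  .check_nonneg(r_net, "r_net")
  stopifnot(dt > 0, tau >= dt)
  if (length(target) != K || any(target < 0) ||
      abs(sum(target) - 1) > 1e-8) {
    stop("`target` must be a length-K probability vector summing to 1",
         call. = FALSE)
  }
  .check_nonneg(eta_b, "eta_b")
  structure(list(K = K, N = N, r_net = r_net, dt = dt, tau = tau,
                 target = target, eta_b = eta_b),
            class = "network_params")
}

#' Network state: excitabilities, synapses and clock
#'
#' @param synapses A [build_synapse_array()] object.
#' @param b Intrinsic excitability vector (length `K`), default all zero.
#' @param t_ms Simulation clock in ms.
#' @return An object of class `network_state`.
#' @export
network_state <- function(synapses, b = numeric(synapses$K), t_ms = 0) {
  stopifnot(inherits(synapses, "compound_synapse_array"))
  if (length(b) != synapses$K || any(!is.finite(b))) {
    stop("`b` must be a finite vector of length K", call. = FALSE)
  }
  structure(list(b = as.numeric(b), synapses = synapses,
                 t_ms = as.numeric(t_ms)),
            class = "network_state")
}

#' Membrane potentials given a binary input vector
#'
#' `u_k = b_k + sum_i W_ki * y_i`.
#'
#' @param state A [network_state()].
#' @param y Binary (or logical) input pulse vector of length `N`.
#' @return Numeric vector of length `K`.
#' @export
membrane_potentials <- function(state, y) {
  stopifnot(inherits(state, "network_state"))
  if (length(y) != state$synapses$N) {
    stop("`y` must have length N", call. = FALSE)
  }
  state$b + as.vector(weight_matrix(state$synapses) %*% as.numeric(y))
}

#' Winner distribution of the network given membrane potentials
#'
#' The probability that neuron `k` wins a network spike is the softmax
#' `exp(u_k - u_inh)` with lateral inhibition
#' `u_inh = log(sum_j exp(u_j))`, computed with a max shift for numerical
#' stability. Invariant under adding a constant to all potentials.
#'
#' @param u Membrane potential vector.
#' @return Probability vector summing to 1.
#' @examples
#' response_distribution(c(log(2), 0)) # c(2/3, 1/3)
#' @export
response_distribution <- function(u) {
  if (!is.numeric(u) || length(u) < 1L || any(is.na(u))) {
    stop("`u` must be a numeric vector", call. = FALSE)
  }
  mx <- max(u)
  if (mx == -Inf) stop("all potentials are -Inf", call. = FALSE)
  p <- exp(u - mx)
  p / sum(p)
}

# sample a categorical winner from unnormalized weights, using one uniform
.sample_winner <- function(p_unnorm) {
  r <- runif(1) * sum(p_unnorm)
  acc <- p_unnorm[1L]
  k <- 1L
  while (acc < r && k < length(p_unnorm)) {
    k <- k + 1L
    acc <- acc + p_unnorm[k]
  }
  k
}

#' Sample the network spike response for one time step
#'
#' Each neuron fires Poisson with rate `r_net * softmax_k`; since the rates
#' sum to `r_net`, the network emits at most one spike per step with
#' probability `1 - exp(-r_net * dt / 1000)` and, given a spike, the winner
#' is drawn from [response_distribution()]. RNG order: one uniform for the
#' spike occurrence, then (only if a spike occurs) one uniform for the
#' winner.
#'
#' @param state A [network_state()].
#' @param y Binary input pulse vector.
#' @param params A [network_params()].
#' @return The winner index, or `NA_integer_` if no spike occurred.
#' @export
sample_network_spike <- function(state, y, params) {
  stopifnot(inherits(params, "network_params"))
  u <- membrane_potentials(state, y)
  p_spike <- 1 - exp(-params$r_net * params$dt / 1000)
  if (runif(1) >= p_spike) return(NA_integer_)
  .sample_winner(exp(u - max(u)))
}

#' Homeostatic intrinsic plasticity step
#'
#' Discretizes `db_k/dt = eta_b * (r_net * c_k - s_k(t))`: every step each
#' excitability drifts up by `eta_b * r_net * c_k * dt` (rates in Hz, dt in
#' ms, converted once here), and the winner's excitability drops by `eta_b`
#' at its spike. The fixed point makes each neuron's long-run spike fraction
#' match its target `c_k`.
#'
#' @param state A [network_state()].
#' @param winner Winner index of this step, or `NA` if no spike.
#' @param params A [network_params()].
#' @return The updated state.
#' @export
homeostatic_step <- function(state, winner, params) {
  stopifnot(inherits(state, "network_state"),
            inherits(params, "network_params"))
  state$b <- state$b +
    params$eta_b * (params$r_net / 1000) * params$target * params$dt
  if (!is.na(winner)) {
    state$b[winner] <- state$b[winner] - params$eta_b
  }
  state
}

#' One full network time step
#'
#' Order of operations: (1) membrane potentials from the current input
#' pulses; (2) sample the spike response; (3) if a spike occurred, apply
#' compound-synapse plasticity for the winner with the current pulses as
#' presynaptic activity; (4) homeostatic step; (5) advance the clock by
#' `dt`.
#'
#' @param state A [network_state()].
#' @param y Binary input pulse vector of length `N`.
#' @param params A [network_params()].
#' @param freeze If `TRUE`, skip synaptic and homeostatic plasticity
#'   (evaluation mode); the spike response is still sampled.
#' @return A list with elements `state` and `winner` (`NA_integer_` when no
#'   spike occurred).
#' @export
wta_step <- function(state, y, params, freeze = FALSE) {
  winner <- sample_network_spike(state, y, params)
  if (!freeze) {
    if (!is.na(winner)) {
      state$synapses <- apply_plasticity_event(state$synapses, winner, y)
    }
    state <- homeostatic_step(state, winner, params)
  }
  state$t_ms <- state$t_ms + params$dt
  list(state = state, winner = winner)
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> K=%d neurons, t=%.1f ms\n",
              x$synapses$K, x$t_ms))
  cat("  b:", paste(sprintf("%.3f", utils::head(x$b, 8)), collapse = " "),
      if (length(x$b) > 8) "...\n" else "\n")
  invisible(x)
}
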