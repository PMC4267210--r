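# Compound memristive synapses: M bistable stochastic switches in parallel.
# A synapse (k, i) carries weight W_ki = sum of the conductances of its active
# switches; with uniform conductance omega this is omega * m_ki, where m_ki is
# the number of active switches. Plasticity flips individual switches with
# probabilities pi_up (potentiation) and pi_down (depression).

#' Switching probabilities of a bistable stochastic switch
#'
#' A bistable switch jumps from its inactive to its active state with
#' probability `pi_up` when a potentiating (LTP) pulse pair arrives, and from
#' active to inactive with probability `pi_down` under a depressing (LTD)
#' pulse.
#'
#' @param pi_up,pi_down Switching probabilities in `[0, 1]`.
#' @return An object of class `switching_params`.
#' @examples
#' switching_params(1e-3, 1e-3)
#' @export
switching_params <- function(pi_up = 1e-3, pi_down = pi_up) {
  .check_prob(pi_up, "pi_up")
  .check_prob(pi_down, "pi_down")
  structure(list(pi_up = pi_up, pi_down = pi_down), class = "switching_params")
}

#' Device-noise specification for a synapse array
#'
#' Describes deviations of physical switches from the idealized model:
#' * `"none"`: all switches identical.
#' * `"spatial"`: each switch draws its active-state conductance once from
#'   a normal distribution (device-to-device variability, fixed over time).
#' * `"temporal"`: the conductance is redrawn around the nominal mean on
#'   every potentiating flip (trial-to-trial instability).
#' * `"spatial_temporal"`: both; the device-specific spatial value is the
#'   mean for the temporal redraws.
#' * `"prob_spatial"`: per-switch switching probabilities drawn from normal
#'   distributions with relative standard deviation `prob_noise_level`,
#'   truncated to `[0, 1]`.
#' * `"systematic_imbalance"`: uniform switches, but
#'   `pi_down = pi_up * (1 - delta)` with imbalance
#'   `delta = (pi_up - pi_down) / pi_up`.
#'
#' All truncations use rejection sampling by default (redraw until the value
#' is in range); set `truncation = "clip"` to clamp instead.
#'
#' @param mode Noise mode, see Details.
#' @param omega_sd Standard deviation of the conductance noise (same units as
#'   the conductance weight `omega`).
#' @param prob_noise_level Relative standard deviation for switching
#'   probability noise (e.g. `0.5` for 50% of the mean).
#' @param delta Systematic imbalance `(pi_up - pi_down) / pi_up`; must leave
#'   `pi_down` in `[0, 1]`.
#' @param truncation `"resample"` or `"clip"`.
#' @return An object of class `device_noise`.
#' @examples
#' device_noise("spatial", omega_sd = 0.05)
#' device_noise("systematic_imbalance", delta = -0.5)
#' @export
device_noise <- function(mode = c("none", "spatial", "temporal",
                                  "spatial_temporal", "prob_spatial",
                                  "systematic_imbalance"),
                         omega_sd = 0, prob_noise_level = 0, delta = 0,
                         truncation = c("resample", "clip")) {
  mode <- match.arg(mode)
  truncation <- match.arg(truncation)
  .check_nonneg(omega_sd, "omega_sd")
  .check_nonneg(prob_noise_level, "prob_noise_level")
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta > 1) {
    stop("`delta` must be a finite number <= 1", call. = FALSE)
  }
  if (mode == "none" && omega_sd != 0) {
    stop("`omega_sd` must be 0 when mode = \"none\"", call. = FALSE)
  }
  structure(list(mode = mode, omega_sd = omega_sd,
                 prob_noise_level = prob_noise_level, delta = delta,
                 truncation = truncation),
            class = "device_noise")
}

# truncated-normal draws; `mean` may be a vector
.rtnorm <- function(n, mean, sd, lower = 0, upper = Inf,
                    method = "resample") {
  mean <- rep_len(as.numeric(mean), n)
  if (sd == 0) return(pmin(pmax(mean, lower), upper))
  x <- rnorm(n, mean, sd)
  if (method == "clip") return(pmin(pmax(x, lower), upper))
  bad <- which(x < lower | x > upper)
  iter <- 0L
  while (length(bad) > 0L && iter < 1000L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    iter <- iter + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lower), upper)
  x
}

#' Build an array of compound memristive synapses
#'
#' Creates the `K x N` array of compound synapses connecting `N` inputs to
#' `K` network neurons, each synapse composed of `M` bistable stochastic
#' switches. Every switch is initialized active independently with
#' probability `init_active_frac`. Device noise (if any) is drawn here:
#' spatial conductance values once per switch, per-switch switching
#' probabilities for `"prob_spatial"`, and the systematic imbalance
#' `pi_down = pi_up * (1 - delta)` for `"systematic_imbalance"`.
#'
#' Arrays without per-switch heterogeneity store only the active-switch
#' counts `m_ki` (the counts are a sufficient description when all switches
#' of a synapse are exchangeable); heterogeneous arrays store the full
#' per-switch state. Both representations update through the same switching
#' semantics (see [apply_plasticity_event()]).
#'
#' @param K,N,M Number of network neurons, inputs, and switches per synapse.
#' @param omega Active-state conductance weight of a single switch (nominal
#'   mean when conductance noise is enabled).
#' @param params A [switching_params()] object.
#' @param noise A [device_noise()] object.
#' @param init_active_frac Probability that a switch starts active.
#' @return An object of class `compound_synapse_array`.
#' @examples
#' arr <- build_synapse_array(K = 2, N = 4, M = 10)
#' weight_matrix(arr)
#' @export
build_synapse_array <- function(K, N, M, omega = 0.1,
                                params = switching_params(),
                                noise = device_noise(),
                                init_active_frac = 0.5) {
  K <- .check_count(K, "K"); N <- .check_count(N, "N")
  M <- .check_count(M, "M")
  .check_nonneg(omega, "omega")
  stopifnot(inherits(params, "switching_params"),
            inherits(noise, "device_noise"))
  .check_prob(init_active_frac, "init_active_frac")

  pi_up <- params$pi_up
  pi_down <- params$pi_down
  if (noise$mode == "systematic_imbalance") {
    pi_down <- pi_up * (1 - noise$delta)
    .check_prob(pi_down, "pi_down implied by delta")
  }

  het_w <- noise$mode %in% c("spatial", "temporal", "spatial_temporal")
  het_pi <- noise$mode == "prob_spatial"
  n_sw <- K * N * M

  arr <- structure(list(
    K = K, N = N, M = M, omega = omega,
    pi_up = pi_up, pi_down = pi_down,
    params = params, noise = noise,
    m = NULL, state = NULL, w = NULL, w_device = NULL,
    pi_up_sw = NULL, pi_down_sw = NULL
  ), class = "compound_synapse_array")

  if (!het_w && !het_pi) {
    # homogeneous: counts are a complete description
    arr$m <- matrix(rbinom(K * N, M, init_active_frac), K, N)
    return(arr)
  }

  arr$state <- array(runif(n_sw) < init_active_frac, dim = c(K, N, M))
  arr$m <- rowSums(arr$state, dims = 2L)
  if (het_w) {
    if (noise$mode %in% c("spatial", "spatial_temporal")) {
      dev <- array(.rtnorm(n_sw, omega, noise$omega_sd,
                           method = noise$truncation), dim = c(K, N, M))
      arr$w_device <- dev
      arr$w <- if (noise$mode == "spatial") dev else
        array(.rtnorm(n_sw, dev, noise$omega_sd, method = noise$truncation),
              dim = c(K, N, M))
    } else { # temporal
      arr$w <- array(.rtnorm(n_sw, omega, noise$omega_sd,
                             method = noise$truncation), dim = c(K, N, M))
    }
  }
  if (het_pi) {
    arr$pi_up_sw <- array(.rtnorm(n_sw, pi_up, noise$prob_noise_level * pi_up,
                                  lower = 0, upper = 1,
                                  method = noise$truncation),
                          dim = c(K, N, M))
    arr$pi_down_sw <- array(.rtnorm(n_sw, pi_down,
                                    noise$prob_noise_level * pi_down,
                                    lower = 0, upper = 1,
                                    method = noise$truncation),
                            dim = c(K, N, M))
  }
  arr
}

.is_heterogeneous <- function(arr) !is.null(arr$state)

#' Number of active switches per synapse
#'
#' @param arr A [build_synapse_array()] object.
#' @return An integer `K x N` matrix of counts `m_ki`.
#' @export
active_counts <- function(arr) {
  stopifnot(inherits(arr, "compound_synapse_array"))
  arr$m
}

#' Total weight of one compound synapse
#'
#' The weight is the sum of the conductances of the active switches,
#' `W_ki = sum_j state_kij * omega_kij`; with uniform conductance this is
#' `omega * m_ki`.
#'
#' @param arr A synapse array.
#' @param k,i Postsynaptic neuron index and input index.
#' @return A single weight value.
#' @export
synapse_weight <- function(arr, k, i) {
  stopifnot(inherits(arr, "compound_synapse_array"))
  k <- .check_count(k, "k"); i <- .check_count(i, "i")
  if (k > arr$K || i > arr$N) stop("index out of range", call. = FALSE)
  if (is.null(arr$w)) return(arr$omega * arr$m[k, i])
  sum(arr$w[k, i, ][arr$state[k, i, ]])
}

#' Weight matrix of a synapse array
#'
#' @param arr A synapse array.
#' @return A numeric `K x N` matrix of synaptic weights `W_ki`.
#' @export
weight_matrix <- function(arr) {
  stopifnot(inherits(arr, "compound_synapse_array"))
  if (is.null(arr$w)) return(arr$omega * arr$m)
  rowSums(arr$w * arr$state, dims = 2L)
}

#' Maximum weight of a synapse
#'
#' `W_max = omega * M`, reached when all switches are active.
#'
#' @param arr A synapse array.
#' @return A single number.
#' @export
max_weight <- function(arr) {
  stopifnot(inherits(arr, "compound_synapse_array"))
  arr$omega * arr$M
}

#' Weight resolution of a compound synapse
#'
#' With `M` switches a synapse supports exactly `M + 1` discrete weight
#' levels (0, omega, ..., M * omega), i.e. `log2(M + 1)` bits of weight
#' information.
#'
#' @param M Number of switches per synapse.
#' @return `n_weight_levels()`: integer count of levels;
#'   `weight_information_bits()`: bits.
#' @examples
#' n_weight_levels(4)         # 5 levels
#' weight_information_bits(4) # ~2.32 bits
#' @export
n_weight_levels <- function(M) {
  M <- .check_count(M, "M")
  M + 1L
}

#' @rdname n_weight_levels
#' @export
weight_information_bits <- function(M) {
  log2(n_weight_levels(M))
}

# -- plasticity ---------------------------------------------------------------

# Count path: vectorized over channels. `mi` counts, `act` logical pulse
# vector. Draw injection (`up_draws`/`dn_draws`) exists so tests can feed both
# bookkeeping paths identical per-switch randomness.
.plasticity_counts <- function(mi, act, M, pi_up, pi_down,
                               up_draws = NULL, dn_draws = NULL) {
  n <- length(mi)
  up <- if (is.null(up_draws)) rbinom(n, M - mi, pi_up) else up_draws
  dn <- if (is.null(dn_draws)) rbinom(n, mi, pi_down) else dn_draws
  up[!act] <- 0L
  dn[act] <- 0L
  mi + up - dn
}

# Per-switch path on one postsynaptic row. s_row: N x M logical; act: length-N
# logical; pu/pd: scalar or N x M. Returns the updated row and the LTP flip
# mask (needed for temporal conductance redraws).
.plasticity_perswitch <- function(s_row, act, pu, pd, u = NULL) {
  nm <- length(s_row)
  if (is.null(u)) u <- matrix(runif(nm), nrow(s_row), ncol(s_row))
  flip_up <- (!s_row) & act & (u < pu)
  flip_dn <- s_row & (!act) & (u < pd)
  s_row[flip_up] <- TRUE
  s_row[flip_dn] <- FALSE
  list(state = s_row, flip_up = flip_up)
}

#' Apply one plasticity event to a synapse array
#'
#' A postsynaptic spike of neuron `k` triggers stochastic switching in all
#' its afferent synapses: for inputs with an active presynaptic pulse
#' (`pre_active = 1`) every inactive switch flips active independently with
#' its `pi_up` (potentiation); for silent inputs every active switch flips
#' inactive with its `pi_down` (depression). Under temporal conductance
#' noise, a switch's conductance is redrawn whenever it flips to the active
#' state.
#'
#' @param arr A synapse array.
#' @param k Index of the spiking postsynaptic neuron.
#' @param pre_active Binary (or logical) vector of length `N`: presynaptic
#'   pulse present per input.
#' @return The updated synapse array.
#' @export
apply_plasticity_event <- function(arr, k, pre_active) {
  stopifnot(inherits(arr, "compound_synapse_array"))
  k <- .check_count(k, "k")
  if (k > arr$K) stop("index out of range", call. = FALSE)
  if (length(pre_active) != arr$N) {
    stop("`pre_active` must have length N", call. = FALSE)
  }
  act <- as.logical(pre_active)

  if (!.is_heterogeneous(arr)) {
    arr$m[k, ] <- .plasticity_counts(arr$m[k, ], act, arr$M,
                                     arr$pi_up, arr$pi_down)
    return(arr)
  }

  s_row <- matrix(arr$state[k, , ], arr$N, arr$M)
  pu <- if (is.null(arr$pi_up_sw)) arr$pi_up else
    matrix(arr$pi_up_sw[k, , ], arr$N, arr$M)
  pd <- if (is.null(arr$pi_down_sw)) arr$pi_down else
    matrix(arr$pi_down_sw[k, , ], arr$N, arr$M)
  res <- .plasticity_perswitch(s_row, act, pu, pd)
  arr$state[k, , ] <- res$state
  arr$m[k, ] <- rowSums(res$state)

  redraw <- arr$noise$mode %in% c("temporal", "spatial_temporal")
  if (redraw && any(res$flip_up)) {
    idx <- which(res$flip_up)
    w_row <- matrix(arr$w[k, , ], arr$N, arr$M)
    mu <- if (arr$noise$mode == "temporal") arr$omega else
      matrix(arr$w_device[k, , ], arr$N, arr$M)[idx]
    w_row[idx] <- .rtnorm(length(idx), mu, arr$noise$omega_sd,
                          method = arr$noise$truncation)
    arr$w[k, , ] <- w_row
  }
  arr
}

#' Expected weight change of one synapse per postsynaptic spike
#'
#' For a homogeneous synapse (uniform conductance and switching
#' probabilities) the expected change of `W_ki` caused by one postsynaptic
#' spike is `(M - m_ki) * omega * pi_up` when the presynaptic pulse is
#' present and `-m_ki * omega * pi_down` when it is absent. With balanced
#' probabilities (`pi_up = pi_down`) this equals
#' `pi_up * W_max * (y_i - W_ki / W_max)`: a stabilizing, linearly
#' weight-dependent STDP rule.
#'
#' @param arr A homogeneous synapse array (per-switch heterogeneity is
#'   rejected because the closed form no longer holds switch-wise).
#' @param k,i Synapse indices.
#' @param pre_active_i Binary: presynaptic pulse present.
#' @return Expected weight change (same units as `omega`).
#' @export
expected_weight_change <- function(arr, k, i, pre_active_i) {
  stopifnot(inherits(arr, "compound_synapse_array"))
  if (.is_heterogeneous(arr)) {
    stop("closed-form expected weight change requires uniform switches; ",
         "this array has per-switch heterogeneity", call. = FALSE)
  }
  k <- .check_count(k, "k"); i <- .check_count(i, "i")
  if (k > arr$K || i > arr$N) stop("index out of range", call. = FALSE)
  m <- arr$m[k, i]
  if (as.logical(pre_active_i)) {
    (arr$M - m) * arr$omega * arr$pi_up
  } else {
    -m * arr$omega * arr$pi_down
  }
}

#' Stationary activation probability of a switch
#'
#' Under i.i.d. plasticity events that are potentiating with probability `q`
#' (and depressing otherwise), a switch's active probability converges to
#' `p* = pi_up * q / (pi_up * q + pi_down * (1 - q))`, and the number of
#' active switches of a synapse converges to `Binomial(M, p*)`. With
#' balanced probabilities, `p* = q`: the weight fraction encodes the
#' expected input.
#'
#' @param params A [switching_params()] object.
#' @param q Probability that an event is potentiating.
#' @return The stationary per-switch activation probability.
#' @examples
#' stationary_activation_prob(switching_params(1e-3, 1e-3), 0.8) # 0.8
#' @export
stationary_activation_prob <- function(params, q) {
  stopifnot(inherits(params, "switching_params"))
  .check_prob(q, "q")
  denom <- params$pi_up * q + params$pi_down * (1 - q)
  if (denom == 0) {
    stop("undefined equilibrium: pi_up * q + pi_down * (1 - q) = 0",
         call. = FALSE)
  }
  params$pi_up * q / denom
}

#' Simulate the switch-count Markov chain of a single synapse
#'
#' Applies `n_events` i.i.d. plasticity events (potentiating with
#' probability `q`) to one compound synapse and records the active-switch
#' count after each event. Useful as a stationarity oracle: after burn-in
#' the counts are distributed `Binomial(M, p*)` with `p*` from
#' [stationary_activation_prob()].
#'
#' @param M Switches per synapse.
#' @param params A [switching_params()] object.
#' @param q Probability of a potentiating event.
#' @param n_events Number of events.
#' @param init_m Initial active count (default `round(M / 2)`).
#' @return Integer vector of counts after each event.
#' @export
switch_chain <- function(M, params, q, n_events, init_m = round(M / 2)) {
  M <- .check_count(M, "M")
  stopifnot(inherits(params, "switching_params"))
  .check_prob(q, "q")
  n_events <- .check_count(n_events, "n_events")
  init_m <- .check_count(init_m, "init_m", min = 0L)
  stopifnot(init_m <= M)
  out <- integer(n_events)
  m <- init_m
  pu <- params$pi_up; pd <- params$pi_down
  for (t in seq_len(n_events)) {
    if (runif(1) < q) {
      m <- m + rbinom(1L, M - m, pu)
    } else {
      m <- m - rbinom(1L, m, pd)
    }
    out[t] <- m
  }
  out
}

#' @export
print.compound_synapse_array <- function(x, ...) {
  cat(sprintf(
    "<compound_synapse_array> K=%d neurons x N=%d inputs, M=%d switches\n",
    x$K, x$N, x$M))
  cat(sprintf("  omega=%g, pi_up=%g, pi_down=%g, noise=%s\n",
              x$omega, x$pi_up, x$pi_down, x$noise$mode))
  cat(sprintf("  mean active fraction: %.3f\n", mean(x$m) / x$M))
  invisible(x)
}
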