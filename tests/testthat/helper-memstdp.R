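# Builders for deterministic fixtures: arrays with prescribed counts or
# per-switch weights, bypassing random initialization.

uniform_array <- function(m, M = 10, omega = 0.1, pi_up = 1e-3,
                          pi_down = pi_up) {
  m <- as.matrix(m)
  arr <- build_synapse_array(nrow(m), ncol(m), M, omega,
                             switching_params(pi_up, pi_down),
                             init_active_frac = 0)
  arr$m <- matrix(as.integer(m), nrow(m), ncol(m))
  stopifnot(all(arr$m >= 0), all(arr$m <= M))
  arr
}

# heterogeneous array with explicit per-switch states and weights
perswitch_array <- function(state, w, omega = 0.1, pi_up = 1e-3,
                            pi_down = pi_up,
                            noise = device_noise("spatial", omega_sd = 0.01)) {
  stopifnot(identical(dim(state), dim(w)))
  arr <- build_synapse_array(dim(state)[1], dim(state)[2], dim(state)[3],
                             omega, switching_params(pi_up, pi_down),
                             noise, init_active_frac = 0)
  arr$state <- array(as.logical(state), dim(state))
  arr$w <- w
  arr$w_device <- w
  arr$m <- rowSums(arr$state, dims = 2L)
  arr
}

# closed-form moments of a normal truncated to [0, Inf)
truncnorm_moments <- function(mu, sd) {
  a <- -mu / sd
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  list(mean = mu + sd * lambda,
       var = sd^2 * (1 + a * lambda - lambda^2))
}

total_variation <- function(emp_counts, probs) {
  p_emp <- emp_counts / sum(emp_counts)
  sum(abs(p_emp - probs)) / 2
}
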