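# Mixture-of-Gaussians generative model implicitly encoded by the synapse
# array: each network neuron k is a mixture component with per-channel
# Gaussian likelihood N(y_i; mu_ki, sigma2). The hardware <-> theory mapping:
#   mu_ki  = m_ki / M = W_ki / W_max
#   sigma2 = 1 / W_max            (W_max = omega * M)
#   eta_W  = pi_up * W_max        (synaptic learning rate)
# All density arithmetic is done in log space.

#' Mixture-of-Gaussians model parameters
#'
#' @param mu `K x N` matrix of per-channel likelihood means in `[0, 1]`.
#' @param sigma2 Shared likelihood variance (> 0).
#' @param prior Mixing prior over the `K` hidden causes (default uniform).
#' @param b_hat Optional bias vector; defaults to `log(prior)`.
#' @return An object of class `mog_params`.
#' @export
mog_params <- function(mu, sigma2, prior = NULL, b_hat = NULL) {
  mu <- as.matrix(mu)
  stopifnot(is.numeric(mu), all(is.finite(mu)))
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0) {
    stop("`sigma2` must be a single positive number", call. = FALSE)
  }
  K <- nrow(mu)
  if (is.null(prior)) prior <- rep(1 / K, K)
  if (length(prior) != K || any(prior < 0) || abs(sum(prior) - 1) > 1e-8) {
    stop("`prior` must be a length-K probability vector", call. = FALSE)
  }
  if (is.null(b_hat)) b_hat <- log(prior)
  stopifnot(length(b_hat) == K)
  structure(list(mu = mu, sigma2 = sigma2, prior = as.numeric(prior),
                 b_hat = as.numeric(b_hat), K = K, N = ncol(mu)),
            class = "mog_params")
}

#' Read the generative model off a synapse array
#'
#' Maps the hardware state to theory parameters: `mu_ki = m_ki / M`,
#' `sigma2 = 1 / W_max` with `W_max = omega * M`, and a uniform prior by
#' default. For arrays with conductance noise the weight fraction
#' `W_ki / W_max` (with nominal `W_max`) is used as the mean estimate.
#'
#' @param arr A [build_synapse_array()] object.
#' @param prior Optional prior (default uniform).
#' @return A [mog_params()] object.
#' @examples
#' arr <- build_synapse_array(2, 4, M = 10, omega = 0.1)
#' mog_from_hardware(arr)$sigma2 # 1
#' @export
mog_from_hardware <- function(arr, prior = NULL) {
  stopifnot(inherits(arr, "compound_synapse_array"))
  w_max <- max_weight(arr)
  if (w_max <= 0) stop("W_max = omega * M must be > 0", call. = FALSE)
  mu <- if (is.null(arr$w)) arr$m / arr$M else weight_matrix(arr) / w_max
  mog_params(mu, sigma2 = 1 / w_max, prior = prior)
}

#' Hardware-to-theory parameter mapping
#'
#' Tabulates the correspondence between the synapse hardware parameters and
#' the generative-model quantities: maximum weight `W_max = omega * M`
#' (equal to the likelihood precision `1 / sigma2`), likelihood variance
#' `sigma2 = 1 / W_max`, synaptic learning rate `eta_W = pi_up * W_max`,
#' the number of discrete weight levels `M + 1` and the corresponding
#' information content `log2(M + 1)` bits.
#'
#' @param omega Conductance weight of one switch.
#' @param M Switches per synapse.
#' @param pi_up Potentiation switching probability.
#' @return A tibble with columns `quantity` and `value`.
#' @examples
#' theory_parameters(omega = 0.1, M = 10, pi_up = 1e-3)
#' @export
theory_parameters <- function(omega, M, pi_up) {
  .check_nonneg(omega, "omega")
  M <- .check_count(M, "M")
  .check_prob(pi_up, "pi_up")
  w_max <- omega * M
  tibble::tibble(
    quantity = c("w_max", "sigma2", "eta_w", "resolution_omega",
                 "weight_levels", "weight_bits"),
    value = c(w_max, 1 / w_max, pi_up * w_max, omega,
              M + 1, log2(M + 1))
  )
}

#' Log-likelihood of one input vector under each mixture component
#'
#' `log p(y | z_k = 1) = sum_i log N(y_i; mu_ki, sigma2)`, including the
#' Gaussian normalization constant (so values are true log densities; the
#' input-only factor cancels in posteriors).
#'
#' @param model A [mog_params()] object.
#' @param y Input vector of length `N` (binary in the spiking network, but
#'   any real values are supported).
#' @return Numeric vector of length `K` of log densities.
#' @export
component_loglik <- function(model, y) {
  stopifnot(inherits(model, "mog_params"))
  y <- as.numeric(y)
  if (length(y) != model$N) stop("`y` must have length N", call. = FALSE)
  s2 <- model$sigma2
  dev <- sweep(model$mu, 2L, y) # mu_ki - y_i
  -model$N / 2 * log(2 * pi * s2) - rowSums(dev^2) / (2 * s2)
}

#' Posterior over hidden causes for one input
#'
#' Computes `p(z_k = 1 | y)` either by direct Bayes normalization of
#' `prior_k * likelihood_k` (in log space), or through the potential form
#' `u_hat_k = b_hat_k - A_k + sum_i W_ki y_i` with `W = mu / sigma2` and
#' `A_k = sigma2 / 2 * sum_i W_ki^2`, followed by a softmax. The two routes
#' are algebraically identical and agree to near machine precision.
#'
#' @param model A [mog_params()] object.
#' @param y Input vector.
#' @param method `"bayes"` or `"potential"`.
#' @return Probability vector of length `K`.
#' @export
mog_posterior <- function(model, y, method = c("bayes", "potential")) {
  method <- match.arg(method)
  if (method == "bayes") {
    lp <- log(model$prior) + component_loglik(model, y)
    return(response_distribution(lp))
  }
  u <- posterior_potentials(model, y)
  response_distribution(u)
}

#' Posterior potentials of the model
#'
#' `u_hat_k = b_hat_k - A_k + sum_i W_ki y_i`, the quantity a network
#' neuron's membrane potential must equal for its softmax response to be
#' the exact posterior.
#'
#' @inheritParams mog_posterior
#' @return Numeric vector of length `K`.
#' @export
posterior_potentials <- function(model, y) {
  stopifnot(inherits(model, "mog_params"))
  y <- as.numeric(y)
  if (length(y) != model$N) stop("`y` must have length N", call. = FALSE)
  W <- model$mu / model$sigma2
  A <- model$sigma2 / 2 * rowSums(W^2)
  model$b_hat - A + as.vector(W %*% y)
}

#' Intrinsic excitabilities that realize exact inference
#'
#' Returns `b_k = b_hat_k - A_k`: wiring these values into the network state
#' (with the weight matrix matching the model, i.e. `W = mu / sigma2`)
#' makes [response_distribution()] of the membrane potentials equal to the
#' exact posterior.
#'
#' @param model A [mog_params()] object.
#' @return Numeric vector of length `K`.
#' @export
posterior_biases <- function(model) {
  stopifnot(inherits(model, "mog_params"))
  W <- model$mu / model$sigma2
  model$b_hat - model$sigma2 / 2 * rowSums(W^2)
}

#' Average log-likelihood of a dataset under the model
#'
#' Mean over samples of `log sum_k prior_k * p(y | z_k = 1)`, evaluated via
#' log-sum-exp. Also returns the Monte-Carlo standard error of the mean,
#' useful to judge jitter between monitoring checkpoints.
#'
#' @param model A [mog_params()] object.
#' @param Y Matrix of input samples (rows) by channels (columns).
#' @return A list with elements `loglik` (mean per-sample log-likelihood)
#'   and `se` (standard error of the mean).
#' @export
mog_log_likelihood <- function(model, Y) {
  stopifnot(inherits(model, "mog_params"))
  Y <- as.matrix(Y)
  if (nrow(Y) == 0) stop("empty dataset", call. = FALSE)
  if (ncol(Y) != model$N) stop("`Y` must have N columns", call. = FALSE)
  s2 <- model$sigma2
  mu <- model$mu
  # log p(y | k) for all samples at once:
  #   -(N/2) log(2 pi s2) - (||y||^2 - 2 mu_k.y + ||mu_k||^2) / (2 s2)
  cross <- mu %*% t(Y)                     # K x n
  y2 <- rowSums(Y^2)                       # n
  mu2 <- rowSums(mu^2)                     # K
  ll_k <- sweep(sweep(2 * cross, 2L, y2), 1L, mu2) / (2 * s2) -
    model$N / 2 * log(2 * pi * s2)
  lp <- ll_k + log(model$prior)
  mx <- apply(lp, 2L, max)
  per_sample <- mx + log(colSums(exp(sweep(lp, 2L, mx))))
  list(loglik = mean(per_sample),
       se = stats::sd(per_sample) / sqrt(length(per_sample)))
}

#' Equilibrium weight encoding under unbalanced switching
#'
#' With systematic imbalance `delta = (pi_up - pi_down) / pi_up`, the
#' stationary weight fraction for an input with time-averaged activity
#' `y_bar` is `W / W_max = y_bar / (y_bar + (1 - delta) * (1 - y_bar))`.
#' At `delta = 0` this is the identity: the weight fraction encodes the
#' expected input linearly; imbalance bends the encoding up (`delta > 0`)
#' or down (`delta < 0`).
#'
#' @param y_bar Expected input activity in `[0, 1]` (vectorized).
#' @param delta Imbalance ratio (<= 1).
#' @return Stationary weight fraction(s) in `[0, 1]`.
#' @examples
#' equilibrium_encoding(0.5, 0)     # 0.5
#' equilibrium_encoding(0.5, -0.5)  # 0.4
#' @export
equilibrium_encoding <- function(y_bar, delta = 0) {
  .check_prob(y_bar, "y_bar")
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta > 1) {
    stop("`delta` must be a finite number <= 1", call. = FALSE)
  }
  denom <- y_bar + (1 - delta) * (1 - y_bar)
  out <- ifelse(denom == 0, 0, y_bar / denom)
  out[y_bar == 0] <- 0
  out
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `D_KL(q || p) = sum_k q_k log(q_k / p_k)`; zero iff the distributions
#' are equal, infinite if `q` puts mass where `p` has none. Used as a
#' diagnostic of how far the network response is from the exact posterior.
#'
#' @param q,p Probability vectors of equal length.
#' @return A single non-negative number (possibly `Inf`).
#' @export
kl_divergence <- function(q, p) {
  if (length(q) != length(p)) stop("lengths differ", call. = FALSE)
  .check_prob(q, "q"); .check_prob(p, "p")
  if (abs(sum(q) - 1) > 1e-6 || abs(sum(p) - 1) > 1e-6) {
    stop("`q` and `p` must sum to 1", call. = FALSE)
  }
  pos <- q > 0
  if (any(p[pos] == 0)) return(Inf)
  sum(q[pos] * log(q[pos] / p[pos]))
}

#' @export
print.mog_params <- function(x, ...) {
  cat(sprintf("<mog_params> K=%d components, N=%d channels, sigma2=%g\n",
              x$K, x$N, x$sigma2))
  invisible(x)
}
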