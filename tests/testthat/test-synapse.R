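test_that("parameter constructors reject invalid values", {
  expect_error(switching_params(-0.1), "probability")
  expect_error(switching_params(0.5, 1.2), "probability")
  expect_error(device_noise("none", omega_sd = 0.1), "omega_sd")
  expect_error(device_noise("systematic_imbalance", delta = 1.5), "delta")
  expect_error(build_synapse_array(0, 3, 5), "K")
  expect_error(build_synapse_array(2, 3, 5, omega = -1), "omega")
})

test_that("initialization sets the activation fraction and weight range", {
  arr0 <- build_synapse_array(3, 4, 10, init_active_frac = 0)
  expect_true(all(weight_matrix(arr0) == 0))

  arr1 <- build_synapse_array(3, 4, 10, omega = 0.1, init_active_frac = 1)
  expect_equal(unname(weight_matrix(arr1)),
               matrix(1, 3, 4)) # W_max = omega * M
  expect_equal(max_weight(arr1), 1)

  set.seed(11)
  arr <- build_synapse_array(10, 100, 10, init_active_frac = 0.3)
  frac <- mean(active_counts(arr)) / 10
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))
})

test_that("spatial conductance noise matches the truncated-normal law", {
  set.seed(12)
  arr <- build_synapse_array(10, 1000, 10, omega = 0.1,
                             noise = device_noise("spatial",
                                                  omega_sd = 0.05))
  mom <- truncnorm_moments(0.1, 0.05)
  n <- length(arr$w)
  expect_equal(n, 1e5)
  expect_true(all(arr$w >= 0))
  expect_lt(abs(mean(arr$w) - mom$mean), 3 * sqrt(mom$var / n))
})

test_that("synapse_weight sums active switch conductances", {
  arr <- uniform_array(matrix(c(0L, 5L), 1, 2), M = 10, omega = 0.1)
  expect_identical(synapse_weight(arr, 1, 1), 0)
  expect_equal(synapse_weight(arr, 1, 2), 0.5)
  expect_error(synapse_weight(arr, 1, 3), "range")

  st <- array(FALSE, c(1, 1, 4)); st[1, 1, c(1, 3)] <- TRUE
  w <- array(0, c(1, 1, 4)); w[1, 1, ] <- c(0.08, 0.5, 0.12, 0.5)
  het <- perswitch_array(st, w)
  expect_equal(synapse_weight(het, 1, 1), 0.20)
  expect_equal(unname(weight_matrix(het))[1, 1], 0.20)
})

test_that("plasticity events flip switches with the right probabilities", {
  # certain potentiation saturates the synapse
  arr <- uniform_array(matrix(3L, 1, 1), M = 10, pi_up = 1, pi_down = 1)
  arr <- apply_plasticity_event(arr, 1, 1)
  expect_identical(active_counts(arr)[1, 1], 10L)

  # pi_down = 0 leaves a silent-input synapse unchanged
  arr <- uniform_array(matrix(5L, 1, 1), M = 10, pi_up = 1, pi_down = 0)
  arr <- apply_plasticity_event(arr, 1, 0)
  expect_identical(active_counts(arr)[1, 1], 5L)

  # empirical mean potentiation matches (M - m) * pi_up = 5e-3
  set.seed(13)
  n_syn <- 2000L; n_events <- 100L
  base <- uniform_array(matrix(5L, 1, n_syn), M = 10, pi_up = 1e-3,
                        pi_down = 1e-3)
  dm <- numeric(n_events)
  for (e in seq_len(n_events)) {
    upd <- apply_plasticity_event(base, 1, rep(1, n_syn))
    dm[e] <- mean(active_counts(upd) - 5L)
  }
  n_trials <- n_syn * n_events
  se <- sqrt(5 * 1e-3 * (1 - 1e-3) / n_trials)
  expect_lt(abs(mean(dm) - 5e-3), 3 * se)
})

test_that("expected weight change follows the stabilizing STDP rule", {
  arr <- uniform_array(matrix(5L, 1, 1), M = 10, omega = 0.1,
                       pi_up = 1e-3, pi_down = 1e-3)
  expect_equal(expected_weight_change(arr, 1, 1, 1), 5e-4)
  expect_equal(expected_weight_change(arr, 1, 1, 0), -5e-4)

  sat <- uniform_array(matrix(10L, 1, 1), M = 10)
  expect_equal(expected_weight_change(sat, 1, 1, 1), 0)

  # balanced closed form: pi_up * W_max * (y - W/W_max)
  for (m in c(0L, 3L, 7L)) {
    a <- uniform_array(matrix(m, 1, 1), M = 10, omega = 0.1, pi_up = 1e-3)
    expect_equal(expected_weight_change(a, 1, 1, 1),
                 1e-3 * 1 * (1 - m / 10))
  }

  set.seed(14)
  het <- build_synapse_array(2, 2, 4,
                             noise = device_noise("spatial",
                                                  omega_sd = 0.02))
  expect_error(expected_weight_change(het, 1, 1, 1), "heterogeneity")
})

test_that("stationary activation probability solves the balance equation", {
  expect_equal(stationary_activation_prob(switching_params(1e-3), 0.8), 0.8)
  expect_equal(stationary_activation_prob(switching_params(0.5, 0.1), 0), 0)
  expect_equal(
    stationary_activation_prob(switching_params(2e-3, 3e-3), 0.5), 0.4)
  expect_error(stationary_activation_prob(switching_params(0.5, 0), 0),
               "equilibrium")
})

test_that("count-based and per-switch updates coincide on shared draws", {
  set.seed(15)
  N <- 6L; M <- 8L
  pu <- 0.3; pd <- 0.2
  s <- matrix(runif(N * M) < 0.5, N, M)
  m_counts <- rowSums(s)
  for (event in 1:50) {
    act <- runif(N) < 0.5
    u <- matrix(runif(N * M), N, M)
    res <- memstdp:::.plasticity_perswitch(s, act, pu, pd, u)
    up_draws <- rowSums((!s) & (u < pu))
    dn_draws <- rowSums(s & (u < pd))
    m_counts <- memstdp:::.plasticity_counts(m_counts, act, M, pu, pd,
                                             up_draws, dn_draws)
    s <- res$state
    expect_identical(m_counts, rowSums(s))
  }
})

# exact stationary law of the count chain from its 11 x 11 transition matrix
exact_stationary <- function(M, pu, pd, q) {
  P <- matrix(0, M + 1, M + 1)
  for (m in 0:M) {
    for (j in 0:(M - m)) {
      P[m + 1, m + j + 1] <- P[m + 1, m + j + 1] +
        q * dbinom(j, M - m, pu)
    }
    for (j in 0:m) {
      P[m + 1, m - j + 1] <- P[m + 1, m - j + 1] +
        (1 - q) * dbinom(j, m, pd)
    }
  }
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

test_that("switch counts equilibrate to the exact stationary law", {
  params <- switching_params(0.3, 0.2)
  q <- 0.5
  exact <- exact_stationary(10, 0.3, 0.2, q)

  set.seed(16)
  chain <- switch_chain(10, params, q, n_events = 2e4)
  chain <- chain[-(1:500)]
  expect_true(all(chain >= 0 & chain <= 10))
  tv <- total_variation(tabulate(chain + 1L, nbins = 11L), exact)
  expect_lt(tv, 0.05)

  # the binomial form is the small-probability limit of the exact law:
  # O(pi) deviation, already visible at large switching probabilities
  p_star <- stationary_activation_prob(params, q) # 0.6
  expect_gt(sum(abs(exact - dbinom(0:10, 10, p_star))) / 2, 0.05)
  small <- exact_stationary(10, 3e-3, 2e-3, q)
  expect_lt(sum(abs(small - dbinom(0:10, 10, p_star))) / 2, 0.005)
})

test_that("synapse arrays round-trip through JSON", {
  set.seed(17)
  arr <- build_synapse_array(3, 5, 6, init_active_frac = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_synapse_array(arr, path)
  back <- read_synapse_array(path)
  expect_identical(back$m, arr$m)
  expect_equal(weight_matrix(back), weight_matrix(arr))

  het <- build_synapse_array(2, 3, 4,
                             noise = device_noise("spatial_temporal",
                                                  omega_sd = 0.05))
  write_synapse_array(het, path)
  back <- read_synapse_array(path)
  expect_equal(weight_matrix(back), weight_matrix(het))
  expect_identical(back$state, het$state)
  expect_equal(back$w_device, het$w_device)
})
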