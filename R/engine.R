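# Internal simulation engine. One pure-R loop drives training and (frozen)
# evaluation; it consumes the RNG in exactly the same order as composing the
# public pieces (per-step encoding draws, spike-occurrence draw, winner draw,
# plasticity draws), so a run is bit-reproducible and equivalent to a manual
# encode/step loop.

.engine <- function(arr, b, params, protos, stream_classes, present_steps,
                    freeze = FALSE, monitor_steps = NULL, monitor_Y = NULL,
                    record_counts = FALSE, t0_ms = 0) {
  K <- arr$K; N <- arr$N; M <- arr$M
  dt <- params$dt
  w <- as.integer(round(params$tau / dt))
  n_slots <- length(stream_classes)
  n_steps <- n_slots * present_steps
  het <- .is_heterogeneous(arr)
  redraw <- arr$noise$mode %in% c("temporal", "spatial_temporal")

  psp <- spike_probability(protos$x, dt, params$tau)
  p_net <- 1 - exp(-params$r_net * dt / 1000)
  drift <- params$eta_b * (params$r_net / 1000) * params$target * dt

  m <- arr$m
  W <- weight_matrix(arr)
  if (het) {
    S <- arr$state
    w_sw <- arr$w
    w_dev <- arr$w_device
    pu_sw <- arr$pi_up_sw
    pd_sw <- arr$pi_down_sw
  }
  pu <- arr$pi_up; pd <- arr$pi_down
  omega <- arr$omega
  trunc_method <- arr$noise$truncation
  omega_sd <- arr$noise$omega_sd

  buf <- matrix(FALSE, w, N)
  cnt <- integer(N)
  ptr <- 1L

  counts <- if (record_counts) matrix(0L, n_slots, K) else NULL
  hist_t <- c(); hist_ll <- c(); hist_se <- c()
  snapshots <- list()
  take_snapshot <- function(step) {
    mu <- if (het) W / (omega * M) else m / M
    model <- mog_params(mu, sigma2 = 1 / (omega * M))
    ll <- mog_log_likelihood(model, monitor_Y)
    hist_t <<- c(hist_t, t0_ms / 1000 + step * dt / 1000)
    hist_ll <<- c(hist_ll, ll$loglik)
    hist_se <<- c(hist_se, ll$se)
    snapshots[[length(snapshots) + 1L]] <<- m
  }
  monitoring <- !is.null(monitor_steps) && !is.null(monitor_Y)
  if (monitoring) take_snapshot(0L)

  n_spikes <- 0L
  spike_counts <- integer(K)
  slot <- 0L
  px <- NULL
  for (step in seq_len(n_steps)) {
    if ((step - 1L) %% present_steps == 0L) {
      slot <- slot + 1L
      px <- psp[stream_classes[slot], ]
    }
    sp <- runif(N) < px
    cnt <- cnt - buf[ptr, ] + sp
    buf[ptr, ] <- sp
    ptr <- if (ptr == w) 1L else ptr + 1L
    y <- cnt > 0L

    u <- b + as.vector(W %*% y)
    if (runif(1) < p_net) {
      p <- exp(u - max(u))
      r <- runif(1) * sum(p)
      k <- 1L; acc <- p[1L]
      while (acc < r && k < K) { k <- k + 1L; acc <- acc + p[k] }
      n_spikes <- n_spikes + 1L
      spike_counts[k] <- spike_counts[k] + 1L
      if (record_counts) counts[slot, k] <- counts[slot, k] + 1L

      if (!freeze) {
        if (!het) {
          mi <- m[k, ]
          up <- rbinom(N, M - mi, pu)
          dn <- rbinom(N, mi, pd)
          up[!y] <- 0L
          dn[y] <- 0L
          mi <- mi + up - dn
          m[k, ] <- mi
          W[k, ] <- omega * mi
        } else {
          s_row <- matrix(S[k, , ], N, M)
          pur <- if (is.null(pu_sw)) pu else matrix(pu_sw[k, , ], N, M)
          pdr <- if (is.null(pd_sw)) pd else matrix(pd_sw[k, , ], N, M)
          res <- .plasticity_perswitch(s_row, y, pur, pdr)
          s_row <- res$state
          S[k, , ] <- s_row
          m[k, ] <- rowSums(s_row)
          if (!is.null(w_sw)) {
            w_row <- matrix(w_sw[k, , ], N, M)
            if (redraw && any(res$flip_up)) {
              idx <- which(res$flip_up)
              mu_r <- if (arr$noise$mode == "temporal") omega else
                matrix(w_dev[k, , ], N, M)[idx]
              w_row[idx] <- .rtnorm(length(idx), mu_r, omega_sd,
                                    method = trunc_method)
              w_sw[k, , ] <- w_row
            }
            W[k, ] <- rowSums(s_row * w_row)
          } else {
            W[k, ] <- omega * m[k, ]
          }
        }
        b <- b + drift
        b[k] <- b[k] - params$eta_b
        if (monitoring && step %% monitor_steps == 0L) take_snapshot(step)
        next
      }
    }
    if (!freeze) b <- b + drift
    if (monitoring && step %% monitor_steps == 0L) take_snapshot(step)
  }

  arr$m <- m
  if (het) {
    arr$state <- S
    arr$w <- w_sw
  }
  history <- if (monitoring) {
    tibble::tibble(time_s = hist_t, loglik = hist_ll, loglik_se = hist_se)
  } else NULL
  list(arr = arr, b = b, t_ms = t0_ms + n_steps * dt,
       history = history, snapshots = snapshots, counts = counts,
       n_spikes = n_spikes, spike_counts = spike_counts)
}
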