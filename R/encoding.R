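# Poisson encoding of intensity patterns into spike rasters and binary
# presynaptic pulse traces y(t). The per-step spike probability is chosen so
# that the time average of the pulse trace equals the intensity: <y_i> = x_i.

#' Per-step spike probability for an intensity
#'
#' An input with intensity `x` spikes per time step with probability
#' `1 - (1 - x)^(dt / tau)`. Because a pulse of duration `tau` follows each
#' spike, the probability that the pulse trace is on at any moment is then
#' exactly `x` (no spike in the last `tau / dt` steps has probability
#' `1 - x`).
#'
#' @param x Intensity in `[0, 1]` (vectorized).
#' @param dt Time step in ms.
#' @param tau Pulse duration in ms.
#' @return Spike probability per step; `x = 1` maps exactly to 1.
#' @examples
#' spike_probability(0.9, dt = 1, tau = 10) # 1 - 0.1^0.1
#' @export
spike_probability <- function(x, dt = 1, tau = 10) {
  .check_prob(x, "x")
  stopifnot(dt > 0, tau > 0)
  1 - (1 - x)^(dt / tau)
}

#' Encode an intensity pattern as a Poisson spike raster
#'
#' Draws independent Bernoulli spikes per input and per time step with
#' [spike_probability()]. Steps are at times `dt, 2*dt, ..., duration_ms`;
#' the RNG is consumed step-major (all inputs within a step, then the next
#' step), so composed simulations are bit-reproducible.
#'
#' @param x Intensity vector of length `N`.
#' @param duration_ms Encoding window in ms (multiple of `dt`).
#' @param dt,tau Time step and pulse duration in ms.
#' @return A tibble with columns `time_ms` and `input` (one row per spike),
#'   with attributes `n_inputs`, `duration_ms`, `dt`, `tau`.
#' @export
encode_pattern <- function(x, duration_ms, dt = 1, tau = 10) {
  .check_prob(x, "x")
  stopifnot(duration_ms > 0, abs(duration_ms / dt - round(duration_ms / dt)) < 1e-9)
  n_steps <- as.integer(round(duration_ms / dt))
  N <- length(x)
  p <- spike_probability(x, dt, tau)
  out_t <- vector("list", n_steps)
  out_i <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    hit <- which(runif(N) < p)
    out_t[[s]] <- rep.int(s, length(hit))
    out_i[[s]] <- hit
  }
  raster <- tibble::tibble(
    time_ms = unlist(out_t) * dt,
    input = unlist(out_i)
  )
  attr(raster, "n_inputs") <- N
  attr(raster, "duration_ms") <- duration_ms
  attr(raster, "dt") <- dt
  attr(raster, "tau") <- tau
  raster
}

#' Convert a spike raster into a binary pulse trace
#'
#' Each spike elicits a rectangular pulse of duration `tau` and amplitude 1;
#' overlapping pulses saturate at 1. The window convention is half-open:
#' `y_i(t) = 1` iff input `i` spiked in `(t - tau, t]`, so a single spike
#' yields exactly `tau / dt` consecutive on-steps.
#'
#' @param raster A raster from [encode_pattern()] (or any tibble with
#'   `time_ms`, `input`).
#' @param n_inputs,duration_ms,dt,tau Taken from the raster attributes when
#'   omitted.
#' @return A binary matrix with `duration_ms / dt` rows (time steps) and
#'   `n_inputs` columns.
#' @export
raster_to_trace <- function(raster, n_inputs = attr(raster, "n_inputs"),
                            duration_ms = attr(raster, "duration_ms"),
                            dt = attr(raster, "dt"),
                            tau = attr(raster, "tau")) {
  stopifnot(!is.null(n_inputs), !is.null(duration_ms), !is.null(dt),
            !is.null(tau))
  n_steps <- as.integer(round(duration_ms / dt))
  w <- as.integer(round(tau / dt))
  spk <- matrix(0L, n_steps, n_inputs)
  if (nrow(raster) > 0) {
    step <- as.integer(round(raster$time_ms / dt))
    stopifnot(all(step >= 1L), all(step <= n_steps))
    spk[cbind(step, raster$input)] <- 1L
  }
  # y[s, i] = 1 iff a spike occurred in steps (s - w, s]
  cs <- apply(spk, 2L, cumsum)
  lagged <- rbind(matrix(0L, w, n_inputs),
                  cs[seq_len(max(n_steps - w, 0L)), , drop = FALSE])
  y <- (cs - lagged[seq_len(n_steps), , drop = FALSE]) > 0L
  storage.mode(y) <- "integer"
  y
}

#' Write a spike raster as a two-column text file
#'
#' @param raster A raster tibble (`time_ms`, `input`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(raster[, c("time_ms", "input")], path,
                     row.names = FALSE, col.names = TRUE, sep = "\t",
                     quote = FALSE)
  invisible(path)
}
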