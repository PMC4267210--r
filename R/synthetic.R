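# Synthetic pattern datasets. Prototypes are two-level intensity images
# (off_level / on_level, default 0.05 / 0.9 as in the digit preprocessing the
# encoding emulates); streams present a uniformly drawn prototype per
# presentation slot; snapshot datasets are binary y-vectors distributed as
# the network sees them after Poisson encoding.

#' Generate two-level prototype patterns
#'
#' Each of the `n_classes` prototypes sets a random subset of about
#' `on_fraction * n_inputs` channels to `on_level` and the rest to
#' `off_level`. Supports lean toward disjointness (channels already used by
#' other prototypes are down-weighted) so the mixture components are
#' identifiable.
#'
#' @param n_classes Number of prototype classes.
#' @param n_inputs Number of input channels.
#' @param on_fraction Fraction of on-channels per prototype (in `(0, 1)`).
#' @param off_level,on_level Intensities of off/on channels, in `[0, 1]`.
#' @return An object of class `prototype_set`: a list with the
#'   `n_classes x n_inputs` intensity matrix `x` and the generation
#'   parameters.
#' @examples
#' set.seed(1)
#' protos <- make_prototypes(5, 100)
#' rowSums(protos$x > 0.5) # 30 on-channels each
#' @export
make_prototypes <- function(n_classes, n_inputs, on_fraction = 0.3,
                            off_level = 0.05, on_level = 0.9) {
  n_classes <- .check_count(n_classes, "n_classes")
  n_inputs <- .check_count(n_inputs, "n_inputs")
  if (on_fraction <= 0 || on_fraction >= 1) {
    stop("`on_fraction` must be in (0, 1)", call. = FALSE)
  }
  .check_prob(off_level, "off_level"); .check_prob(on_level, "on_level")
  n_on <- max(1L, round(on_fraction * n_inputs))
  if (n_inputs < n_on + 1L) {
    stop("`n_inputs` too small for distinct prototypes", call. = FALSE)
  }
  x <- matrix(off_level, n_classes, n_inputs)
  used <- integer(n_inputs)
  for (c in seq_len(n_classes)) {
    w <- 1 / (1 + 3 * used)
    on <- sample.int(n_inputs, n_on, prob = w)
    x[c, on] <- on_level
    used[on] <- used[on] + 1L
  }
  if (n_classes > 1L && anyDuplicated(split(x, row(x)))) {
    stop("failed to generate pairwise distinct prototypes; increase ",
         "`n_inputs`", call. = FALSE)
  }
  structure(list(x = x, n_classes = n_classes, n_inputs = n_inputs,
                 on_fraction = on_fraction, off_level = off_level,
                 on_level = on_level),
            class = "prototype_set")
}

#' Sample a presentation stream of prototypes
#'
#' Draws one prototype uniformly at random per presentation slot.
#'
#' @param protos A [make_prototypes()] object.
#' @param total_ms Total stream duration in ms (multiple of
#'   `presentation_ms`).
#' @param presentation_ms Duration of one presentation in ms.
#' @return A tibble of class `pattern_stream` with columns `onset_ms` and
#'   `class`.
#' @export
sample_stream <- function(protos, total_ms, presentation_ms = 100) {
  stopifnot(inherits(protos, "prototype_set"))
  if (abs(total_ms / presentation_ms -
          round(total_ms / presentation_ms)) > 1e-9) {
    stop("`total_ms` must be a multiple of `presentation_ms`",
         call. = FALSE)
  }
  n_slots <- as.integer(round(total_ms / presentation_ms))
  out <- tibble::tibble(
    onset_ms = (seq_len(n_slots) - 1) * presentation_ms,
    class = sample.int(protos$n_classes, n_slots, replace = TRUE)
  )
  attr(out, "presentation_ms") <- presentation_ms
  class(out) <- c("pattern_stream", class(out))
  out
}

#' Draw binary input snapshots as the network sees them
#'
#' For each sample a prototype is drawn uniformly, Poisson encoding is run
#' for a warm-up of `2 * tau` (after which the box-kernel pulse trace is
#' stationary), and the binary trace at the final step is recorded. Channel
#' marginals equal the prototype intensities: `P(y_i = 1) = x_i`.
#'
#' @param protos A [make_prototypes()] object.
#' @param n_samples Number of snapshots.
#' @param dt,tau Time step and pulse duration in ms.
#' @return A list of class `snapshot_set` with the binary `n_samples x N`
#'   matrix `y` and the integer class vector `class`.
#' @export
snapshot_dataset <- function(protos, n_samples, dt = 1, tau = 10) {
  stopifnot(inherits(protos, "prototype_set"))
  n_samples <- .check_count(n_samples, "n_samples")
  w <- as.integer(round(tau / dt))
  cls <- sample.int(protos$n_classes, n_samples, replace = TRUE)
  p <- spike_probability(protos$x, dt, tau)[cls, , drop = FALSE]
  n <- n_samples * protos$n_inputs
  y <- matrix(FALSE, n_samples, protos$n_inputs)
  for (s in seq_len(2L * w)) {
    sp <- matrix(runif(n), n_samples, protos$n_inputs) < p
    if (s > w) y <- y | sp # only spikes within the final tau window count
  }
  storage.mode(y) <- "integer"
  structure(list(y = y, class = cls), class = "snapshot_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf(
    "<prototype_set> %d classes x %d inputs, levels {%g, %g}, on_fraction %g\n",
    x$n_classes, x$n_inputs, x$off_level, x$on_level, x$on_fraction))
  invisible(x)
}
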