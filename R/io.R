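# Round-trip serialization of synapse arrays through a single JSON file:
# switch states as 0/1 vectors, weights and probabilities as numeric vectors,
# parameters inline.

#' Write a synapse array to a JSON file
#'
#' @param arr A [build_synapse_array()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_synapse_array <- function(arr, path) {
  stopifnot(inherits(arr, "compound_synapse_array"))
  payload <- list(
    K = arr$K, N = arr$N, M = arr$M, omega = arr$omega,
    pi_up = arr$pi_up, pi_down = arr$pi_down,
    params = unclass(arr$params), noise = unclass(arr$noise),
    m = as.integer(arr$m),
    state = if (!is.null(arr$state)) as.integer(arr$state),
    w = if (!is.null(arr$w)) as.numeric(arr$w),
    w_device = if (!is.null(arr$w_device)) as.numeric(arr$w_device),
    pi_up_sw = if (!is.null(arr$pi_up_sw)) as.numeric(arr$pi_up_sw),
    pi_down_sw = if (!is.null(arr$pi_down_sw)) as.numeric(arr$pi_down_sw)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a synapse array from a JSON file
#'
#' @param path Path written by [write_synapse_array()].
#' @return A `compound_synapse_array`.
#' @export
read_synapse_array <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims3 <- c(p$K, p$N, p$M)
  arr <- structure(list(
    K = as.integer(p$K), N = as.integer(p$N), M = as.integer(p$M),
    omega = p$omega, pi_up = p$pi_up, pi_down = p$pi_down,
    params = switching_params(p$params$pi_up, p$params$pi_down),
    noise = device_noise(p$noise$mode, p$noise$omega_sd,
                         p$noise$prob_noise_level, p$noise$delta,
                         p$noise$truncation),
    m = matrix(as.integer(p$m), p$K, p$N),
    state = NULL, w = NULL, w_device = NULL,
    pi_up_sw = NULL, pi_down_sw = NULL
  ), class = "compound_synapse_array")
  if (!is.null(p$state)) {
    arr$state <- array(as.logical(p$state), dims3)
  }
  if (!is.null(p$w)) arr$w <- array(p$w, dims3)
  if (!is.null(p$w_device)) arr$w_device <- array(p$w_device, dims3)
  if (!is.null(p$pi_up_sw)) arr$pi_up_sw <- array(p$pi_up_sw, dims3)
  if (!is.null(p$pi_down_sw)) arr$pi_down_sw <- array(p$pi_down_sw, dims3)
  arr
}
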