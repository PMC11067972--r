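#' Leaky integrate-and-fire parameters
#'
#' The discrete-time LIF neuron used throughout the package follows the
#' hard-reset update
#' \deqn{V^{t+1} = k_\tau V^t (1 - O^t) + \sum_k w_k O^{t}_{pre,k}, \quad
#'       O^{t+1} = \Theta(V^{t+1} - V_{th}),}
#' where \eqn{\Theta} is the Heaviside step with the convention
#' \eqn{\Theta(0) = 1} (a neuron exactly at threshold fires).
#'
#' @param k_tau membrane decay factor, in (0, 1). Default 0.25.
#' @param v_th firing threshold, > 0. Default 0.5.
#' @param T number of simulation steps, >= 1. Default 8.
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(k_tau = 0.25, v_th = 0.5, T = 8L) {
  if (!is.finite(k_tau) || k_tau <= 0 || k_tau >= 1)
    stop("`k_tau` must lie strictly in (0, 1)")
  if (!is.finite(v_th) || v_th <= 0) stop("`v_th` must be > 0")
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("`T` must be a positive integer")
  structure(list(k_tau = k_tau, v_th = v_th, T = T), class = "lif_params")
}

#' Single LIF update step
#'
#' One application of the membrane update and spike rule for a scalar neuron.
#' The hard reset multiplies the carried potential by `(1 - spiked_prev)`, so
#' a neuron that fired at the previous step integrates from zero.
#'
#' @param V membrane potential at the previous step.
#' @param spiked_prev 0/1, whether the neuron fired at the previous step.
#' @param drive summed synaptic input (including bias) at the current step.
#' @param params a [lif_params] object.
#' @return list with `V_next` (numeric) and `O_next` (0 or 1).
#' @export
lif_step <- function(V, spiked_prev, drive, params) {
  if (!all(is.finite(c(V, spiked_prev, drive))))
    stop("non-finite input to lif_step")
  if (!all(spiked_prev %in% c(0, 1))) stop("`spiked_prev` must be 0/1")
  V_next <- params$k_tau * V * (1 - spiked_prev) + drive
  list(V_next = V_next, O_next = as.numeric(V_next >= params$v_th))
}

#' Forward simulation of a layered LIF network
#'
#' Runs the network for `params$T` steps from zero initial membrane
#' potential. The drive to neuron `(i, j)` at step `t` is
#' `sum_k w[j, k] * presyn_k(t)` where the presynaptic vector is the previous
#' layer's spikes at the same step `t`, augmented with a constant-1 bias
#' channel in position 1.
#'
#' When `smooth = TRUE` the Heaviside spike is replaced by its sigmoid
#' relaxation `O = plogis((V - v_th) / smooth_width)`, giving a fully
#' differentiable surrogate network. This relaxation is what the
#' finite-difference gradient checks differentiate; it is not used for
#' training.
#'
#' @param weights a [network_weights] object.
#' @param input_spikes `M_0 x T` matrix of 0/1 input spikes (real-valued
#'   allowed when `smooth = TRUE`).
#' @param params a [lif_params] object.
#' @param smooth logical; use the smooth spike relaxation.
#' @param smooth_width steepness of the relaxation (matches the
#'   `sigmoid_derivative` surrogate width).
#' @return an object of class `spike_record`: list with `O` (list of
#'   `l + 1` matrices, element 1 being the input) and `V` (list of `l`
#'   matrices for layers `1..l`). Layers are indexed 0 (input) to `l`
#'   throughout the package.
#' @export
simulate_forward <- function(weights, input_spikes, params,
                             smooth = FALSE, smooth_width = 1) {
  input_spikes <- as.matrix(input_spikes)
  M0 <- weights$layer_sizes[1L]
  if (nrow(input_spikes) != M0 || ncol(input_spikes) != params$T)
    stop(sprintf("input_spikes must be %d x %d", M0, params$T))
  if (!smooth && !all(input_spikes %in% c(0, 1)))
    stop("input spikes must be binary")
  l <- length(weights$weights)
  Tn <- params$T
  O <- vector("list", l + 1L)
  V <- vector("list", l)
  O[[1L]] <- input_spikes
  for (i in seq_len(l)) {
    Mi <- weights$layer_sizes[i + 1L]
    O[[i + 1L]] <- matrix(0, Mi, Tn)
    V[[i]] <- matrix(0, Mi, Tn)
  }
  for (t in seq_len(Tn)) {
    for (i in seq_len(l)) {
      presyn <- c(1, O[[i]][, t])
      drive <- drop(weights$weights[[i]] %*% presyn)
      if (t == 1L) {
        v <- drive
      } else {
        v <- params$k_tau * V[[i]][, t - 1L] * (1 - O[[i + 1L]][, t - 1L]) + drive
      }
      V[[i]][, t] <- v
      O[[i + 1L]][, t] <- if (smooth) {
        plogis((v - params$v_th) / smooth_width)
      } else {
        as.numeric(v >= params$v_th)
      }
    }
  }
  structure(list(O = O, V = V, params = params,
                 smooth = smooth, smooth_width = smooth_width),
            class = "spike_record")
}

#' Constant (rate-1) spike encoding of a binary vector
#'
#' Bit `x_m = 1` becomes a spike at every one of the `T` steps; bit 0 stays
#' silent. This is the deterministic encoder used for the XOR task.
#'
#' @param x binary vector.
#' @param T number of time steps.
#' @return `length(x) x T` binary matrix.
#' @export
encode_constant <- function(x, T) {
  if (!all(x %in% c(0, 1))) stop("`x` entries must be 0/1")
  matrix(rep(as.numeric(x), T), nrow = length(x), ncol = T)
}

#' Poisson (Bernoulli-per-step) rate encoding
#'
#' Each input channel with rate `r_m` in `[0, 1]` spikes independently at each
#' step with probability `r_m`, using the current RNG state. Provided as the
#' stochastic alternative to [encode_constant]; seed it explicitly for
#' reproducible batches.
#'
#' @param rates numeric vector of per-channel firing probabilities in [0, 1].
#' @param T number of time steps.
#' @return `length(rates) x T` binary matrix.
#' @export
encode_poisson <- function(rates, T) {
  if (any(rates < 0 | rates > 1)) stop("`rates` must lie in [0, 1]")
  matrix(rbinom(length(rates) * T, 1L, rep(rates, T)),
         nrow = length(rates), ncol = T)
}

#' Rate decoding of a spike record
#'
#' Per-neuron mean firing rate `(1/T) sum_t O^t` of the requested layer
#' (0 = input, `l` = output; default output).
#'
#' @param record a `spike_record`.
#' @param layer layer index in `0..l`; `NULL` means the output layer.
#' @return numeric vector of rates in [0, 1].
#' @export
rate_decode <- function(record, layer = NULL) {
  l <- length(record$V)
  if (is.null(layer)) layer <- l
  if (layer < 0L || layer > l) stop("invalid layer index")
  O <- record$O[[layer + 1L]]
  if (ncol(O) == 0L) return(rep(0, nrow(O)))
  rowMeans(O)
}

#' Export a spike record as CSV
#'
#' Long format with columns `layer, neuron, t, V, O`. The input layer
#' (layer 0) has no membrane potential; its `V` is `NA`.
#'
#' @param record a `spike_record`.
#' @param path output file path.
#' @export
write_spike_record_csv <- function(record, path) {
  rows <- list()
  for (li in seq_along(record$O)) {
    O <- record$O[[li]]
    V <- if (li == 1L) matrix(NA_real_, nrow(O), ncol(O)) else record$V[[li - 1L]]
    rows[[li]] <- data.frame(
      layer = li - 1L,
      neuron = rep(seq_len(nrow(O)), times = ncol(O)),
      t = rep(seq_len(ncol(O)), each = nrow(O)),
      V = as.numeric(V),
      O = as.numeric(O))
  }
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
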