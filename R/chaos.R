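#' Chaotic-loss configuration
#'
#' Controls the neuron-intrinsic chaotic term added to the task loss. Every
#' masked neuron `(i, j)` contributes
#' \deqn{-z [ I_0 \ln h_{ij} + (1 - I_0) \ln(1 - h_{ij}) ],}
#' where `h_ij` is the sigmoid of its time-averaged drive (see
#' [hidden_activity]). A single scalar intensity `z` is shared by all masked
#' neurons and annealed geometrically, `z <- beta * z`, after every
#' full-batch update (chaotic simulated annealing).
#'
#' @param z0 initial chaos intensity, >= 0. Default 20.
#' @param beta annealing constant in (0, 1). Default 0.9995.
#' @param I0 target hidden activity in (0, 1). Default 0.65.
#' @param mask which neurons receive the chaotic term: `"all"` (default), or
#'   a list with one integer vector of neuron indices per layer `1..l`
#'   (empty vector = no chaos in that layer).
#' @param anneal_granularity `"per_batch"` (default) or `"per_epoch"`. With
#'   full-batch training, as used for the desk-scale tasks here, the two
#'   coincide (one batch per epoch).
#' @param include_bias logical; whether the chaotic gradient is applied to
#'   the bias column as well (the drive inside `h` always includes the bias
#'   channel `s_0 = 1`). Default `TRUE`.
#' @return an object of class `chaos_config`.
#' @export
chaos_config <- function(z0 = 20, beta = 0.9995, I0 = 0.65, mask = "all",
                         anneal_granularity = c("per_batch", "per_epoch"),
                         include_bias = TRUE) {
  if (!is.finite(z0) || z0 < 0) stop("`z0` must be >= 0")
  if (!is.finite(beta) || beta <= 0 || beta >= 1)
    stop("`beta` must lie strictly in (0, 1)")
  if (!is.finite(I0) || I0 <= 0 || I0 >= 1)
    stop("`I0` must lie strictly in (0, 1)")
  anneal_granularity <- match.arg(anneal_granularity)
  structure(list(z0 = z0, beta = beta, I0 = I0, mask = mask,
                 anneal_granularity = anneal_granularity,
                 include_bias = isTRUE(include_bias)),
            class = "chaos_config")
}

# Resolve a chaos mask against layer sizes -> list of integer vectors
resolve_mask <- function(mask, layer_sizes) {
  l <- length(layer_sizes) - 1L
  if (identical(mask, "all"))
    return(lapply(seq_len(l), function(i) seq_len(layer_sizes[i + 1L])))
  if (identical(mask, "none") || is.null(mask))
    return(replicate(l, integer(0), simplify = FALSE))
  if (!is.list(mask) || length(mask) != l)
    stop("mask must be \"all\", \"none\", or a list with one entry per layer")
  out <- lapply(seq_len(l), function(i) {
    idx <- as.integer(mask[[i]])
    if (any(idx < 1L | idx > layer_sizes[i + 1L]))
      stop(sprintf("mask layer %d references nonexistent neurons", i))
    idx
  })
  out
}

#' Mean presynaptic activity for a layer
#'
#' The time-averaged presynaptic spike vector feeding layer `i`:
#' `s_k = (1/T) sum_t O_{i-1,k}^t` for `k = 1..M_{i-1}`, with the constant
#' bias channel `s_0 = 1` prepended in position 1.
#'
#' @param record a `spike_record`.
#' @param layer post-synaptic layer index in `1..l`.
#' @return numeric vector of length `M_{i-1} + 1`, entries in [0, 1].
#' @export
mean_presyn_activity <- function(record, layer) {
  l <- length(record$V)
  if (layer < 1L || layer > l) stop("invalid layer index")
  c(1, rate_decode(record, layer - 1L))
}

#' Hidden activity of a neuron
#'
#' `h = sigmoid(<w, s>)`, the sigmoid of the time-averaged weighted drive,
#' including the bias via `s_0 = 1`. Always strictly inside (0, 1).
#'
#' @param weights_row the neuron's weight row (bias first).
#' @param s mean presynaptic activity from [mean_presyn_activity].
#' @return scalar `h` in (0, 1).
#' @export
hidden_activity <- function(weights_row, s) {
  if (length(weights_row) != length(s)) stop("length mismatch")
  plogis(sum(weights_row * s))
}

#' Value of the chaotic loss for one neuron
#'
#' `-z * (I0 * log(h) + (1 - I0) * log(1 - h))`: the cross-entropy of `h`
#' against the constant target `I0`, scaled by the chaos intensity. Strictly
#' convex in `h` with its unique minimum at `h = I0`. `h` is clamped to
#' `[1e-12, 1 - 1e-12]` inside the logs only; the analytic gradient path
#' needs no clamp.
#'
#' @param h hidden activity in (0, 1).
#' @param z chaos intensity, >= 0.
#' @param I0 target activity in (0, 1).
#' @return scalar loss, >= 0.
#' @export
chaotic_loss_value <- function(h, z, I0) {
  if (any(h <= 0 | h >= 1)) stop("`h` must lie strictly in (0, 1)")
  hc <- pmin(pmax(h, 1e-12), 1 - 1e-12)
  -z * (I0 * log(hc) + (1 - I0) * log(1 - hc))
}

#' Analytic gradient of the chaotic loss
#'
#' The derivative of the chaotic loss with respect to weight `w_ijk`
#' collapses analytically: the `1/(h(1-h))` of the cross-entropy cancels the
#' `h(1-h)` of the sigmoid, leaving
#' \deqn{\partial loss_{chaos} / \partial w_{ijk} = -z (I_0 - h) s_k.}
#' Implemented in this cancelled form (never as the quotient), so it is
#' finite for all `h` in (0, 1) however extreme.
#'
#' @param z chaos intensity.
#' @param I0 target activity.
#' @param h hidden activity of the neuron.
#' @param s_k mean presynaptic activity (vectorised over `k`).
#' @return gradient entries `-z * (I0 - h) * s_k`.
#' @export
chaotic_gradient <- function(z, I0, h, s_k) {
  -z * (I0 - h) * s_k
}

#' One annealing step of the chaos intensity
#'
#' Geometric decay `z <- beta * z`; `m` applications give `z0 * beta^m`.
#'
#' @param z current intensity, >= 0.
#' @param beta annealing constant in (0, 1).
#' @return the annealed intensity.
#' @export
anneal <- function(z, beta) {
  if (z < 0) stop("`z` must be >= 0")
  if (beta <= 0 || beta >= 1) stop("`beta` must lie in (0, 1)")
  beta * z
}

#' Logistic-map chaos source (ablation)
#'
#' External, non-neuron-intrinsic chaos used to ablate the intrinsic chaotic
#' term: each weight carries an independent logistic-map state
#' `x <- 4 x (1 - x)` and receives the additive perturbation
#' `z * (x_next - 0.5)` in place of the intrinsic chaotic term.
#'
#' @param state current logistic state in (0, 1).
#' @param z chaos intensity.
#' @return list with `perturbation` and `next_state`.
#' @export
logistic_chaos_term <- function(state, z) {
  if (any(state <= 0 | state >= 1)) stop("`state` must lie strictly in (0, 1)")
  next_state <- 4 * state * (1 - state)
  list(perturbation = z * (next_state - 0.5), next_state = next_state)
}
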