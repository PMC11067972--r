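#' Surrogate derivative specification
#'
#' The spike nonlinearity is a Heaviside step, whose derivative is zero
#' almost everywhere; backpropagation replaces it with a surrogate.
#' Two standard shapes are provided:
#' \describe{
#'   \item{rectangular}{`1/width` for `|u| <= width/2`, else 0 — a boxcar
#'     window around threshold.}
#'   \item{sigmoid_derivative}{`sigma'(u / width) / width`, the exact
#'     derivative of the sigmoid relaxation `sigma(u / width)`.}
#' }
#' where `u = V - v_th` is the distance to threshold.
#'
#' @param kind `"rectangular"` (default) or `"sigmoid_derivative"`.
#' @param width support / steepness parameter, > 0. Default 1.
#' @return an object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(kind = c("rectangular", "sigmoid_derivative"),
                           width = 1) {
  kind <- match.arg(kind)
  if (!is.finite(width) || width <= 0) stop("`width` must be > 0")
  structure(list(kind = kind, width = width), class = "surrogate_spec")
}

#' Evaluate the surrogate derivative
#'
#' @param u numeric (vectorised): membrane potential minus threshold.
#' @param spec a [surrogate_spec].
#' @return numeric, the surrogate pseudo-derivative at `u`.
#' @export
surrogate_derivative <- function(u, spec) {
  switch(spec$kind,
    rectangular = ifelse(abs(u) <= spec$width / 2, 1 / spec$width, 0),
    sigmoid_derivative = {
      s <- plogis(u / spec$width)
      s * (1 - s) / spec$width
    })
}

#' Task loss specification
#'
#' Losses act on the rate-decoded output layer. `mse_rate` is the mean over
#' output neurons of squared rate error; `cross_entropy_rate` is the mean
#' binary cross-entropy of the rates against the targets (rates clamped to
#' `[1e-12, 1 - 1e-12]` inside the logs).
#'
#' @param kind `"mse_rate"` (default) or `"cross_entropy_rate"`.
#' @param target numeric vector of per-output-neuron target rates.
#' @return an object of class `loss_spec`.
#' @export
loss_spec <- function(kind = c("mse_rate", "cross_entropy_rate"), target) {
  kind <- match.arg(kind)
  target <- as.numeric(target)
  if (!all(is.finite(target))) stop("non-finite target")
  structure(list(kind = kind, target = target), class = "loss_spec")
}

#' Task-loss value of a spike record
#'
#' @param record a `spike_record`.
#' @param spec a [loss_spec]; `spec$target` must match the output layer size.
#' @return scalar loss, >= 0.
#' @export
loss_bp_value <- function(record, spec) {
  r <- rate_decode(record)
  if (length(r) != length(spec$target))
    stop("target length does not match output layer size")
  switch(spec$kind,
    mse_rate = mean((r - spec$target)^2),
    cross_entropy_rate = {
      rc <- pmin(pmax(r, 1e-12), 1 - 1e-12)
      -mean(spec$target * log(rc) + (1 - spec$target) * log(1 - rc))
    })
}

# dL/d(rate) for each output neuron
loss_rate_grad <- function(rates, spec) {
  switch(spec$kind,
    mse_rate = 2 * (rates - spec$target) / length(rates),
    cross_entropy_rate = {
      rc <- pmin(pmax(rates, 1e-12), 1 - 1e-12)
      (-spec$target / rc + (1 - spec$target) / (1 - rc)) / length(rates)
    })
}

#' Surrogate-gradient backpropagation through time
#'
#' Unrolls the LIF recursion over `t = T..1` and backpropagates the task loss
#' with the spike derivative replaced by [surrogate_derivative]. Two choices
#' for the hard reset's factor `(1 - O^t)`:
#' \describe{
#'   \item{detach}{(default) the factor is treated as a constant during
#'     differentiation — no gradient flows through the reset. The standard,
#'     numerically stable convention.}
#'   \item{through}{the dependence `dV^{t+1}/dO^t = -k_tau V^t` is kept, with
#'     the same surrogate applied to `dO^t/dV^t`. With `smooth = TRUE` this
#'     is the exact chain rule of the relaxed network, which the
#'     finite-difference tests rely on.}
#' }
#'
#' @param weights a [network_weights] object.
#' @param input_spikes `M_0 x T` input matrix.
#' @param params a [lif_params] object.
#' @param loss a [loss_spec].
#' @param sg a [surrogate_spec].
#' @param reset_grad `"detach"` or `"through"`.
#' @param smooth run the forward pass with the sigmoid spike relaxation of
#'   width `sg$width` (see [simulate_forward]); requires
#'   `sg$kind == "sigmoid_derivative"` so the backward pass is its exact
#'   derivative.
#' @param record optional precomputed `spike_record` for these inputs.
#' @return list of gradient matrices shaped like `weights$weights`, with
#'   attribute `"loss"` holding the forward loss value.
#' @export
backprop_bptt <- function(weights, input_spikes, params, loss, sg,
                          reset_grad = c("detach", "through"),
                          smooth = FALSE, record = NULL) {
  reset_grad <- match.arg(reset_grad)
  if (smooth && sg$kind != "sigmoid_derivative")
    stop("smooth forward requires the sigmoid_derivative surrogate")
  if (is.null(record))
    record <- simulate_forward(weights, input_spikes, params,
                               smooth = smooth, smooth_width = sg$width)
  l <- length(weights$weights)
  Tn <- params$T
  rates <- rate_decode(record)
  if (length(rates) != length(loss$target))
    stop("target length does not match output layer size")
  dO_out <- loss_rate_grad(rates, loss) / Tn   # dL/dO_{l,j}^t, same for all t

  grads <- vector("list", l)
  deltaV_next <- NULL  # deltaV of layer i+1, M_{i+1} x T
  for (i in rev(seq_len(l))) {
    Vi <- record$V[[i]]
    Oi <- record$O[[i + 1L]]
    Mi <- nrow(Vi)
    g <- matrix(surrogate_derivative(Vi - params$v_th, sg), Mi, Tn)
    deltaV <- matrix(0, Mi, Tn)
    W_next_syn <- if (i < l) weights$weights[[i + 1L]][, -1L, drop = FALSE]
    for (t in rev(seq_len(Tn))) {
      dO <- if (i == l) dO_out else drop(crossprod(W_next_syn, deltaV_next[, t]))
      if (reset_grad == "through" && t < Tn) {
        dO <- dO + deltaV[, t + 1L] * (-params$k_tau * Vi[, t])
      }
      dv <- dO * g[, t]
      if (t < Tn) dv <- dv + deltaV[, t + 1L] * params$k_tau * (1 - Oi[, t])
      deltaV[, t] <- dv
    }
    presyn <- rbind(1, record$O[[i]])  # (M_{i-1}+1) x T
    gi <- deltaV %*% t(presyn)
    if (!all(is.finite(gi)))
      stop(sprintf("non-finite gradient in layer %d", i))
    grads[[i]] <- gi
    deltaV_next <- deltaV
  }
  attr(grads, "loss") <- loss_bp_value(record, loss)
  grads
}

#' Plain gradient-descent weight update
#'
#' `w <- w - eta * gradient`, elementwise over every layer matrix.
#'
#' @param weights a [network_weights] object.
#' @param gradient list of matrices shaped like `weights$weights`.
#' @param eta learning rate, > 0.
#' @return updated [network_weights].
#' @export
bp_update <- function(weights, gradient, eta) {
  if (!is.finite(eta) || eta <= 0) stop("`eta` must be > 0")
  if (length(gradient) != length(weights$weights)) stop("shape mismatch")
  w <- weights$weights
  for (i in seq_along(w)) {
    if (!all(dim(gradient[[i]]) == dim(w[[i]]))) stop("shape mismatch")
    w[[i]] <- w[[i]] - eta * gradient[[i]]
  }
  network_weights(w, weights$layer_sizes)
}

#' Export a gradient (or any weight-shaped list) as CSV
#'
#' Long format `layer, row, col, value`; `col` counts from 0 so the bias
#' column is 0, matching the subscript convention `w_{ijk}` with `k = 0` for
#' the bias.
#'
#' @param gradient list of matrices.
#' @param path output file path.
#' @export
write_gradient_csv <- function(gradient, path) {
  rows <- lapply(seq_along(gradient), function(i) {
    m <- gradient[[i]]
    data.frame(layer = i,
               row = rep(seq_len(nrow(m)), times = ncol(m)),
               col = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
               value = as.numeric(m))
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
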