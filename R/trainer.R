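#' Training state
#'
#' The mutable state of a run: current weights, chaos intensity `z`,
#' iteration counter `m` (the pseudo-time of the weight-update map) and
#' learning rate.
#'
#' @param weights a [network_weights] object.
#' @param z current chaos intensity, >= 0.
#' @param m iteration counter, >= 0.
#' @param eta learning rate, > 0.
#' @return an object of class `train_state`.
#' @export
train_state <- function(weights, z, m = 0L, eta = 0.1) {
  if (!is.finite(z) || z < 0) stop("`z` must be >= 0")
  if (!is.finite(eta) || eta <= 0) stop("`eta` must be > 0")
  structure(list(weights = weights, z = z, m = as.integer(m), eta = eta),
            class = "train_state")
}

#' Combine the task gradient with the chaotic term
#'
#' On masked rows the combined gradient is `grad_bp + grad_chaos`, i.e.
#' `grad_bp - z * (I0 - h) * s` entrywise, so that
#' `w <- w - eta * combined` is exactly the three-term chaotic update
#' (task-gradient descent plus the annealed negative-feedback term). On all
#' other rows it is `grad_bp` unchanged — this is the "plug-in" contract: any
#' baseline optimizer can consume the combined gradient in place of its own.
#'
#' When the chaos term is absent (`chaos_terms = NULL` or an empty mask) the
#' returned object is `grad_bp` itself, bitwise.
#'
#' @param grad_bp list of task-gradient matrices.
#' @param chaos_terms list of chaotic-gradient matrices (same shapes), or
#'   `NULL`.
#' @param mask list of masked neuron (row) indices per layer, as produced by
#'   `resolve_mask`.
#' @return list of combined gradient matrices.
#' @export
combine_gradients <- function(grad_bp, chaos_terms, mask) {
  if (is.null(chaos_terms)) return(grad_bp)
  out <- grad_bp
  for (i in seq_along(out)) {
    rows <- mask[[i]]
    if (length(rows) == 0L) next
    if (any(rows > nrow(out[[i]])))
      stop(sprintf("mask layer %d references nonexistent rows", i))
    out[[i]][rows, ] <- out[[i]][rows, , drop = FALSE] +
      chaos_terms[[i]][rows, , drop = FALSE]
  }
  out
}

# Full-batch task gradient + chaotic gradient at intensity z.
# batch: list(inputs = list of M0 x T matrices, targets = M_l x n matrix)
# Returns list(grad_bp, grad_chaos (NULL if z == 0 or empty mask),
#              loss_bp, loss_chaos)
batch_gradients <- function(weights, batch, params, loss_kind, sg, z, I0,
                            mask, include_bias) {
  n <- length(batch$inputs)
  l <- length(weights$weights)
  grad_bp <- lapply(weights$weights, function(m) array(0, dim(m)))
  any_chaos <- z > 0 && any(vapply(mask, length, integer(1)) > 0L)
  grad_ch <- if (any_chaos)
    lapply(weights$weights, function(m) array(0, dim(m))) else NULL
  loss_bp <- 0
  loss_ch <- 0
  for (nidx in seq_len(n)) {
    loss <- loss_spec(loss_kind, batch$targets[, nidx])
    rec <- simulate_forward(weights, batch$inputs[[nidx]], params)
    g <- backprop_bptt(weights, batch$inputs[[nidx]], params, loss, sg,
                       record = rec)
    for (i in seq_len(l)) grad_bp[[i]] <- grad_bp[[i]] + g[[i]] / n
    loss_bp <- loss_bp + attr(g, "loss") / n
    if (any_chaos) {
      for (i in seq_len(l)) {
        rows <- mask[[i]]
        if (length(rows) == 0L) next
        s <- mean_presyn_activity(rec, i)
        for (j in rows) {
          h <- hidden_activity(weights$weights[[i]][j, ], s)
          gc <- chaotic_gradient(z, I0, h, s)
          if (!include_bias) gc[1L] <- 0
          grad_ch[[i]][j, ] <- grad_ch[[i]][j, ] + gc / n
          # plogis saturates to exactly 0/1 for |drive| beyond ~37; the loss
          # logs need the same clamp the compiled engine applies
          hc <- min(max(h, 1e-12), 1 - 1e-12)
          loss_ch <- loss_ch + chaotic_loss_value(hc, z, I0) / n
        }
      }
    }
  }
  list(grad_bp = grad_bp, grad_chaos = grad_ch,
       loss_bp = loss_bp, loss_chaos = loss_ch)
}

#' One full-batch chaotic training step
#'
#' A single application of the weight-update map `G`: forward-simulate the
#' batch, backpropagate the task loss, evaluate the chaotic gradients of the
#' masked neurons at the current intensity `z`, combine, take one
#' gradient-descent step, anneal `z`, and increment `m`. Deterministic given
#' the state and batch. With `z = 0` the step is exactly (bit-for-bit) the
#' baseline surrogate-gradient step: the chaos path is not entered at all.
#'
#' @param state a [train_state].
#' @param batch list with `inputs` (list of `M_0 x T` spike matrices) and
#'   `targets` (`M_l x n` matrix of target rates).
#' @param params a [lif_params].
#' @param sg a [surrogate_spec].
#' @param chaos a [chaos_config] (its `z0` is ignored; `state$z` is used).
#' @param loss_kind `"mse_rate"` or `"cross_entropy_rate"`.
#' @return the successor [train_state], with attributes `"loss_bp"` and
#'   `"loss_chaos"`.
#' @export
csbp_step <- function(state, batch, params, sg, chaos,
                      loss_kind = "mse_rate") {
  mask <- resolve_mask(chaos$mask, state$weights$layer_sizes)
  bg <- batch_gradients(state$weights, batch, params, loss_kind, sg,
                        state$z, chaos$I0, mask, chaos$include_bias)
  combined <- combine_gradients(bg$grad_bp, bg$grad_chaos, mask)
  new_w <- bp_update(state$weights, combined, state$eta)
  new_z <- anneal(state$z, chaos$beta)
  out <- train_state(new_w, new_z, state$m + 1L, state$eta)
  attr(out, "loss_bp") <- bg$loss_bp
  attr(out, "loss_chaos") <- bg$loss_chaos
  out
}

#' Train a spiking network with the chaotic update
#'
#' Full-batch training on a built-in task. Weights are initialised uniformly
#' on `init_interval` from `seed`; each epoch is one full-batch update, so
#' epochs and iterations of the update map coincide. The chaos intensity
#' starts at `chaos$z0` and is annealed after every update; `z0 = 0` gives
#' the plain surrogate-gradient baseline.
#'
#' @param task `"xor"` or `"regression"`.
#' @param arch integer vector of layer sizes, e.g. `c(2, 5, 2)`.
#' @param params a [lif_params].
#' @param chaos a [chaos_config].
#' @param sg a [surrogate_spec].
#' @param loss_kind `"mse_rate"` (default) or `"cross_entropy_rate"`.
#' @param eta learning rate.
#' @param epochs number of full-batch updates, >= 1.
#' @param seed integer seed for weight initialisation (and for the encoder
#'   when the task uses a stochastic one).
#' @param init_interval weight initialisation interval, default `c(-1, 1)`.
#' @param track list of tracked weight indices, each `c(layer, row, col)`
#'   with `col = 0` for the bias (e.g. `list(c(2, 2, 0))` tracks `w_220`).
#' @param engine `"cpp"` (default, compiled hot loop) or `"r"` (reference
#'   implementation; identical arithmetic, orders of magnitude slower).
#' @param record_weights keep the full flattened weight vector at every
#'   epoch (needed by [windowed_lyapunov]).
#' @return a `data.frame` of class `trajectory_log` with columns `m`, `z`,
#'   `loss_bp`, `loss_chaos` and one `w_<layer><row><col>` column per tracked
#'   weight. Attributes: `final_weights` ([network_weights]), `config`
#'   (the run configuration), and optionally `weights_history`
#'   (epochs x n_params matrix).
#' @export
train <- function(task = c("xor", "regression"), arch = c(2, 5, 2),
                  params = lif_params(), chaos = chaos_config(),
                  sg = surrogate_spec(), loss_kind = "mse_rate",
                  eta = 0.1, epochs = 100L, seed = 0L,
                  init_interval = c(-1, 1),
                  track = list(c(2, 2, 0)),
                  engine = c("cpp", "r"), record_weights = FALSE) {
  task <- match.arg(task)
  engine <- match.arg(engine)
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("`epochs` must be >= 1")
  set.seed(as.integer(seed))
  batch <- task_batch(task, arch, params)
  weights <- random_weights(arch, init_interval)
  mask <- resolve_mask(chaos$mask, weights$layer_sizes)
  track <- validate_track(track, weights)

  if (engine == "cpp") {
    res <- csbp_train_cpp(
      weights$weights, batch$inputs, batch$targets,
      params$k_tau, params$v_th, params$T,
      match(sg$kind, c("rectangular", "sigmoid_derivative")) - 1L, sg$width,
      match(loss_kind, c("mse_rate", "cross_entropy_rate")) - 1L,
      eta, chaos$z0, chaos$beta, chaos$I0,
      mask, chaos$include_bias, epochs,
      track_matrix(track), record_weights)
    log <- as.data.frame(res$log)
    final_w <- network_weights(res$weights, weights$layer_sizes)
    hist <- res$weights_hist
  } else {
    state <- train_state(weights, chaos$z0, 0L, eta)
    nw <- length(flatten_weights(weights))
    log <- matrix(NA_real_, epochs, 4L + length(track))
    hist <- if (record_weights) matrix(NA_real_, epochs, nw) else NULL
    for (ep in seq_len(epochs)) {
      z_used <- state$z
      state <- csbp_step(state, batch, params, sg, chaos, loss_kind)
      log[ep, ] <- c(ep - 1L, z_used, attr(state, "loss_bp"),
                     attr(state, "loss_chaos"),
                     vapply(track, function(ix)
                       state$weights$weights[[ix[1L]]][ix[2L], ix[3L] + 1L],
                       numeric(1)))
      if (record_weights) hist[ep, ] <- flatten_weights(state$weights)
    }
    log <- as.data.frame(log)
    final_w <- state$weights
  }
  names(log) <- c("m", "z", "loss_bp", "loss_chaos",
                  vapply(track, function(ix)
                    paste0("w_", ix[1L], ix[2L], ix[3L]), character(1)))
  attr(log, "final_weights") <- final_w
  attr(log, "config") <- list(
    task = task, arch = arch, params = params, chaos = chaos, sg = sg,
    loss_kind = loss_kind, eta = eta, epochs = epochs, seed = seed,
    init_interval = init_interval, track = track)
  attr(log, "batch") <- batch
  if (!is.null(hist)) attr(log, "weights_history") <- hist
  class(log) <- c("trajectory_log", "data.frame")
  log
}

validate_track <- function(track, weights) {
  lapply(track, function(ix) {
    ix <- as.integer(ix)
    if (length(ix) != 3L) stop("track entries must be c(layer, row, col)")
    if (ix[1L] < 1L || ix[1L] > length(weights$weights))
      stop("tracked layer out of range")
    m <- weights$weights[[ix[1L]]]
    if (ix[2L] < 1L || ix[2L] > nrow(m) || ix[3L] < 0L || ix[3L] > ncol(m) - 1L)
      stop("tracked weight index out of range")
    ix
  })
}

track_matrix <- function(track) {
  if (length(track) == 0L) return(matrix(0L, 0L, 3L))
  do.call(rbind, track)
}

#' Write a trajectory log as CSV
#'
#' Columns `m, z, loss_bp, loss_chaos` plus one column per tracked weight.
#'
#' @param log a `trajectory_log`.
#' @param path output file path.
#' @export
write_trajectory_csv <- function(log, path) {
  write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory log CSV
#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  read.csv(path)
}

#' Predicted classes from a trained network
#'
#' Forward-simulates each batch input with the given weights and returns the
#' argmax of the output rates; exact rate ties break toward the first
#' (lowest-index) class.
#'
#' @param weights a [network_weights].
#' @param batch a task batch (see [task_batch]).
#' @param params a [lif_params].
#' @return integer vector of 0-based class labels.
#' @export
predict_classes <- function(weights, batch, params) {
  vapply(batch$inputs, function(inp) {
    r <- rate_decode(simulate_forward(weights, inp, params))
    which.max(r) - 1L   # which.max takes the first maximum: ties -> class 0
  }, integer(1))
}
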