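#' Layered weight container for a spiking network
#'
#' A feed-forward network with layer sizes `M_0, ..., M_l` is parameterised by
#' one weight matrix per layer `i = 1..l` of shape `M_i x (M_{i-1} + 1)`.
#' Column 1 of each matrix is the bias: during simulation the presynaptic
#' layer is augmented with a constant-1 pseudo-spike channel at index 0, so
#' `w[j, 1]` is the bias of neuron `j` and `w[j, k + 1]` the weight from
#' presynaptic neuron `k`.
#'
#' @param weights list of numeric matrices, one per layer, with
#'   `ncol(weights[[i]]) == nrow(weights[[i - 1]]) + 1` (and
#'   `ncol(weights[[1]]) == M_0 + 1`).
#' @param layer_sizes optional integer vector `c(M_0, ..., M_l)`; inferred
#'   from the matrices when omitted.
#' @return an object of class `network_weights`.
#' @export
network_weights <- function(weights, layer_sizes = NULL) {
  if (!is.list(weights) || length(weights) < 1L)
    stop("`weights` must be a non-empty list of matrices")
  weights <- lapply(weights, function(w) {
    w <- as.matrix(w)
    storage.mode(w) <- "double"
    w
  })
  inferred <- c(ncol(weights[[1L]]) - 1L, vapply(weights, nrow, integer(1)))
  if (is.null(layer_sizes)) layer_sizes <- inferred
  layer_sizes <- as.integer(layer_sizes)
  if (!identical(layer_sizes, inferred))
    stop("`layer_sizes` inconsistent with matrix shapes")
  if (any(layer_sizes < 1L)) stop("all layer sizes must be positive")
  for (i in seq_along(weights)) {
    if (ncol(weights[[i]]) != layer_sizes[i] + 1L)
      stop(sprintf("layer %d: expected %d columns (bias + presynaptic), got %d",
                   i, layer_sizes[i] + 1L, ncol(weights[[i]])))
    if (!all(is.finite(weights[[i]])))
      stop(sprintf("layer %d: non-finite weight entries", i))
  }
  structure(list(layer_sizes = layer_sizes, weights = weights),
            class = "network_weights")
}

#' Random uniform weight initialisation
#'
#' Draws every weight and bias independently from `U(interval[1], interval[2])`
#' using the current RNG state (callers seed via [set.seed()] or the `seed`
#' argument of [train()]).
#'
#' @param layer_sizes integer vector `c(M_0, ..., M_l)`.
#' @param interval length-2 numeric, the support of the uniform draw.
#'   `c(0, 0)` yields an all-zero network (degenerate but valid).
#' @return a [network_weights] object.
#' @export
random_weights <- function(layer_sizes, interval = c(-1, 1)) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) stop("need at least input and output layer")
  if (length(interval) != 2L || interval[1] > interval[2])
    stop("`interval` must be c(lo, hi) with lo <= hi")
  l <- length(layer_sizes) - 1L
  w <- vector("list", l)
  for (i in seq_len(l)) {
    n <- layer_sizes[i + 1L] * (layer_sizes[i] + 1L)
    vals <- if (interval[1] == interval[2]) rep(interval[1], n)
            else runif(n, interval[1], interval[2])
    w[[i]] <- matrix(vals, nrow = layer_sizes[i + 1L])
  }
  network_weights(w, layer_sizes)
}

#' @export
print.network_weights <- function(x, ...) {
  cat("<network_weights> [", paste(x$layer_sizes, collapse = ","), "], ",
      sum(vapply(x$weights, length, integer(1))), " parameters\n", sep = "")
  invisible(x)
}

#' Flatten network weights to a vector / restore from a vector
#'
#' Used by the dynamical-systems tools, which view the training update as a
#' map on the flat parameter vector `W`. Order: layer 1..l, column-major
#' within each matrix.
#'
#' @param nw a [network_weights] object.
#' @return `flatten_weights`: numeric vector.
#' @export
flatten_weights <- function(nw) {
  unlist(lapply(nw$weights, as.numeric), use.names = FALSE)
}

#' @rdname flatten_weights
#' @param x numeric vector of length `sum(M_i * (M_{i-1} + 1))`.
#' @param template a [network_weights] object supplying the shapes.
#' @return `unflatten_weights`: a [network_weights] object.
#' @export
unflatten_weights <- function(x, template) {
  sizes <- vapply(template$weights, length, integer(1))
  if (length(x) != sum(sizes)) stop("weight vector has wrong length")
  idx <- c(0L, cumsum(sizes))
  w <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    w[[i]] <- matrix(x[(idx[i] + 1L):idx[i + 1L]],
                     nrow = nrow(template$weights[[i]]))
  }
  network_weights(w, template$layer_sizes)
}

#' Write / read network weights as JSON
#'
#' Nested-list layout keyed `layer_sizes` and `weights` (row-major lists per
#' layer), readable by [jsonlite::fromJSON].
#'
#' @param nw a [network_weights] object.
#' @param path file path.
#' @export
write_weights_json <- function(nw, path) {
  obj <- list(layer_sizes = nw$layer_sizes,
              weights = lapply(nw$weights, function(m) apply(m, 1L, c, simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_weights_json
#' @export
read_weights_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  w <- lapply(obj$weights, function(rows) {
    if (is.matrix(rows)) rows else do.call(rbind, rows)
  })
  network_weights(w, as.integer(obj$layer_sizes))
}
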