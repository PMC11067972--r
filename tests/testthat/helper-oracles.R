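# Independent scalar-loop oracle for the layered LIF forward pass: nested
# loops over (layer, neuron, time), no matrix ops, written directly from the
# membrane update rule. Deliberately duplicates nothing from R/lif.R.
oracle_forward <- function(weights, input_spikes, k_tau, v_th, Tn) {
  sizes <- weights$layer_sizes
  l <- length(weights$weights)
  O <- vector("list", l + 1L)
  V <- vector("list", l)
  O[[1]] <- input_spikes
  for (i in 1:l) {
    O[[i + 1]] <- matrix(0, sizes[i + 1], Tn)
    V[[i]] <- matrix(0, sizes[i + 1], Tn)
  }
  for (t in 1:Tn) {
    for (i in 1:l) {
      for (j in 1:sizes[i + 1]) {
        drive <- weights$weights[[i]][j, 1]
        for (k in 1:sizes[i]) {
          drive <- drive + weights$weights[[i]][j, k + 1] * O[[i]][k, t]
        }
        if (t == 1) {
          v <- drive
        } else {
          carried <- if (O[[i + 1]][j, t - 1] == 1) 0 else k_tau * V[[i]][j, t - 1]
          v <- carried + drive
        }
        V[[i]][j, t] <- v
        O[[i + 1]][j, t] <- if (v >= v_th) 1 else 0
      }
    }
  }
  list(O = O, V = V)
}

# Random small network + binary input, from the current RNG state
random_case <- function(arch = c(2, 3, 2), Tn = 8, interval = c(-1.5, 1.5)) {
  w <- random_weights(arch, interval)
  inp <- matrix(rbinom(arch[1] * Tn, 1, 0.5), arch[1], Tn)
  list(weights = w, input = inp, params = lif_params(T = Tn))
}

# The standard XOR batch used across tests
xor_batch <- function(params = lif_params()) task_batch("xor", c(2, 5, 2), params)
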