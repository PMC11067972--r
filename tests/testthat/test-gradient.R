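test_that("surrogate derivatives evaluate their defining formulas", {
  rect <- surrogate_spec("rectangular", width = 1)
  sig <- surrogate_spec("sigmoid_derivative", width = 1)
  expect_equal(surrogate_derivative(0, rect), 1)
  expect_equal(surrogate_derivative(0.5, rect), 1)    # boundary inside
  expect_equal(surrogate_derivative(1, rect), 0)
  expect_equal(surrogate_derivative(0, sig), 0.25)
  w2 <- surrogate_spec("rectangular", width = 2)
  expect_equal(surrogate_derivative(0.9, w2), 0.5)
  expect_error(surrogate_spec("rectangular", width = 0), "width")
})

test_that("loss values match direct formula evaluation", {
  p <- lif_params(T = 4)
  w <- network_weights(list(matrix(c(10, 0, -10, 0), 2, 2)))  # rates 1, 0
  rec <- simulate_forward(w, matrix(0, 1, 4), p)
  expect_equal(rate_decode(rec), c(1, 0))
  expect_equal(loss_bp_value(rec, loss_spec("mse_rate", c(1, 0))), 0)
  expect_equal(loss_bp_value(rec, loss_spec("mse_rate", c(0, 1))), 1)
  # random case against the formula written out longhand
  set.seed(33)
  cs <- random_case(c(2, 3, 2), Tn = 8)
  rec <- simulate_forward(cs$weights, cs$input, cs$params)
  tgt <- c(0.25, 0.75)
  r <- rowSums(rec$O[[3]]) / 8
  expect_equal(loss_bp_value(rec, loss_spec("mse_rate", tgt)),
               ((r[1] - tgt[1])^2 + (r[2] - tgt[2])^2) / 2)
  expect_error(loss_bp_value(rec, loss_spec("mse_rate", c(1, 0, 0))), "length")
})

test_that("backprop_bptt matches finite differences on the smoothed network", {
  # smooth forward + sigmoid surrogate + gradient through the reset is the
  # exact chain rule of the relaxed network, so central differences of the
  # loss are an independent oracle
  sg <- surrogate_spec("sigmoid_derivative", width = 1)
  for (seed in c(42, 43)) {
    set.seed(seed)
    cs <- random_case(c(2, 3, 2), Tn = 4)
    loss <- loss_spec("mse_rate", c(1, 0))
    g <- backprop_bptt(cs$weights, cs$input, cs$params, loss, sg,
                       reset_grad = "through", smooth = TRUE)
    fd <- lapply(seq_along(cs$weights$weights), function(i) {
      m <- cs$weights$weights[[i]]
      out <- m * 0
      for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
        pert <- function(d) {
          wp <- cs$weights
          wp$weights[[i]][r, cc] <- m[r, cc] + d
          loss_bp_value(simulate_forward(wp, cs$input, cs$params,
                                         smooth = TRUE, smooth_width = 1),
                        loss)
        }
        out[r, cc] <- (pert(1e-4) - pert(-1e-4)) / 2e-4
      }
      out
    })
    ga <- unlist(g)
    fa <- unlist(fd)
    expect_lt(max(abs(ga - fa)) / max(abs(fa)), 1e-4)
  }
})

test_that("gradients vanish for neurons outside the surrogate support", {
  # output neuron parked far above threshold: |V - v_th| > width/2 at every
  # step, so the rectangular surrogate is 0 along the only path and every
  # gradient entry (including upstream ones) is exactly 0
  p <- lif_params(T = 6)
  w <- network_weights(list(matrix(0.1, 2, 3), matrix(c(5, 5, 1, 1, 1, 1), 2, 3)))
  inp <- encode_constant(c(1, 1), 6)
  g <- backprop_bptt(w, inp, p, loss_spec("mse_rate", c(1, 0)),
                     surrogate_spec("rectangular", width = 1))
  expect_true(all(unlist(g) == 0))
})

test_that("bias gradients follow the same recursion with unit presynaptic input", {
  set.seed(55)
  cs <- random_case(c(2, 3, 2), Tn = 6)
  sg <- surrogate_spec("rectangular", width = 4)  # wide: everything active
  loss <- loss_spec("mse_rate", c(0, 1))
  g <- backprop_bptt(cs$weights, cs$input, cs$params, loss, sg)
  # move the bias onto an always-on extra input neuron (bias column zeroed):
  # the forward pass is unchanged and the new synapse's gradient must equal
  # the original bias gradient
  w1 <- cs$weights$weights[[1]]
  w_aug <- network_weights(list(
    cbind(0, w1[, 2:3], w1[, 1]), cs$weights$weights[[2]]), c(3L, 3L, 2L))
  g_aug <- backprop_bptt(w_aug, rbind(cs$input, 1), cs$params, loss, sg)
  expect_equal(g_aug[[1]][, 4], g[[1]][, 1], tolerance = 1e-14)
  expect_equal(g_aug[[1]][, 1], g[[1]][, 1], tolerance = 1e-14)
})

test_that("bp_update is elementwise gradient descent", {
  w <- network_weights(list(matrix(1, 2, 3)))
  g0 <- list(matrix(0, 2, 3))
  expect_equal(bp_update(w, g0, 0.1)$weights, w$weights)
  g <- list(matrix(0.5, 2, 3))
  expect_equal(bp_update(w, g, 0.1)$weights[[1]], matrix(0.95, 2, 3))
  # linearity: two half-steps with a fixed gradient equal one full step
  half <- bp_update(bp_update(w, g, 0.05), g, 0.05)
  expect_equal(half$weights, bp_update(w, g, 0.1)$weights)
  expect_error(bp_update(w, list(matrix(0, 3, 3)), 0.1), "mismatch")
})

test_that("backprop is deterministic and exports cleanly", {
  set.seed(66)
  cs <- random_case(c(2, 4, 2), Tn = 8)
  loss <- loss_spec("mse_rate", c(1, 0))
  sg <- surrogate_spec()
  g1 <- backprop_bptt(cs$weights, cs$input, cs$params, loss, sg)
  g2 <- backprop_bptt(cs$weights, cs$input, cs$params, loss, sg)
  expect_identical(g1, g2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gradient_csv(g1, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 4 * 3 + 2 * 5)
  expect_equal(min(df$col), 0)  # bias column is 0
  expect_equal(df$value[df$layer == 2], as.numeric(g1[[2]]))
})
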