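test_that("lif_step follows the hard-reset membrane update", {
  p <- lif_params(k_tau = 0.25, v_th = 0.5)
  # reset zeroes the carried potential
  s <- lif_step(V = 0.8, spiked_prev = 1, drive = 0.3, p)
  expect_equal(s$V_next, 0.3)
  expect_equal(s$O_next, 0)
  # decayed carry plus drive crosses threshold; spike at equality convention
  s <- lif_step(V = 0.4, spiked_prev = 0, drive = 0.5, p)
  expect_equal(s$V_next, 0.6)
  expect_equal(s$O_next, 1)
  expect_equal(lif_step(0, 0, p$v_th, p)$O_next, 1)  # exactly at threshold
  # quiescence
  s <- lif_step(0, 0, 0, p)
  expect_equal(s$V_next, 0)
  expect_equal(s$O_next, 0)
  expect_error(lif_step(NaN, 0, 0, p), "non-finite")
})

test_that("lif_params validates its domain", {
  expect_error(lif_params(k_tau = 1), "k_tau")
  expect_error(lif_params(v_th = 0), "v_th")
  expect_error(lif_params(T = 0), "T")
})

test_that("simulate_forward handles degenerate networks", {
  p <- lif_params(T = 6)
  w <- network_weights(list(matrix(0, 3, 3), matrix(0, 2, 4)))
  inp <- encode_constant(c(1, 0), 6)
  rec <- simulate_forward(w, inp, p)
  expect_true(all(unlist(rec$V) == 0))
  expect_true(all(rec$O[[2]] == 0) && all(rec$O[[3]] == 0))
  # single chain: drive w = v_th alone reaches threshold every step
  w1 <- network_weights(list(matrix(c(0, p$v_th), 1, 2)))
  rec1 <- simulate_forward(w1, encode_constant(1, 6), p)
  expect_equal(as.numeric(rec1$O[[2]]), rep(1, 6))
  expect_error(simulate_forward(w, encode_constant(c(1, 0, 1), 6), p), "x 6")
})

test_that("simulate_forward agrees exactly with the scalar-loop oracle", {
  set.seed(101)
  for (arch in list(c(2, 3, 2), c(3, 5, 4, 2), c(1, 2, 1))) {
    for (rep in 1:5) {
      cs <- random_case(arch, Tn = 16)
      rec <- simulate_forward(cs$weights, cs$input, cs$params)
      orc <- oracle_forward(cs$weights, cs$input, cs$params$k_tau,
                            cs$params$v_th, cs$params$T)
      for (i in seq_along(rec$V)) {
        expect_identical(rec$O[[i + 1]], orc$O[[i + 1]])
        expect_equal(rec$V[[i]], orc$V[[i]], tolerance = 1e-14)
      }
    }
  }
})

test_that("spike records satisfy binariness, reset and determinism invariants", {
  set.seed(202)
  for (rep in 1:10) {
    cs <- random_case(c(2, 4, 2), Tn = 12)
    rec <- simulate_forward(cs$weights, cs$input, cs$params)
    for (i in seq_along(rec$V)) {
      O <- rec$O[[i + 1]]; V <- rec$V[[i]]
      expect_true(all(O %in% c(0, 1)))
      expect_true(all(rate_decode(rec, i) >= 0 & rate_decode(rec, i) <= 1))
      # hard reset: the carried term into t+1 vanishes after a spike
      for (t in seq_len(cs$params$T - 1)) {
        carry <- cs$params$k_tau * V[, t] * (1 - O[, t])
        expect_true(all(carry[O[, t] == 1] == 0))
        drive <- drop(cs$weights$weights[[i]] %*% c(1, rec$O[[i]][, t + 1]))
        expect_equal(V[, t + 1], carry + drive, tolerance = 1e-14)
      }
    }
    rec2 <- simulate_forward(cs$weights, cs$input, cs$params)
    expect_identical(rec$O, rec2$O)
    expect_identical(rec$V, rec2$V)
  }
})

test_that("encoders and rate decoding behave as specified", {
  e <- encode_constant(c(1, 0), 8)
  expect_equal(e[1, ], rep(1, 8))
  expect_equal(e[2, ], rep(0, 8))
  expect_equal(encode_constant(c(0, 0), 5), matrix(0, 2, 5))
  expect_equal(dim(encode_constant(c(1, 1), 1)), c(2L, 1L))
  expect_error(encode_constant(c(0.5, 1), 4), "0/1")

  set.seed(7)
  ep <- encode_poisson(c(0.8, 0.2, 0), 50)
  expect_true(all(ep %in% c(0, 1)))
  expect_equal(ep[3, ], rep(0, 50))

  p <- lif_params(T = 4)
  w <- network_weights(list(matrix(c(0, 1), 1, 2)))
  rec <- simulate_forward(w, matrix(c(1, 0, 1, 0), 1, 4), p)
  expect_equal(rate_decode(rec, 0), 0.5)   # alternating input
  expect_error(rate_decode(rec, 3), "invalid layer")
})

test_that("spike-record CSV export is complete and well-formed", {
  set.seed(11)
  cs <- random_case(c(2, 3, 2), Tn = 5)
  rec <- simulate_forward(cs$weights, cs$input, cs$params)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_record_csv(rec, path)
  df <- read.csv(path)
  expect_named(df, c("layer", "neuron", "t", "V", "O"))
  expect_equal(nrow(df), (2 + 3 + 2) * 5)
  expect_true(all(is.na(df$V[df$layer == 0])))
  got <- df[df$layer == 2, ]
  expect_equal(matrix(got$O, 2, 5), rec$O[[3]], ignore_attr = TRUE)
  expect_equal(matrix(got$V, 2, 5), rec$V[[2]], ignore_attr = TRUE)
})
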