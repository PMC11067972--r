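test_that("max_lyapunov recovers known exponents", {
  # logistic map at r = 4: lambda = ln 2 exactly
  est <- max_lyapunov(function(x) 4 * x * (1 - x), 0.3, n_iter = 1e5,
                      n_discard = 100)
  expect_lt(abs(est$lambda_max - log(2)) / log(2), 0.01)
  # linear contraction: every step stretches by exactly 0.5
  est <- max_lyapunov(function(x) 0.5 * x, 1, n_iter = 1000, n_discard = 0)
  expect_equal(est$lambda_max, log(0.5), tolerance = 1e-10)
  # identity map: zero
  est <- max_lyapunov(function(x) x, c(1, 2), n_iter = 500, n_discard = 0)
  expect_equal(est$lambda_max, 0)
  expect_error(max_lyapunov(function(x) x, 1, n_iter = 10, n_discard = 10),
               "n_iter")
  expect_error(max_lyapunov(function(x) 2 * x + 1e300, 1, n_iter = 50,
                            n_discard = 0), "non-finite")
})

test_that("find_fixed_point solves the scalar reduced map for all z", {
  wbar_true <- log(13 / 7)
  for (z in c(0.5, 2, 8.79, 20, 100)) {
    rep <- find_fixed_point(chaos_map_scalar(z), x_init = 0, I0 = 0.65)
    expect_lt(abs(rep$w_bar - wbar_true), 1e-8)
    expect_lt(rep$prediction_error, 1e-8)
    # closed-form multiplier |1 - eta*z*sigma'(wbar)|, sigma'(wbar) = I0(1-I0)
    expect_equal(rep$jacobian_spectrum, abs(1 - z * 0.65 * 0.35),
                 tolerance = 1e-5)
    expect_equal(rep$repeller, abs(1 - z * 0.2275) > 1)
  }
})

test_that("z = 0 degenerates to the identity map and is flagged", {
  rep <- find_fixed_point(chaos_map_scalar(0), x_init = 0.37)
  expect_true(rep$degenerate)
  expect_equal(rep$w_bar, 0.37)
})

test_that("prediction error decays like 1/z on maps with a task gradient", {
  # constant stand-in gradient g0 shifts the fixed point by O(1/z);
  # doubling z must at least roughly halve the prediction error
  errs <- vapply(c(50, 100, 200, 400), function(z) {
    find_fixed_point(chaos_map_scalar(z, g0 = 0.5), x_init = 0.6,
                     I0 = 0.65)$prediction_error
  }, numeric(1))
  ratios <- errs[-1] / errs[-length(errs)]
  expect_true(all(ratios <= 0.6))
})

test_that("snap-back search behaves per the repeller prerequisites", {
  I0 <- 0.65
  # strong chaos: candidate seeded at ln(0.3/0.7) leads to an orbit landing
  # on the fixed point
  fp <- find_fixed_point(chaos_map_scalar(50), x_init = 0, I0 = I0)
  sb <- snapback_check(chaos_map_scalar(50), fp$w_bar, I0, tol = 1e-8)
  expect_equal(sb$theorem_seed, log(0.3 / 0.7))
  expect_true(sb$repeller)
  expect_true(sb$found)
  expect_lt(sb$closest_approach, 1e-6)
  expect_gt(abs(sb$w0 - fp$w_bar), 1e-4)
  # weak chaos: |1 - 0.2275 z| < 1, not a repeller, prerequisites fail
  fp1 <- find_fixed_point(chaos_map_scalar(1), x_init = 0, I0 = I0)
  sb1 <- snapback_check(chaos_map_scalar(1), fp1$w_bar, I0)
  expect_false(sb1$repeller)
  expect_false(sb1$found)
  expect_error(snapback_check(chaos_map_scalar(50), fp$w_bar, 0.5), "0.5")
})

test_that("bifurcation scan resolves fixed point vs chaos regimes", {
  fam <- function(z) chaos_map_scalar(z)
  tab <- bifurcation_scan(fam, z_grid = c(16, 25, 2), x0 = 0.1,
                          n_transient = 2000, n_sample = 64)
  expect_named(tab, c("z", "sample_index", "value"))
  # below the repeller threshold z < 8.79: a single attracting fixed point
  expect_equal(count_attractor_values(tab$value[tab$z == 2]), 1L)
  # chaotic band (lambda > 0 at z = 16): many distinct attractor values
  expect_gt(count_attractor_values(tab$value[tab$z == 16]), 10L)
  # period-3 window around z ~ 20-40, the Li-Yorke signature
  expect_equal(count_attractor_values(tab$value[tab$z == 25]), 3L)
  # z = 0: the map is the identity; samples constant at the initial point
  tab0 <- bifurcation_scan(fam, 0, x0 = 0.25, n_transient = 10, n_sample = 8)
  expect_true(all(tab0$value == 0.25))
})

test_that("windowed lyapunov enforces its preconditions", {
  run <- train(epochs = 100, seed = 1, eta = 1)
  expect_error(windowed_lyapunov(run), "record_weights")
  run <- train(epochs = 100, seed = 1, eta = 1, record_weights = TRUE)
  expect_error(windowed_lyapunov(run, window_len = 10), ">= 50")
  expect_error(windowed_lyapunov(run, window_len = 200), "longer")
  tab <- windowed_lyapunov(run, window_len = 50,
                           window_starts = c(1L, 40L))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$z, run$z[c(1, 40)])
})
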