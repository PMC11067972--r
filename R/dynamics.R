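#' Maximum Lyapunov exponent of a discrete map (Benettin method)
#'
#' Two-trajectory estimator: a reference orbit and a companion displaced by
#' `delta0` are iterated together; after every step the separation `d_i` is
#' measured, `ln(d_i / delta0)` is accumulated, and the companion is
#' renormalised back onto the sphere of radius `delta0` around the reference.
#' The estimate is the mean of the retained log-stretch factors (natural-log
#' units per iteration).
#'
#' Steps where the separation collapses to exactly zero (possible on maps
#' with flat pieces, e.g. a rectangular surrogate far from threshold) carry
#' no usable stretch information; they are dropped from the mean and counted
#' in `n_degenerate`.
#'
#' @param map_fn function mapping a numeric vector to a numeric vector.
#' @param x0 initial state.
#' @param n_iter total iterations, > `n_discard`.
#' @param delta0 initial perturbation magnitude, > 0. Default 1e-8.
#' @param n_discard transient iterations excluded from the mean. Default 100
#'   (capped at `n_iter %/% 2`).
#' @param direction optional vector (normalised internally) for the initial
#'   displacement; default the all-ones direction, which is generic in the
#'   sense of overlapping every coordinate subspace (a single coordinate
#'   axis can lie in an invariant neutral subspace of a structured map and
#'   then never feels the expanding directions).
#' @return object of class `lyapunov_estimate`: list with `lambda_max`,
#'   `window = c(n_discard + 1, n_iter)`, `delta0`, `renorm_every = 1`,
#'   `n_degenerate`.
#' @export
max_lyapunov <- function(map_fn, x0, n_iter, delta0 = 1e-8,
                         n_discard = min(100L, n_iter %/% 2L),
                         direction = NULL) {
  if (delta0 <= 0) stop("`delta0` must be > 0")
  n_iter <- as.integer(n_iter)
  n_discard <- as.integer(n_discard)
  if (n_iter <= n_discard || n_discard < 0L)
    stop("need n_iter > n_discard >= 0")
  x <- as.numeric(x0)
  if (is.null(direction)) direction <- rep(1, length(x))
  direction <- direction / sqrt(sum(direction^2))
  y <- x + delta0 * direction
  logs <- numeric(n_iter)
  degen <- 0L
  for (i in seq_len(n_iter)) {
    x <- map_fn(x)
    y <- map_fn(y)
    if (!all(is.finite(x)) || !all(is.finite(y)))
      stop(sprintf("orbit diverged to non-finite values at iteration %d", i))
    d <- sqrt(sum((y - x)^2))
    if (d == 0) {
      logs[i] <- NA_real_
      degen <- degen + 1L
      y <- x + delta0 * direction
    } else {
      logs[i] <- log(d / delta0)
      y <- x + (delta0 / d) * (y - x)
    }
  }
  kept <- logs[(n_discard + 1L):n_iter]
  structure(list(lambda_max = mean(kept, na.rm = TRUE),
                 window = c(n_discard + 1L, n_iter),
                 delta0 = delta0, renorm_every = 1L,
                 n_degenerate = degen),
            class = "lyapunov_estimate")
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("<lyapunov_estimate> lambda_max = %.6f (window %d..%d)\n",
              x$lambda_max, x$window[1], x$window[2]))
  invisible(x)
}

#' Frozen-z training map of a run
#'
#' The training update is nonautonomous (z shrinks every iteration). For
#' dynamical analysis we freeze z and obtain an autonomous map
#' `G_z: W -> W` on the flat weight vector: one full-batch update at fixed
#' intensity `z`. Built from a run's stored configuration and batch.
#'
#' @param run a `trajectory_log` from [train()].
#' @param z frozen chaos intensity.
#' @param eta optional learning-rate override.
#' @return function from flat weight vector to flat weight vector.
#' @export
training_map <- function(run, z, eta = NULL) {
  cfg <- attr(run, "config")
  batch <- attr(run, "batch")
  if (is.null(cfg) || is.null(batch)) stop("run lacks config/batch attributes")
  if (is.null(eta)) eta <- cfg$eta
  arch <- as.integer(cfg$arch)
  mask <- resolve_mask(cfg$chaos$mask, arch)
  sgk <- match(cfg$sg$kind, c("rectangular", "sigmoid_derivative")) - 1L
  lk <- match(cfg$loss_kind, c("mse_rate", "cross_entropy_rate")) - 1L
  p <- cfg$params
  force(z)
  function(wvec) {
    csbp_map_cpp(as.numeric(wvec), arch, batch$inputs, batch$targets,
                 p$k_tau, p$v_th, p$T, sgk, cfg$sg$width, lk,
                 eta, z, cfg$chaos$I0, mask, cfg$chaos$include_bias)
  }
}

#' Windowed Lyapunov exponents along a training run
#'
#' The training map changes every iteration through annealing; exponents are
#' therefore reported per window with z frozen at the window's opening
#' value: for each window start `m`, the autonomous map `G_{z_m}` is built
#' and the Benettin estimate is run for `window_len` iterations from the
#' recorded weight state at `m`. A stated approximation of the nonautonomous
#' dynamics, valid because z moves slowly (beta close to 1).
#'
#' @param run a `trajectory_log` produced with `record_weights = TRUE`.
#' @param window_len iterations per window, >= 50. Default 200.
#' @param window_starts 1-based epoch indices opening each window; default
#'   10 evenly spaced windows over the run.
#' @param delta0 Benettin perturbation size.
#' @return `data.frame` with columns `start_m`, `z`, `lambda_max`.
#' @export
windowed_lyapunov <- function(run, window_len = 200L, window_starts = NULL,
                              delta0 = 1e-8) {
  window_len <- as.integer(window_len)
  if (window_len < 50L) stop("`window_len` must be >= 50")
  hist <- attr(run, "weights_history")
  if (is.null(hist)) stop("run was not trained with record_weights = TRUE")
  n_ep <- nrow(hist)
  if (window_len > n_ep) stop("window longer than trajectory")
  if (is.null(window_starts))
    window_starts <- unique(round(seq(1L, n_ep - window_len + 1L,
                                      length.out = 10L)))
  out <- data.frame(start_m = integer(0), z = numeric(0),
                    lambda_max = numeric(0))
  for (s in window_starts) {
    z <- run$z[s]
    fmap <- training_map(run, z)
    est <- max_lyapunov(fmap, hist[s, ], n_iter = window_len,
                        delta0 = delta0, n_discard = 0L)
    out <- rbind(out, data.frame(start_m = run$m[s], z = z,
                                 lambda_max = est$lambda_max))
  }
  out
}

# Numerical Jacobian of map_fn at x (central differences)
num_jacobian <- function(map_fn, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- 1e-6 * (1 + abs(x))
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    e <- rep(0, n); e[k] <- h[k]
    J[, k] <- (map_fn(x + e) - map_fn(x - e)) / (2 * h[k])
  }
  J
}

#' Locate a fixed point of a map by damped Newton iteration
#'
#' Solves `G(x) - x = 0` with a numerically differenced Jacobian and simple
#' step-halving damping. Reports the Jacobian eigenvalue magnitudes of `G`
#' at the root (a fixed point is a repeller when all exceed 1) and, when
#' `I0` is supplied, the large-z closed-form prediction
#' `epsilon * log(I0 / (1 - I0))` with its error.
#'
#' The identity map (e.g. the chaos-free update with zero task gradient) has
#' every point fixed; this degenerate case is detected (`G(x0) = x0` and
#' Jacobian indistinguishable from the identity) and flagged instead of
#' solved.
#'
#' @param map_fn function from numeric vector to numeric vector.
#' @param x_init starting point.
#' @param tol residual tolerance on `|G(x) - x|` (max-norm). Default 1e-12.
#' @param max_iter Newton iteration cap. Default 100.
#' @param I0 optional target activity for the closed-form prediction.
#' @param epsilon scale constant of the prediction; for the scalar
#'   single-input reduction with mean presynaptic activity `s` it is `1/s`.
#'   Default 1.
#' @return object of class `fixed_point_report`: `w_bar`, `residual`,
#'   `jacobian_spectrum` (eigenvalue magnitudes), `repeller` (all > 1),
#'   `degenerate`, `converged`, `theorem_prediction`, `prediction_error`.
#' @export
find_fixed_point <- function(map_fn, x_init, tol = 1e-12, max_iter = 100L,
                             I0 = NULL, epsilon = 1) {
  if (tol <= 0) stop("`tol` must be > 0")
  x <- as.numeric(x_init)
  n <- length(x)
  Fx <- map_fn(x) - x
  J0 <- num_jacobian(map_fn, x)
  if (max(abs(Fx)) < tol && max(abs(J0 - diag(n))) < 1e-8) {
    return(structure(list(w_bar = x, residual = max(abs(Fx)),
                          jacobian_spectrum = rep(1, n), repeller = FALSE,
                          degenerate = TRUE, converged = TRUE,
                          theorem_prediction = NULL, prediction_error = NA_real_),
                     class = "fixed_point_report"))
  }
  converged <- max(abs(Fx)) < tol
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    J <- num_jacobian(map_fn, x) - diag(n)
    step <- tryCatch(solve(J, Fx), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      x_new <- x - lam * step
      F_new <- map_fn(x_new) - x_new
      if (all(is.finite(F_new)) &&
          (max(abs(F_new)) < max(abs(Fx)) || lam < 1e-8)) break
      lam <- lam / 2
    }
    x <- x_new
    Fx <- F_new
    converged <- max(abs(Fx)) < tol
  }
  if (!converged)
    warning("fixed-point search did not reach tolerance; residual = ",
            format(max(abs(Fx))))
  J <- num_jacobian(map_fn, x)
  spec <- Mod(eigen(J, only.values = TRUE)$values)
  pred <- if (is.null(I0)) NULL else epsilon * log(I0 / (1 - I0))
  structure(list(w_bar = x, residual = max(abs(Fx)),
                 jacobian_spectrum = spec,
                 repeller = all(spec > 1),
                 degenerate = FALSE, converged = converged,
                 theorem_prediction = pred,
                 prediction_error = if (is.null(pred)) NA_real_
                                    else max(abs(x - pred))),
            class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  if (x$degenerate) {
    cat("<fixed_point_report> degenerate: map is (locally) the identity;",
        "every point fixed\n")
  } else {
    cat(sprintf("<fixed_point_report> w_bar = %s, residual = %.2e, |eig(J)| = %s, repeller = %s\n",
                paste(signif(x$w_bar, 8), collapse = ", "), x$residual,
                paste(signif(x$jacobian_spectrum, 6), collapse = ", "),
                x$repeller))
  }
  invisible(x)
}

#' Numerical snap-back repeller check
#'
#' A snap-back repeller is a repelling fixed point `w_bar` together with a
#' point `w0 != w_bar` inside its repelling neighbourhood whose finite-step
#' forward image lands back on `w_bar` — a sufficient condition for chaos in
#' the sense of Marotto. This check is numerical and one-sided: it verifies
#' the repeller prerequisite from the Jacobian spectrum at `w_bar`, seeds a
#' root search at the closed-form large-z candidate
#' `epsilon * log((2 I0 - 1) / (2 - 2 I0))` (for `I0 > 0.5`; the mirrored
#' formula for `I0 < 0.5`), and Newton-solves `G^k(w) = w_bar` for
#' `k = 1..max_steps`. Failure to find an orbit is reported as "not found",
#' never as disproof.
#'
#' @param map_fn the map `G`.
#' @param w_bar repelling fixed point (from [find_fixed_point]).
#' @param I0 target activity; must differ from 0.5 (at 0.5 the candidate
#'   formula degenerates and the check is rejected).
#' @param epsilon scale constant of the seed formula (see
#'   [find_fixed_point]). Default 1.
#' @param max_steps largest orbit length tried. Default 8.
#' @param tol acceptance tolerance on `|G^k(w0) - w_bar|`. Default 1e-8.
#' @return object of class `snapback_report`: `found`, `repeller`, `w0`,
#'   `steps`, `closest_approach`, `theorem_seed`.
#' @export
snapback_check <- function(map_fn, w_bar, I0, epsilon = 1,
                           max_steps = 8L, tol = 1e-8) {
  if (abs(I0 - 0.5) < 1e-12)
    stop("snap-back candidate formula requires I0 != 0.5")
  w_bar <- as.numeric(w_bar)
  n <- length(w_bar)
  seed_val <- if (I0 > 0.5) epsilon * log((2 * I0 - 1) / (2 - 2 * I0))
              else epsilon * log((2 * I0) / (1 - 2 * I0))
  seed <- rep(seed_val, n)
  spec <- Mod(eigen(num_jacobian(map_fn, w_bar), only.values = TRUE)$values)
  rep_ok <- all(spec > 1)
  res <- structure(list(found = FALSE, repeller = rep_ok, w0 = NULL,
                        steps = NA_integer_, closest_approach = NA_real_,
                        theorem_seed = seed_val),
                   class = "snapback_report")
  if (!rep_ok) return(res)
  iterate_k <- function(x, k) { for (i in seq_len(k)) x <- map_fn(x); x }
  best <- Inf
  for (k in seq_len(max_steps)) {
    Hk <- function(x) iterate_k(x, k) - w_bar
    x <- seed
    ok <- FALSE
    for (it in 1:60) {
      Fx <- Hk(x)
      if (!all(is.finite(Fx))) break
      if (max(abs(Fx)) < tol) { ok <- TRUE; break }
      Jk <- num_jacobian(function(y) iterate_k(y, k), x)
      step <- tryCatch(solve(Jk, Fx), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        x_new <- x - lam * step
        F_new <- Hk(x_new)
        if (all(is.finite(F_new)) &&
            (max(abs(F_new)) < max(abs(Fx)) || lam < 1e-8)) break
        lam <- lam / 2
      }
      x <- x_new
    }
    if (ok) {
      sep <- sqrt(sum((x - w_bar)^2))
      # exclude the trivial solution w0 = w_bar; require w0 itself to lie in
      # the expanding region
      spec0 <- Mod(eigen(num_jacobian(map_fn, x), only.values = TRUE)$values)
      if (sep > 1e-4 * (1 + sqrt(sum(w_bar^2))) && all(spec0 > 1)) {
        ca <- max(abs(Hk(x)))
        if (ca < best) {
          best <- ca
          res$found <- TRUE
          res$w0 <- x
          res$steps <- k
          res$closest_approach <- ca
        }
        break
      }
    }
  }
  res
}

#' @export
print.snapback_report <- function(x, ...) {
  if (!x$repeller) {
    cat("<snapback_report> fixed point is not a repeller;",
        "snap-back prerequisites fail\n")
  } else if (x$found) {
    cat(sprintf("<snapback_report> snap-back point found: %d-step image within %.2e of the fixed point\n",
                x$steps, x$closest_approach))
  } else {
    cat("<snapback_report> repeller confirmed but no snap-back orbit located (not disproof)\n")
  }
  invisible(x)
}

#' Bifurcation scan over the chaos intensity
#'
#' For each value of the (frozen) intensity `z`, iterates the map, discards a
#' transient, and records sampled values of a scalar observable of the
#' attractor. Scanning z downwards with continuation (each z starts from the
#' previous attractor state) traces the chaos -> periodic -> fixed-point
#' route as the intensity anneals.
#'
#' @param map_fn_family function `z -> map`.
#' @param z_grid intensities to scan (any order; scanned as given).
#' @param x0 initial state for the first z.
#' @param n_transient iterations discarded per z. Default 500.
#' @param n_sample iterations recorded per z. Default 64.
#' @param observable index of the recorded coordinate, or a function of the
#'   state. Default the first coordinate.
#' @param continue start each z from the previous z's final state. Default
#'   `TRUE`.
#' @return `data.frame` with columns `z`, `sample_index`, `value`.
#' @export
bifurcation_scan <- function(map_fn_family, z_grid, x0, n_transient = 500L,
                             n_sample = 64L, observable = 1L,
                             continue = TRUE) {
  if (n_transient < 1L || n_sample < 1L)
    stop("n_transient and n_sample must be >= 1")
  obs <- if (is.function(observable)) observable
         else function(x) x[[observable]]
  x <- as.numeric(x0)
  out <- vector("list", length(z_grid))
  for (zi in seq_along(z_grid)) {
    fmap <- map_fn_family(z_grid[zi])
    xz <- if (continue) x else as.numeric(x0)
    for (i in seq_len(n_transient)) {
      xz <- fmap(xz)
      if (!all(is.finite(xz)))
        stop(sprintf("non-finite orbit at z = %g", z_grid[zi]))
    }
    vals <- numeric(n_sample)
    for (i in seq_len(n_sample)) {
      xz <- fmap(xz)
      if (!all(is.finite(xz)))
        stop(sprintf("non-finite orbit at z = %g", z_grid[zi]))
      vals[i] <- obs(xz)
    }
    x <- xz
    out[[zi]] <- data.frame(z = z_grid[zi], sample_index = seq_len(n_sample),
                            value = vals)
  }
  do.call(rbind, out)
}

#' Count distinct attractor values in a sample
#'
#' Clusters sorted sampled values, starting a new cluster wherever the gap
#' between neighbours exceeds `tol`. A fixed point gives 1, a period-p orbit
#' p, chaos many.
#'
#' @param values numeric samples.
#' @param tol gap threshold. Default 1e-4.
#' @return integer cluster count.
#' @export
count_attractor_values <- function(values, tol = 1e-4) {
  v <- sort(values)
  if (length(v) == 0L) return(0L)
  sum(c(TRUE, diff(v) > tol))
}

#' Scalar reduced chaotic update map
#'
#' The single-neuron, single-input reduction of the chaotic update used for
#' closed-form verification: `w' = w - eta * g0 + eta * z * (I0 - sigmoid(w * s)) * s`.
#' With `g0 = 0` (no task gradient) its unique fixed point is
#' `(1/s) * log(I0 / (1 - I0))` for every `z > 0`, and the fixed point is a
#' repeller exactly when `eta * z * s^2 * sigma'(w_bar * s) > 2`.
#'
#' @param z chaos intensity.
#' @param eta learning rate. Default 1.
#' @param I0 target activity. Default 0.65.
#' @param s mean presynaptic activity. Default 1.
#' @param g0 constant stand-in task gradient. Default 0.
#' @return function of a scalar weight.
#' @export
chaos_map_scalar <- function(z, eta = 1, I0 = 0.65, s = 1, g0 = 0) {
  force(z); force(eta); force(I0); force(s); force(g0)
  function(w) w - eta * g0 + eta * z * (I0 - plogis(w * s)) * s
}
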