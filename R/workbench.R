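#' The XOR task
#'
#' The four rows of exclusive-or with one-hot class targets:
#' (0,0) and (1,1) are class 0, (0,1) and (1,0) class 1.
#'
#' @return list with `inputs` (4 x 2 binary matrix, one row per sample),
#'   `targets` (2 x 4 one-hot matrix, one column per sample) and `classes`
#'   (length-4 integer vector of 0-based labels).
#' @export
xor_dataset <- function() {
  inputs <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  classes <- as.integer(xor(inputs[, 1], inputs[, 2]))
  targets <- vapply(classes, function(cl) {
    t <- c(0, 0); t[cl + 1L] <- 1; t
  }, numeric(2))
  list(inputs = inputs, targets = targets, classes = classes)
}

#' Synthetic 1-D regression task
#'
#' A stand-in continuous-target fixture: `y = sin(x)` on a uniform grid over
#' `[0, 2*pi]`, with optional Gaussian noise drawn from `seed`. It exercises
#' the continuous-target (rate-regression) code path; it does not claim to
#' match any published regression benchmark.
#'
#' @param n_points number of grid points, >= 2. Default 16.
#' @param seed RNG seed for the noise. Default 0.
#' @param noise_sd standard deviation of additive noise. Default 0
#'   (deterministic, seed-independent).
#' @return list with numeric vectors `x` and `y`.
#' @export
regression_dataset <- function(n_points = 16L, seed = 0L, noise_sd = 0) {
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("`n_points` must be >= 2")
  x <- seq(0, 2 * pi, length.out = n_points)
  y <- sin(x)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(n_points, sd = noise_sd)
  }
  list(x = x, y = y)
}

#' Build the spike-encoded full batch for a task
#'
#' XOR: each input bit pair is constant-encoded ([encode_constant]) over
#' `params$T` steps; targets are the one-hot columns. Regression: the two
#' input channels carry deterministic evenly spaced spike trains at rates
#' `x / 2pi` and `1 - x / 2pi`; the single output target rate is
#' `(y + 1) / 2` (sin mapped into [0, 1]).
#'
#' @param task `"xor"` or `"regression"`.
#' @param arch layer sizes; `arch[1]` must be 2 and, for regression, the
#'   output layer must have 1 neuron.
#' @param params a [lif_params].
#' @return list with `inputs` (list of `M_0 x T` matrices) and `targets`
#'   (`M_l x n` matrix).
#' @export
task_batch <- function(task, arch, params) {
  if (task == "xor") {
    ds <- xor_dataset()
    if (arch[1] != 2L || arch[length(arch)] != 2L)
      stop("XOR task needs arch with 2 inputs and 2 outputs")
    inputs <- lapply(seq_len(nrow(ds$inputs)), function(i)
      encode_constant(ds$inputs[i, ], params$T))
    list(inputs = inputs, targets = ds$targets)
  } else if (task == "regression") {
    if (arch[1] != 2L || arch[length(arch)] != 1L)
      stop("regression task needs arch with 2 inputs and 1 output")
    ds <- regression_dataset()
    r <- ds$x / (2 * pi)
    inputs <- lapply(seq_along(ds$x), function(i)
      rbind(evenly_spaced_spikes(r[i], params$T),
            evenly_spaced_spikes(1 - r[i], params$T)))
    list(inputs = inputs, targets = matrix((ds$y + 1) / 2, nrow = 1))
  } else stop("unknown task: ", task)
}

# Deterministic rate encoder: spike at t when floor(t*r) increments.
evenly_spaced_spikes <- function(rate, T) {
  t <- seq_len(T)
  as.numeric(floor(t * rate + 1e-9) - floor((t - 1) * rate + 1e-9) >= 1)
}

#' Run configuration
#'
#' Bundles every knob of a run into one serialisable object. Round-trips
#' losslessly through JSON ([write_run_config] / [read_run_config]).
#'
#' @param task task name.
#' @param arch layer sizes.
#' @param params a [lif_params].
#' @param chaos a [chaos_config].
#' @param sg a [surrogate_spec].
#' @param loss_kind loss name.
#' @param eta learning rate.
#' @param epochs full-batch updates per run.
#' @param seed base RNG seed.
#' @param init_interval weight initialisation interval.
#' @param track tracked weight indices, list of `c(layer, row, col)`.
#' @param out_dir output directory for artifacts (optional).
#' @return an object of class `run_config`.
#' @export
run_config <- function(task = "xor", arch = c(2, 5, 2),
                       params = lif_params(), chaos = chaos_config(),
                       sg = surrogate_spec(), loss_kind = "mse_rate",
                       eta = 1.0, epochs = 10000L, seed = 0L,
                       init_interval = c(-1, 1), track = list(c(2, 2, 0)),
                       out_dir = NULL) {
  structure(list(task = task, arch = as.integer(arch), params = params,
                 chaos = chaos, sg = sg, loss_kind = loss_kind, eta = eta,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init_interval = as.numeric(init_interval),
                 track = lapply(track, as.integer), out_dir = out_dir),
            class = "run_config")
}

#' Serialise / deserialise a run configuration as JSON
#'
#' @param config a [run_config].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$params <- unclass(obj$params)
  obj$chaos <- unclass(obj$chaos)
  obj$sg <- unclass(obj$sg)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  mask <- obj$chaos$mask
  if (is.list(mask)) mask <- lapply(mask, as.integer)
  run_config(
    task = obj$task, arch = obj$arch,
    params = lif_params(obj$params$k_tau, obj$params$v_th, obj$params$T),
    chaos = chaos_config(obj$chaos$z0, obj$chaos$beta, obj$chaos$I0,
                         mask = mask,
                         anneal_granularity = obj$chaos$anneal_granularity,
                         include_bias = obj$chaos$include_bias),
    sg = surrogate_spec(obj$sg$kind, obj$sg$width),
    loss_kind = obj$loss_kind, eta = obj$eta, epochs = obj$epochs,
    seed = obj$seed, init_interval = obj$init_interval,
    track = if (is.matrix(obj$track)) asplit(obj$track, 1)
            else lapply(obj$track, identity),
    out_dir = obj$out_dir)
}

run_from_config <- function(config, seed = config$seed, z0 = NULL,
                            init_interval = config$init_interval,
                            record_weights = FALSE) {
  chaos <- config$chaos
  if (!is.null(z0))
    chaos <- chaos_config(z0, chaos$beta, chaos$I0, chaos$mask,
                          chaos$anneal_granularity, chaos$include_bias)
  train(task = config$task, arch = config$arch, params = config$params,
        chaos = chaos, sg = config$sg, loss_kind = config$loss_kind,
        eta = config$eta, epochs = config$epochs, seed = seed,
        init_interval = init_interval, track = config$track,
        record_weights = record_weights)
}

#' Final-window mean task loss of a run
#'
#' Mean of `loss_bp` over the last `window` epochs (default the last 500).
#'
#' @param log a `trajectory_log` (or a data frame with a `loss_bp` column).
#' @param window number of trailing epochs. Default 500.
#' @return scalar mean loss.
#' @export
final_window_mse <- function(log, window = 500L) {
  lb <- log$loss_bp
  if (length(lb) < window) window <- length(lb)
  mean(tail(lb, window))
}

#' Paired chaotic-vs-baseline XOR experiment
#'
#' For each seed, trains the same initialisation twice — once with the
#' chaotic term (z0 from the config, default 20 with beta 0.9995) and once
#' with the plain surrogate-gradient baseline (z0 = 0) — for the full
#' 10 000-epoch horizon, then summarises the final-window (last 500 epochs)
#' mean MSE and the 4-row XOR accuracy of each run. Optionally writes
#' per-run trajectory CSVs and a windowed Lyapunov table for the first seed.
#'
#' @param config a [run_config]; defaults to the [2,5,2] XOR setup with
#'   z0 = 20, beta = 0.9995, eta = 1, 10 000 epochs.
#' @param seeds integer vector of seeds. Default 0:9.
#' @param out_dir optional directory for CSV artifacts.
#' @param lyapunov compute the windowed Lyapunov table for the first seed's
#'   chaotic run. Default TRUE.
#' @param window_len Lyapunov window length. Default 200.
#' @return object of class `experiment_summary`: `per_seed` data frame
#'   (seed, mse_csbp, mse_bp, acc_csbp, acc_bp), `lyapunov` data frame or
#'   NULL, `config`, `paths`.
#' @export
run_fig2_experiment <- function(config = run_config(), seeds = 0:9,
                                out_dir = NULL, lyapunov = TRUE,
                                window_len = 200L) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  per_seed <- data.frame(seed = seeds, mse_csbp = NA_real_, mse_bp = NA_real_,
                         acc_csbp = NA_real_, acc_bp = NA_real_)
  paths <- character(0)
  lyap <- NULL
  for (si in seq_along(seeds)) {
    rec_w <- lyapunov && si == 1L
    run_c <- run_from_config(config, seed = seeds[si], record_weights = rec_w)
    run_b <- run_from_config(config, seed = seeds[si], z0 = 0)
    batch <- attr(run_c, "batch")
    cls <- xor_dataset()$classes
    per_seed$mse_csbp[si] <- final_window_mse(run_c)
    per_seed$mse_bp[si] <- final_window_mse(run_b)
    per_seed$acc_csbp[si] <-
      mean(predict_classes(attr(run_c, "final_weights"), batch,
                           config$params) == cls)
    per_seed$acc_bp[si] <-
      mean(predict_classes(attr(run_b, "final_weights"), batch,
                           config$params) == cls)
    if (rec_w) lyap <- windowed_lyapunov(run_c, window_len = window_len)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      pc <- file.path(out_dir, sprintf("xor_csbp_seed%d.csv", seeds[si]))
      pb <- file.path(out_dir, sprintf("xor_bp_seed%d.csv", seeds[si]))
      write_trajectory_csv(run_c, pc)
      write_trajectory_csv(run_b, pb)
      paths <- c(paths, pc, pb)
    }
  }
  if (!is.null(out_dir) && !is.null(lyap)) {
    pl <- file.path(out_dir, "lyapunov_windows.csv")
    write.csv(lyap, pl, row.names = FALSE)
    paths <- c(paths, pl)
  }
  structure(list(per_seed = per_seed, lyapunov = lyap, config = config,
                 paths = paths),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("<experiment_summary>\n")
  cat(sprintf("  median final-window MSE: chaotic %.4g vs baseline %.4g\n",
              median(x$per_seed$mse_csbp), median(x$per_seed$mse_bp)))
  cat(sprintf("  XOR solved (4/4): chaotic %d/%d seeds, baseline %d/%d\n",
              sum(x$per_seed$acc_csbp == 1), nrow(x$per_seed),
              sum(x$per_seed$acc_bp == 1), nrow(x$per_seed)))
  if (!is.null(x$lyapunov))
    cat(sprintf("  lambda_max: first window %+.4f (z = %.3g), last window %+.4f (z = %.3g)\n",
                x$lyapunov$lambda_max[1], x$lyapunov$z[1],
                tail(x$lyapunov$lambda_max, 1), tail(x$lyapunov$z, 1)))
  invisible(x)
}

#' Initialisation-robustness experiment
#'
#' Trains XOR from uniform initialisations on each interval (default the
#' four intervals [-1,1], [-2,2], [-5,5], [-10,10]), with and without the
#' chaotic term, over several seeds per cell, and compares the
#' across-interval spread (max - min of per-interval mean final MSE) of the
#' two methods. A smaller spread under the chaotic update is the
#' initialisation-robustness property.
#'
#' @param config a [run_config].
#' @param init_intervals list of length-2 numeric intervals.
#' @param seeds seeds per cell. Default 0:4 (5 seeds).
#' @return object of class `robustness_summary`: `table` (interval, seed,
#'   mse_csbp, mse_bp, acc_csbp, acc_bp), `spread_csbp`, `spread_bp`,
#'   `csbp_spread_leq` (logical property).
#' @export
run_robustness_experiment <- function(config = run_config(),
                                      init_intervals = list(c(-1, 1), c(-2, 2),
                                                            c(-5, 5), c(-10, 10)),
                                      seeds = 0:4) {
  for (iv in init_intervals)
    if (length(iv) != 2L || iv[1] > iv[2]) stop("malformed interval")
  rows <- list()
  cls <- xor_dataset()$classes
  for (ii in seq_along(init_intervals)) {
    iv <- init_intervals[[ii]]
    for (sd in seeds) {
      run_c <- run_from_config(config, seed = sd, init_interval = iv)
      run_b <- run_from_config(config, seed = sd, z0 = 0, init_interval = iv)
      batch <- attr(run_c, "batch")
      rows[[length(rows) + 1L]] <- data.frame(
        interval_lo = iv[1], interval_hi = iv[2], seed = sd,
        mse_csbp = final_window_mse(run_c),
        mse_bp = final_window_mse(run_b),
        acc_csbp = mean(predict_classes(attr(run_c, "final_weights"), batch,
                                        config$params) == cls),
        acc_bp = mean(predict_classes(attr(run_b, "final_weights"), batch,
                                      config$params) == cls))
    }
  }
  tab <- do.call(rbind, rows)
  key <- paste(tab$interval_lo, tab$interval_hi)
  mean_c <- tapply(tab$mse_csbp, key, mean)
  mean_b <- tapply(tab$mse_bp, key, mean)
  spread_c <- max(mean_c) - min(mean_c)
  spread_b <- max(mean_b) - min(mean_b)
  structure(list(table = tab, spread_csbp = spread_c, spread_bp = spread_b,
                 csbp_spread_leq = spread_c <= spread_b),
            class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("<robustness_summary> across-interval MSE spread: chaotic %.4g, baseline %.4g (chaotic <= baseline: %s)\n",
              x$spread_csbp, x$spread_bp, x$csbp_spread_leq))
  invisible(x)
}
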