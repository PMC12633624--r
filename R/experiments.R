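#' Transition sweep of the linearized dynamics
#'
#' For each gain and realization, propagates the linearized (Kesten) dynamics
#' for `depth` steps and records the quiescence order parameter (fraction of
#' final components within `epsilon` of zero).  In annealed mode each
#' realization/gain runs with fresh per-step matrices.  In quenched mode the
#' protocol fixes one base matrix per realization, drawn at unit gain (scale
#' 1/N^(1/alpha)), and rescales the same realization by every gain in the
#' grid; the initial vector is also shared across the grid.
#'
#' @param alpha stability index.
#' @param n_units network size N.
#' @param gains sorted gain grid.
#' @param modes subset of `c("annealed", "quenched")`.
#' @param n_realizations realizations per mode (default 10).
#' @param depth propagation steps T (default 100).
#' @param epsilon order-parameter threshold (default 0.1).
#' @param seed root seed; one sub-stream per (mode, realization).
#' @return data frame (alpha, n_units, mode, gain, realization,
#'   order_parameter, seed).
#' @export
run_transition_experiment <- function(alpha, n_units, gains,
                                      modes = c("annealed", "quenched"),
                                      n_realizations = 10, depth = 100,
                                      epsilon = 0.1, seed = NULL) {
  stopifnot(length(gains) >= 1, !is.unsorted(gains), n_realizations >= 1)
  modes <- match.arg(modes, several.ok = TRUE)
  seeds <- if (is.null(seed))
    vector("list", length(modes) * n_realizations)
  else as.list(spawn_seeds(seed, length(modes) * n_realizations))
  rows <- list()
  si <- 0
  for (mode in modes) {
    for (r in seq_len(n_realizations)) {
      si <- si + 1
      s <- seeds[[si]]
      rows[[length(rows) + 1]] <- with_seed(s, {
        init <- runif(n_units, -1, 1)
        base_w <- if (mode == "quenched")
          sample_weight_matrix(network_config(n_units, alpha, gain = 1))
        f <- vapply(gains, function(g) {
          cfg <- network_config(n_units, alpha, g)
          st <- simulate_linear(cfg, mode = mode, depth = depth, init = init,
                                weights = if (!is.null(base_w)) g * base_w)
          order_parameter(st, epsilon)
        }, numeric(1))
        data.frame(alpha = alpha, n_units = n_units, mode = mode,
                   gain = gains, realization = r, order_parameter = f,
                   seed = if (is.null(s)) NA_integer_ else s)
      })
    }
  }
  do.call(rbind, rows)
}

#' Per-realization transition gain from an order-parameter curve
#'
#' Interpolates the gain at which the order parameter falls through 1/2
#' along a sorted gain grid.  Returns `NA` if the curve never brackets 1/2.
#'
#' @param gains sorted gain grid.
#' @param f order-parameter values on the grid.
#' @return interpolated transition gain or `NA`.
#' @export
order_transition_gain <- function(gains, f) {
  stopifnot(length(gains) == length(f), length(gains) >= 2,
            !is.unsorted(gains))
  for (i in seq_len(length(gains) - 1)) {
    if (f[i] >= 0.5 && f[i + 1] < 0.5) {
      return(gains[i] + (f[i] - 0.5) * (gains[i + 1] - gains[i]) /
               (f[i] - f[i + 1]))
    }
  }
  NA_real_
}

#' Maximal-Lyapunov-exponent sweep over a gain grid
#'
#' For each gain, estimates the maximal Lyapunov exponent across `n_trials`
#' trials (fresh weight matrix, initial condition and input stream per trial
#' under the default realization policy) with the last-`k_accum`-steps
#' accumulation protocol, then locates the upward zero crossing of the mean
#' curve.
#'
#' @inheritParams run_transition_experiment
#' @param gains sorted gain grid (>= 2 points).
#' @param n_trials trials per gain (default 10).
#' @param horizon trajectory length T (default 3000).
#' @param k_accum accumulation steps K (default 100).
#' @param input `"none"` or `"gaussian"`.
#' @param input_variance variance of the Gaussian drive.
#' @param share_matrix if `TRUE`, each trial draws one base matrix at unit
#'   gain and rescales the same realization by every gain in the grid (the
#'   quenched-sweep protocol); rows of `trials` are then per-realization
#'   exponent curves with sharp individual transitions, the input to
#'   [realization_crossing_gains()].  Default `FALSE`: a fresh matrix per
#'   (gain, trial).
#' @return a `sweep_result`: `table` (gain, mle_mean, mle_sd, n_trials,
#'   seed), per-trial matrix `trials` (n_trials x n_gains), `crossing_gain`
#'   (mean-curve crossing), `alpha`, `n_units`.
#' @export
run_mle_sweep <- function(alpha, n_units, gains, n_trials = 10,
                          horizon = 3000, k_accum = 100,
                          input = c("none", "gaussian"),
                          input_variance = 0.01, share_matrix = FALSE,
                          seed = NULL) {
  stopifnot(length(gains) >= 2, !is.unsorted(gains))
  input <- match.arg(input)
  trials <- matrix(NA_real_, n_trials, length(gains))
  if (share_matrix) {
    seeds <- if (is.null(seed)) vector("list", n_trials)
             else as.list(spawn_seeds(seed, n_trials))
    for (r in seq_len(n_trials)) {
      trials[r, ] <- with_seed(seeds[[r]], {
        base_w <- sample_weight_matrix(network_config(n_units, alpha, 1))
        vapply(gains, function(g) {
          lyapunov_spectrum(network_config(n_units, alpha, g),
                            horizon = horizon, warmup = horizon - k_accum,
                            n_exponents = 1, input = input,
                            input_variance = input_variance,
                            weights = g * base_w)$exponents[1]
        }, numeric(1))
      })
    }
    seed_col <- rep(vapply(seeds, function(s)
      if (is.null(s)) NA_integer_ else s, integer(1))[1], length(gains))
  } else {
    seeds <- if (is.null(seed)) vector("list", length(gains))
             else as.list(spawn_seeds(seed, length(gains)))
    for (i in seq_along(gains)) {
      cfg <- network_config(n_units, alpha, gains[i])
      ml <- max_lyapunov(cfg, horizon = horizon, k_accum = k_accum,
                         n_trials = n_trials, input = input,
                         input_variance = input_variance, seed = seeds[[i]])
      trials[, i] <- ml$trials
    }
    seed_col <- vapply(seeds, function(s)
      if (is.null(s)) NA_integer_ else s, integer(1))
  }
  tab <- data.frame(gain = gains, mle_mean = colMeans(trials),
                    mle_sd = apply(trials, 2, sd), n_trials = n_trials,
                    seed = seed_col)
  out <- structure(list(table = tab, trials = trials, alpha = alpha,
                        n_units = n_units, horizon = horizon,
                        k_accum = k_accum, share_matrix = share_matrix,
                        seed = seed),
                   class = "sweep_result")
  out$crossing_gain <- estimate_transition_gain(out)
  out
}

#' Per-realization transition gains from a matrix-sharing sweep
#'
#' For each realization (row of `sweep$trials`), interpolates the gain at
#' which that realization's maximal exponent first crosses zero.  The mean of
#' these per-realization crossings is the "average critical gain" estimator:
#' individual quenched realizations transition sharply, so it is considerably
#' more stable than the crossing of the trial-averaged curve, whose long
#' near-zero plateau makes the latter noisy.  Meaningful when the sweep was
#' run with `share_matrix = TRUE`.
#'
#' @param sweep a `sweep_result`.
#' @return numeric vector of per-realization crossing gains (`NA` where a
#'   realization never crosses upward inside the grid).
#' @export
realization_crossing_gains <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  apply(sweep$trials, 1, function(m) {
    g <- estimate_transition_gain(sweep$table$gain, m)
    if (is.null(g)) NA_real_ else g
  })
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> alpha = %g, N = %d, %d gains x %d trials\n",
              x$alpha, x$n_units, nrow(x$table), x$table$n_trials[1]))
  cat(sprintf("  crossing gain: %s\n",
              if (is.null(x$crossing_gain)) "none"
              else sprintf("%.4f", x$crossing_gain)))
  invisible(x)
}

#' Width of the edge-of-chaos gain window
#'
#' Length of the gain interval over which |mean maximal exponent| stays at
#' or below `band`, measured on the mean sweep curve with linear
#' interpolation of the entry and exit points.  A wider window means the
#' network sits near the edge of chaos over a broader gain range.
#'
#' @param sweep a `sweep_result`.
#' @param band exponent band (default 0.05).
#' @return window width in gain units (0 if the curve never enters the band).
#' @export
edge_window_width <- function(sweep, band = 0.05) {
  stopifnot(inherits(sweep, "sweep_result"), band > 0)
  g <- sweep$table$gain
  m <- sweep$table$mle_mean
  inside <- abs(m) <= band
  if (!any(inside)) return(0)
  cross <- function(y) {  # all gains where the curve crosses level y
    out <- numeric(0)
    for (i in seq_len(length(g) - 1)) {
      if ((m[i] - y) * (m[i + 1] - y) < 0)
        out <- c(out, g[i] + (y - m[i]) * (g[i + 1] - g[i]) / (m[i + 1] - m[i]))
    }
    out
  }
  pts <- sort(c(cross(-band), cross(band), g[inside]))
  max(pts) - min(pts)
}

#' Dimensionality of near-critical dynamics
#'
#' At each gain, runs `n_trials` realizations of the nonlinear network,
#' computes the top-`n_exponents` Lyapunov spectrum (Benettin QR), the
#' Kaplan-Yorke dimension, and the participation ratio of the last `retain`
#' states of the same run.  Trials whose activity has fully collapsed to the
#' quiescent state have no attractor variance; their participation ratio is
#' recorded as `NA`.
#'
#' @inheritParams run_mle_sweep
#' @param gains gain grid (need not bracket a crossing).
#' @param horizon trajectory length (default 1500).
#' @param warmup accumulation warmup (default 500).
#' @param n_exponents tracked exponents (default min(N, 100)).
#' @param retain states kept for the covariance (default 500).
#' @return a `dimensionality_result`: `table` (alpha, n_units, gain, trial,
#'   mle, d_ky, pr, seed) and `spectra` (list, one exponent matrix
#'   rank-by-trial per gain).
#' @export
run_dimensionality_experiment <- function(alpha, n_units, gains,
                                          n_trials = 10, horizon = 1500,
                                          warmup = 500, n_exponents = NULL,
                                          retain = 500, seed = NULL) {
  stopifnot(length(gains) >= 1, n_trials >= 1, horizon > warmup,
            retain >= 2, retain <= horizon)
  if (is.null(n_exponents)) n_exponents <- min(n_units, 100L)
  seeds <- if (is.null(seed)) vector("list", length(gains) * n_trials)
           else as.list(spawn_seeds(seed, length(gains) * n_trials))
  rows <- list()
  spectra <- vector("list", length(gains))
  names(spectra) <- format(gains)
  si <- 0
  for (i in seq_along(gains)) {
    spec_mat <- matrix(NA_real_, n_exponents, n_trials)
    for (tr in seq_len(n_trials)) {
      si <- si + 1
      cfg <- network_config(n_units, alpha, gains[i], seed = seeds[[si]])
      res <- lyapunov_spectrum(cfg, horizon = horizon, warmup = warmup,
                               n_exponents = n_exponents,
                               keep_states = retain)
      spec_mat[, tr] <- res$exponents
      pr <- tryCatch(
        participation_ratio(suppressWarnings(
          empirical_covariance(res$states))),
        error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        alpha = alpha, n_units = n_units, gain = gains[i], trial = tr,
        mle = res$exponents[1], d_ky = kaplan_yorke(res$exponents), pr = pr,
        seed = if (is.null(seeds[[si]])) NA_integer_ else seeds[[si]])
    }
    spectra[[i]] <- spec_mat
  }
  structure(list(table = do.call(rbind, rows), spectra = spectra,
                 alpha = alpha, n_units = n_units, seed = seed),
            class = "dimensionality_result")
}

#' Zero out the largest-magnitude weights
#'
#' Removes the `n_remove` entries of largest absolute value (the
#' "mega-synapses" of a heavy-tailed matrix), ties broken by row-major
#' position, and returns the ablated copy.
#'
#' @param weights N x N weight matrix.
#' @param n_remove number of entries to zero, between 0 and N^2.
#' @return the ablated matrix.
#' @export
ablate_top_weights <- function(weights, n_remove) {
  stopifnot(is.matrix(weights))
  if (n_remove < 0 || n_remove > length(weights))
    stop("n_remove must lie between 0 and N^2")
  if (n_remove == 0) return(weights)
  a <- t(weights)  # linear index of t(W) is row-major order of W
  ord <- order(-abs(a), seq_along(a))
  a[ord[seq_len(n_remove)]] <- 0
  t(a)
}

#' Mega-synapse ablation experiment
#'
#' Per trial, draws a weight matrix, measures the maximal Lyapunov exponent,
#' then re-measures after zeroing the `n_remove` largest-magnitude weights
#' (same initial condition), quantifying how strongly a handful of extreme
#' weights drives the dynamics.
#'
#' @inheritParams run_mle_sweep
#' @param gain the gain at which to evaluate.
#' @param n_remove weights removed per trial (default 10).
#' @return data frame (alpha, n_units, gain, trial, n_remove, frac_removed,
#'   mle_full, mle_ablated, seed).
#' @export
run_ablation_experiment <- function(alpha, n_units, gain, n_remove = 10,
                                    n_trials = 10, horizon = 3000,
                                    k_accum = 100, seed = NULL) {
  seeds <- if (is.null(seed)) vector("list", n_trials)
           else as.list(spawn_seeds(seed, n_trials))
  cfg <- network_config(n_units, alpha, gain)
  rows <- lapply(seq_len(n_trials), function(tr) {
    with_seed(seeds[[tr]], {
      w <- sample_weight_matrix(cfg)
      init <- runif(n_units, -1, 1)
      lam <- function(wm) lyapunov_spectrum(
        cfg, horizon = horizon, warmup = horizon - k_accum, n_exponents = 1,
        init = init, weights = wm)$exponents[1]
      data.frame(alpha = alpha, n_units = n_units, gain = gain, trial = tr,
                 n_remove = n_remove, frac_removed = n_remove / n_units^2,
                 mle_full = lam(w),
                 mle_ablated = lam(ablate_top_weights(w, n_remove)),
                 seed = if (is.null(seeds[[tr]])) NA_integer_ else seeds[[tr]])
    })
  })
  do.call(rbind, rows)
}

#' Delayed-XOR reservoir task
#'
#' Drives the network with a random bit stream u(t) in \{0, 1\} through a
#' fixed random input vector, trains a ridge-regression readout on
#' post-washout states to predict the XOR of the bits at lags `delay` and
#' `delay + 1`, and reports held-out classification accuracy per
#' (alpha, gain).  Bits are encoded as 0/1 rather than as a symmetric -1/+1
#' stream: with the odd tanh activation a centered stream leaves the state an
#' (asymptotically) odd function of the input history, while the XOR target
#' is even, so parity would be linearly unlearnable by symmetry; the 0/1
#' encoding breaks that symmetry.  Task parameters (delay 1, 2000/1000
#' train/test steps, ridge penalty 1e-4, input scale 0.5) are package
#' defaults, all exposed.
#'
#' @param alpha_grid stability indices to evaluate.
#' @param gains gain grid.
#' @param n_units reservoir size (default 300).
#' @param delay lag of the first XOR argument (default 1: target at time t is
#'   XOR of u(t-1) and u(t-2)).
#' @param train_steps,test_steps readout training and evaluation lengths.
#' @param washout initial steps discarded before training (default 100).
#' @param ridge_penalty ridge penalty (>= 0; intercept unpenalized).
#' @param input_scale multiplier on the input vector.
#' @param seed root seed; one sub-stream per (alpha, gain).
#' @return data frame (alpha, n_units, gain, delay, accuracy, seed).
#' @export
run_xor_reservoir <- function(alpha_grid, gains, n_units = 300, delay = 1,
                              train_steps = 2000, test_steps = 1000,
                              washout = 100, ridge_penalty = 1e-4,
                              input_scale = 0.5, seed = NULL) {
  stopifnot(delay >= 0, train_steps > delay, test_steps > delay,
            ridge_penalty >= 0)
  grid <- expand.grid(alpha = alpha_grid, gain = gains)
  seeds <- if (is.null(seed)) vector("list", nrow(grid))
           else as.list(spawn_seeds(seed, nrow(grid)))
  total <- washout + train_steps + test_steps
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    with_seed(seeds[[i]], {
      cfg <- network_config(n_units, grid$alpha[i], grid$gain[i])
      w <- sample_weight_matrix(cfg)
      w_in <- rnorm(n_units)
      u <- sample(0:1, total, replace = TRUE)
      inputs <- outer(u, input_scale * w_in)
      states <- cpp_simulate_rnn(w, runif(n_units, -1, 1), inputs, total)
      # row t+1 of `states` is x(t), the state after input u(t)
      b <- u
      t_idx <- (washout + 1):total
      t_idx <- t_idx[t_idx > delay + 1]
      y <- ifelse(xor(b[t_idx - delay] == 1, b[t_idx - delay - 1] == 1), 1, -1)
      x_all <- states[t_idx + 1, , drop = FALSE]
      tr <- seq_len(min(train_steps, length(t_idx) - test_steps))
      te <- (length(t_idx) - test_steps + 1):length(t_idx)
      if (length(unique(y[tr])) < 2) stop("degenerate task: constant targets")
      xc <- cbind(1, x_all[tr, , drop = FALSE])
      pen <- diag(c(0, rep(ridge_penalty, n_units)))
      beta <- solve(crossprod(xc) + pen, crossprod(xc, y[tr]))
      pred <- drop(cbind(1, x_all[te, , drop = FALSE]) %*% beta)
      mean(ifelse(pred >= 0, 1, -1) == y[te])
    })
  }, numeric(1))
  data.frame(alpha = grid$alpha, n_units = n_units, gain = grid$gain,
             delay = delay, accuracy = acc,
             seed = vapply(seeds, function(s)
               if (is.null(s)) NA_integer_ else s, integer(1)))
}

#' Width of the high-accuracy gain window of a reservoir sweep
#'
#' Length of the gain interval (linear interpolation on the accuracy-vs-gain
#' curve) over which accuracy stays at or above `threshold`, for one alpha.
#'
#' @param gains sorted gain grid.
#' @param accuracy accuracies on the grid.
#' @param threshold accuracy threshold (default 0.9).
#' @return window width in gain units.
#' @export
accuracy_window_width <- function(gains, accuracy, threshold = 0.9) {
  stopifnot(length(gains) == length(accuracy), !is.unsorted(gains))
  above <- accuracy >= threshold
  if (!any(above)) return(0)
  pts <- gains[above]
  for (i in seq_len(length(gains) - 1)) {
    if ((accuracy[i] - threshold) * (accuracy[i + 1] - threshold) < 0)
      pts <- c(pts, gains[i] + (threshold - accuracy[i]) *
                 (gains[i + 1] - gains[i]) / (accuracy[i + 1] - accuracy[i]))
  }
  max(pts) - min(pts)
}
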