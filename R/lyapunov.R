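#' Lyapunov spectrum by the Benettin QR method
#'
#' Evolves the network together with an orthonormal frame of `n_exponents`
#' tangent vectors pushed through the exact per-step Jacobian
#' diag(1 - x(t+1)^2) W.  The frame is re-orthonormalized by QR every step
#' (sign convention: positive diagonal of R) and the logs of the diagonal of
#' R are accumulated after a warmup during which the state evolves but no
#' accumulation takes place.  Exponents are the time averages over the
#' accumulation window, sorted nonincreasing.
#'
#' Per-step log contractions are clamped below at `floor_log` (default
#' log of machine epsilon) so that zero maps — e.g. gain 0, where the true
#' maximal exponent is -Inf — return finite, flagged values.
#'
#' `activation = "linear"` replaces tanh by the identity, a test hook for
#' which the Jacobian is the constant matrix W and the exponents converge to
#' sorted log|eigenvalues(W)|.
#'
#' @param config a [network_config()].
#' @param horizon total steps T (> warmup).
#' @param warmup steps excluded from accumulation (default 500).
#' @param n_exponents frame size m <= N; default all N for N <= 1000, else
#'   100 (the full-spectrum cost per step is O(N^2 m)).
#' @param input `"none"` or `"gaussian"` drive.
#' @param input_variance variance of the Gaussian drive.
#' @param init `"random"` or numeric N-vector.
#' @param weights optional pre-drawn weight matrix.
#' @param activation `"tanh"` (default) or `"linear"` (test hook).
#' @param frame optional N x m initial orthonormal frame (default the first m
#'   coordinate vectors).
#' @param keep_states if > 0, also return the last `keep_states` states (for
#'   covariance-based dimensionality from the same run).
#' @param floor_log per-step lower clamp for log contractions.
#' @return a `lyapunov_result`: `exponents` (nonincreasing), `n_tracked`,
#'   `warmup`, `accumulation_steps`, `floored`, `final_state`, and `states`
#'   (matrix, only when `keep_states > 0`).
#' @export
lyapunov_spectrum <- function(config, horizon, warmup = 500,
                              n_exponents = NULL,
                              input = c("none", "gaussian"),
                              input_variance = 0.01, init = "random",
                              weights = NULL,
                              activation = c("tanh", "linear"), frame = NULL,
                              keep_states = 0,
                              floor_log = log(.Machine$double.eps)) {
  stopifnot(inherits(config, "network_config"))
  input <- match.arg(input)
  activation <- match.arg(activation)
  n <- config$n_units
  if (is.null(n_exponents)) n_exponents <- if (n <= 1000) n else 100L
  if (n_exponents > n) stop("n_exponents must not exceed n_units")
  stopifnot(horizon > warmup, warmup >= 0)
  res <- with_seed(config$seed, {
    if (is.null(weights)) weights <- sample_weight_matrix(
      network_config(n, config$alpha, config$gain))
    x0 <- if (identical(init, "random")) runif(n, -1, 1) else as.numeric(init)
    if (length(x0) != n) stop("init must have length n_units")
    inputs <- if (input == "gaussian")
      matrix(rnorm(horizon * n, sd = sqrt(input_variance)), horizon, n)
    cpp_lyapunov(weights, x0, as.integer(horizon), as.integer(warmup),
                 as.integer(n_exponents), activation == "linear", inputs,
                 frame, floor_log, as.integer(keep_states))
  })
  structure(list(exponents = drop(res$exponents),
                 n_tracked = as.integer(n_exponents),
                 warmup = as.integer(warmup),
                 accumulation_steps = as.integer(horizon - warmup),
                 floored = res$floored, final_state = drop(res$final_state),
                 states = res$states, config = config),
            class = "lyapunov_result")
}

#' Maximal Lyapunov exponent across trials
#'
#' Runs a single-vector Benettin accumulation (`n_exponents = 1`) per trial
#' and summarizes the maximal exponent across trials.  Under the default
#' `"realization"` policy each trial draws a fresh weight matrix, initial
#' condition and (if any) input stream; `"input"` fixes one weight matrix and
#' redraws only initial conditions and inputs, the input-averaging variant.
#'
#' The default protocol accumulates over the last `k_accum` steps of a
#' `horizon`-step run (warmup = horizon - k_accum).
#'
#' @inheritParams lyapunov_spectrum
#' @param k_accum accumulation steps K (default 100).
#' @param n_trials number of trials (>= 1).
#' @param trial_policy `"realization"` or `"input"`.
#' @param seed optional root seed spawning one sub-stream per trial.
#' @return list with `mean`, `sd`, per-trial vector `trials`, and `floored`
#'   (any trial clamped).
#' @export
max_lyapunov <- function(config, horizon = 3000, k_accum = 100, n_trials = 10,
                         input = c("none", "gaussian"), input_variance = 0.01,
                         trial_policy = c("realization", "input"),
                         seed = NULL) {
  stopifnot(n_trials >= 1, k_accum >= 1, horizon > k_accum)
  input <- match.arg(input)
  trial_policy <- match.arg(trial_policy)
  seeds <- if (is.null(seed)) vector("list", n_trials + 1)
           else as.list(spawn_seeds(seed, n_trials + 1))
  base <- network_config(config$n_units, config$alpha, config$gain)
  shared_w <- if (trial_policy == "input")
    with_seed(seeds[[n_trials + 1]], sample_weight_matrix(base))
  floored <- FALSE
  trials <- vapply(seq_len(n_trials), function(i) {
    res <- with_seed(seeds[[i]], {
      w <- if (is.null(shared_w)) sample_weight_matrix(base) else shared_w
      lyapunov_spectrum(base, horizon = horizon, warmup = horizon - k_accum,
                        n_exponents = 1, input = input,
                        input_variance = input_variance, weights = w)
    })
    floored <<- floored || res$floored
    res$exponents[1]
  }, numeric(1))
  list(mean = mean(trials), sd = if (n_trials > 1) sd(trials) else NA_real_,
       trials = trials, floored = floored)
}

#' Transition gain from a maximal-exponent sweep
#'
#' Locates the first sign change of the mean maximal Lyapunov exponent from
#' negative to nonnegative along a sorted gain grid and refines it by linear
#' interpolation between the bracketing grid points.  Returns `NULL` when the
#' curve never crosses upward.
#'
#' @param sweep a `sweep_result` from [run_mle_sweep()], or a numeric vector
#'   of gains (in which case `mle` must be given).
#' @param mle mean maximal exponents matching the gain vector.
#' @return interpolated crossing gain, or `NULL`.
#' @export
estimate_transition_gain <- function(sweep, mle = NULL) {
  if (inherits(sweep, "sweep_result")) {
    gains <- sweep$table$gain
    mle <- sweep$table$mle_mean
  } else {
    gains <- sweep
  }
  stopifnot(is.numeric(gains), is.numeric(mle), length(gains) == length(mle),
            length(gains) >= 2)
  if (is.unsorted(gains, strictly = TRUE)) stop("gain grid must be sorted")
  for (i in seq_len(length(gains) - 1)) {
    if (mle[i] < 0 && mle[i + 1] >= 0) {
      return(gains[i] + (0 - mle[i]) * (gains[i + 1] - gains[i]) /
               (mle[i + 1] - mle[i]))
    }
  }
  NULL
}

#' Kaplan-Yorke (Lyapunov) dimension
#'
#' With exponents lambda_1 >= ... >= lambda_m and k the largest index such
#' that the cumulative sum of the first k exponents is >= 0, the dimension is
#' k + (sum of first k exponents) / |lambda_(k+1)|.  Conventions for the
#' edges: if lambda_1 < 0 there is no expanding direction and the dimension
#' is 0; if the full sum is nonnegative the tracked spectrum cannot bound the
#' attractor and the list length m is returned.
#'
#' @param exponents numeric vector sorted nonincreasing.
#' @return the Kaplan-Yorke dimension.
#' @export
kaplan_yorke <- function(exponents) {
  stopifnot(is.numeric(exponents), length(exponents) >= 1)
  if (is.unsorted(rev(exponents))) stop("exponents must be nonincreasing")
  cs <- cumsum(exponents)
  ok <- which(cs >= 0)
  if (length(ok) == 0) return(0)
  k <- max(ok)
  if (k == length(exponents)) return(length(exponents))
  k + cs[k] / abs(exponents[k + 1])
}
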