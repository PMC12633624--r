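#' One step of the tanh rate network
#'
#' Computes x(t+1) = tanh(W x(t) + I(t)) componentwise.
#'
#' @param state numeric N-vector x(t).
#' @param weights N x N weight matrix.
#' @param input optional numeric N-vector of external input (default zero).
#' @return numeric N-vector, every component strictly inside (-1, 1).
#' @export
step_rnn <- function(state, weights, input = NULL) {
  n <- length(state)
  if (!is.matrix(weights) || nrow(weights) != n || ncol(weights) != n)
    stop("weights must be an N x N matrix matching the state length")
  pre <- drop(weights %*% state)
  if (!is.null(input)) {
    if (length(input) != n) stop("input length must match the state length")
    pre <- pre + input
  }
  tanh(pre)
}

#' Simulate the recurrent network
#'
#' Iterates the tanh network for `horizon` steps with a fixed (quenched)
#' weight matrix, optionally driven by i.i.d. Gaussian inputs (fresh per step
#' and unit; default variance 0.01).  When `config$seed` is set, the weight
#' matrix, the random initial condition and the input stream are all drawn
#' from a stream seeded from it, so trajectories are reproducible.
#'
#' @param config a [network_config()].
#' @param horizon number of update steps T (>= 1).
#' @param input `"none"` or `"gaussian"`.
#' @param input_variance per-unit variance of the Gaussian drive.
#' @param init `"random"` (components i.i.d. uniform on (-1, 1)) or a numeric
#'   N-vector.
#' @param weights optional pre-drawn weight matrix to reuse.
#' @return an `rnn_trajectory`: list with `states` ((T+1) x N matrix, initial
#'   state in row 1), `horizon`, `input_kind`, and the `config`.
#' @export
simulate_rnn <- function(config, horizon, input = c("none", "gaussian"),
                         input_variance = 0.01, init = "random",
                         weights = NULL) {
  stopifnot(inherits(config, "network_config"), horizon >= 1)
  input <- match.arg(input)
  n <- config$n_units
  states <- with_seed(config$seed, {
    if (is.null(weights)) weights <- sample_weight_matrix(
      network_config(n, config$alpha, config$gain))
    x0 <- if (identical(init, "random")) runif(n, -1, 1) else as.numeric(init)
    if (length(x0) != n) stop("init must have length n_units")
    inputs <- if (input == "gaussian")
      matrix(rnorm(horizon * n, sd = sqrt(input_variance)), horizon, n)
    cpp_simulate_rnn(weights, x0, inputs, as.integer(horizon))
  })
  structure(list(states = states, horizon = as.integer(horizon),
                 input_kind = input, config = config),
            class = "rnn_trajectory")
}

#' Jacobian of one network step
#'
#' The exact Jacobian of x -> tanh(W x + I) evaluated on the post-update
#' state x(t+1) is diag(1 - x(t+1)^2) W; at the quiescent state it is W
#' itself since tanh'(0) = 1.
#'
#' @param next_state the post-update state x(t+1) of the step being
#'   differentiated.
#' @param weights N x N weight matrix.
#' @return N x N Jacobian matrix.
#' @export
rnn_jacobian <- function(next_state, weights) {
  n <- length(next_state)
  if (!is.matrix(weights) || nrow(weights) != n || ncol(weights) != n)
    stop("weights must be an N x N matrix matching the state length")
  (1 - next_state^2) * weights
}

#' Linearized (Kesten) dynamics with log-magnitude bookkeeping
#'
#' Evolves the linearization around the quiescent state,
#' eps(t+1) = W(t) eps(t), for `depth` steps.  In `annealed` mode a fresh
#' alpha-stable weight matrix is drawn every step (the feedforward picture);
#' in `quenched` mode one matrix is drawn once and reused.  The state is
#' renormalized to a unit 2-norm direction every step and its magnitude
#' carried as a natural logarithm, so arbitrarily deep sub- or super-critical
#' propagation neither underflows nor overflows.  Per-step log growth of the
#' 2-norm and of the alpha-norm is recorded (the latter is the quantity the
#' scalar stability-property recursion predicts in annealed mode).
#'
#' @param config a [network_config()].
#' @param mode `"annealed"` or `"quenched"`.
#' @param depth number of steps T (>= 1).
#' @param init `"random"` (i.i.d. uniform on (-1, 1)) or a nonzero numeric
#'   N-vector.
#' @param weights optional quenched matrix to reuse (quenched mode only).
#' @return a `loglinear_state`: list with unit-2-norm `direction`,
#'   `log_magnitude`, per-step `log_growth` (2-norm) and `log_growth_alpha`,
#'   `mode`, `depth`, `config`.
#' @export
simulate_linear <- function(config, mode = c("annealed", "quenched"), depth,
                            init = "random", weights = NULL) {
  stopifnot(inherits(config, "network_config"), depth >= 1)
  mode <- match.arg(mode)
  n <- config$n_units
  alpha <- config$alpha
  out <- with_seed(config$seed, {
    x0 <- if (identical(init, "random")) runif(n, -1, 1) else as.numeric(init)
    if (length(x0) != n) stop("init must have length n_units")
    if (all(x0 == 0)) stop("initial vector must be nonzero")
    if (mode == "annealed") {
      cpp_linear_annealed(x0, alpha, config$scale, as.integer(depth))
    } else {
      if (is.null(weights)) weights <- sample_weight_matrix(
        network_config(n, alpha, config$gain))
      v <- x0
      nrm <- sqrt(sum(v^2))
      logmag <- log(nrm)
      v <- v / nrm
      g2 <- ga <- numeric(depth)
      for (t in seq_len(depth)) {
        an_before <- sum(abs(v)^alpha)
        w <- drop(weights %*% v)
        nrm <- sqrt(sum(w^2))
        if (nrm == 0 || !is.finite(nrm))
          stop("degenerate propagation at step ", t)
        g2[t] <- log(nrm)
        ga[t] <- (log(sum(abs(w)^alpha)) - log(an_before)) / alpha
        logmag <- logmag + g2[t]
        v <- w / nrm
      }
      list(direction = v, log_magnitude = logmag, log_growth = g2,
           log_growth_alpha = ga)
    }
  })
  structure(c(out, list(mode = mode, depth = as.integer(depth),
                        config = config)),
            class = "loglinear_state")
}

#' Log-magnitudes of the final linearized state
#'
#' Returns log|eps_i(T)| for each component, computed in log space as
#' log|direction_i| + log_magnitude so that states far from the transition
#' (whose true magnitudes overflow doubles) remain comparable.
#'
#' @param state a `loglinear_state` from [simulate_linear()].
#' @return numeric N-vector of natural-log magnitudes (-Inf for exact zeros).
#' @export
final_log_abs <- function(state) {
  stopifnot(inherits(state, "loglinear_state"))
  log(abs(state$direction)) + state$log_magnitude
}

#' Quiescence order parameter
#'
#' Fraction of components of the final linearized state within `threshold`
#' of zero: 1 deep in the quiescent phase, 0 above the transition.  For a
#' `loglinear_state` the comparison |eps_i| < threshold is evaluated in log
#' space, so super-critical runs whose magnitudes overflow are handled
#' exactly.
#'
#' @param state numeric vector of final-state components, or a
#'   `loglinear_state`.
#' @param threshold positive closeness threshold epsilon (default 0.1).
#' @return fraction in \[0, 1\].
#' @export
order_parameter <- function(state, threshold = 0.1) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (inherits(state, "loglinear_state"))
    return(mean(final_log_abs(state) < log(threshold)))
  stopifnot(is.numeric(state))
  mean(abs(state) < threshold)
}
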