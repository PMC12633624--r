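#' Monte-Carlo estimate of the finite-size log-growth correction Xi
#'
#' Estimates `Xi(N, alpha) = E[(1/alpha) log((1/N) sum_j |z_j|^alpha)]` with
#' z_j i.i.d. unit-scale symmetric alpha-stable, the expected per-step
#' log-growth correction of the annealed linearized dynamics.  The annealed
#' critical gain is g* = exp(-Xi): below it perturbations of the quiescent
#' state contract, above it they expand.
#'
#' The expectation is placed outside the logarithm: inside, E|z|^alpha
#' diverges for alpha < 2 and the quantity would be undefined, while the
#' outside placement reproduces the Gaussian limit Xi = log(sqrt(2)) and the
#' (log N)^(-1/alpha) asymptotics, and is what the norm-process derivation
#' yields.
#'
#' @param n_units network size N.
#' @param alpha stability index in (0, 2].
#' @param n_samples Monte-Carlo replicates (>= 100; default 10^4).
#' @param seed optional seed for the estimate's stream.
#' @return a `theory_prediction`: list with `n_units`, `alpha`, `xi`,
#'   `xi_stderr`, `g_star = exp(-xi)`, `n_samples`, `seed`.
#' @export
xi_monte_carlo <- function(n_units, alpha, n_samples = 1e4, seed = NULL) {
  check_alpha(alpha)
  stopifnot(n_units >= 1, n_samples >= 100)
  xs <- with_seed(seed, cpp_xi_samples(n_units, alpha, as.integer(n_samples)))
  xi <- mean(xs)
  structure(list(n_units = n_units, alpha = alpha, xi = xi,
                 xi_stderr = sd(xs) / sqrt(length(xs)),
                 g_star = exp(-xi), n_samples = as.integer(n_samples),
                 seed = seed),
            class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf(
    "<theory_prediction> N = %g, alpha = %g: Xi = %.5f (se %.2g), g* = %.5f\n",
    x$n_units, x$alpha, x$xi, x$xi_stderr, x$g_star))
  invisible(x)
}

#' Closed-form Xi for Gaussian networks (alpha = 2)
#'
#' For alpha = 2, (1/N) sum z_j^2 with z ~ N(0, 2) is distributed as
#' (2/N) chi^2_N, and E log chi^2_N = log 2 + digamma(N/2), giving the exact
#' value Xi(N, 2) = (digamma(N/2) + log(4/N)) / 2.  As N grows this tends to
#' log(sqrt(2)), i.e. g* -> 1/sqrt(2), recovering the classical Gaussian
#' transition at `N E[W^2] = 1`.
#'
#' @param n_units network size N (vectorized); `Inf` gives the limit
#'   log(2)/2.
#' @return numeric vector of Xi values.
#' @export
xi_gaussian <- function(n_units) {
  stopifnot(is.numeric(n_units), all(n_units >= 1))
  ifelse(is.infinite(n_units), log(2) / 2,
         (digamma(n_units / 2) + log(4 / n_units)) / 2)
}

#' Annealed critical gain g*(N, alpha)
#'
#' Returns g* = exp(-Xi(N, alpha)).  For alpha = 2 the exact digamma closed
#' form is used by default (Monte Carlo remains available for
#' cross-validation); other alpha use [xi_monte_carlo()].
#'
#' @inheritParams xi_monte_carlo
#' @param exact_gaussian use the closed form when alpha = 2 (default TRUE).
#' @return numeric vector of critical gains, one per element of `n_units`.
#' @export
critical_gain <- function(n_units, alpha, n_samples = 1e4, seed = NULL,
                          exact_gaussian = TRUE) {
  check_alpha(alpha)
  if (alpha == 2 && exact_gaussian) return(exp(-xi_gaussian(n_units)))
  seeds <- if (is.null(seed)) vector("list", length(n_units))
           else as.list(spawn_seeds(seed, length(n_units)))
  vapply(seq_along(n_units), function(i)
    xi_monte_carlo(n_units[i], alpha, n_samples, seeds[[i]])$g_star,
    numeric(1))
}

#' Asymptotic decay of the critical gain with network size
#'
#' For alpha < 2 the critical gain decays logarithmically,
#' g* ~ 1/(log N)^(1/alpha), so the regression of log g*(N) on log log N
#' should have slope near -1/alpha.  Fits that regression over a grid of
#' network sizes and returns the slope together with the per-N estimates.
#' For alpha = 2 the digamma closed form is used and the slope is instead
#' near 0 (the Gaussian g* converges to a constant).
#'
#' @param alpha stability index in (0, 2].
#' @param n_grid vector of at least two network sizes, ideally spanning
#'   several decades.
#' @param n_samples Monte-Carlo replicates per grid point.
#' @param seed optional root seed.
#' @return an `asymptotic_fit`: list with `slope`, `expected_slope`
#'   (-1/alpha, or 0 for alpha = 2), the fitted `lm` object and a `table` of
#'   (n_units, xi, g_star).
#' @export
asymptotic_gain_check <- function(alpha, n_grid, n_samples = 500,
                                  seed = NULL) {
  check_alpha(alpha)
  if (length(n_grid) < 2) stop("n_grid too short: need at least two sizes")
  if (any(n_grid <= exp(1))) stop("n_grid sizes must exceed e for log log N")
  g <- critical_gain(n_grid, alpha, n_samples, seed)
  tab <- data.frame(n_units = n_grid, xi = -log(g), g_star = g)
  fit <- lm(log(g_star) ~ log(log(n_units)), data = tab)
  structure(list(slope = unname(coef(fit)[2]),
                 expected_slope = if (alpha == 2) 0 else -1 / alpha,
                 fit = fit, table = tab),
            class = "asymptotic_fit")
}

#' Theory table over an (N, alpha) grid
#'
#' Tabulates Xi and g* over a grid of sizes and stability indices — the data
#' behind the transition-point-versus-size curves.
#'
#' @param n_grid vector of network sizes.
#' @param alpha_grid vector of stability indices.
#' @param n_samples Monte-Carlo replicates per cell.
#' @param seed optional root seed.
#' @return data frame with columns n_units, alpha, xi, xi_stderr, g_star,
#'   n_samples, seed.
#' @export
theory_table <- function(n_grid, alpha_grid, n_samples = 1e4, seed = NULL) {
  grid <- expand.grid(n_units = n_grid, alpha = alpha_grid)
  seeds <- if (is.null(seed)) vector("list", nrow(grid))
           else as.list(spawn_seeds(seed, nrow(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- xi_monte_carlo(grid$n_units[i], grid$alpha[i], n_samples, seeds[[i]])
    data.frame(n_units = p$n_units, alpha = p$alpha, xi = p$xi,
               xi_stderr = p$xi_stderr, g_star = p$g_star,
               n_samples = p$n_samples,
               seed = if (is.null(seeds[[i]])) NA_integer_ else seeds[[i]])
  })
  do.call(rbind, rows)
}
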