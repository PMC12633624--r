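#' Symmetric alpha-stable distribution specification
#'
#' Bundles the stability index alpha and scale sigma of a centered symmetric
#' Levy alpha-stable law in the convention where the characteristic function
#' at argument k is exp(-|sigma k|^alpha).  Under this convention alpha = 2
#' is Gaussian with variance 2 sigma^2 (not sigma^2) and alpha = 1 with
#' sigma = 1 is the standard Cauchy.
#'
#' @param alpha stability index in (0, 2].
#' @param scale scale sigma > 0.
#' @return an object of class `stable_spec`.
#' @export
stable_spec <- function(alpha, scale = 1) {
  check_alpha(alpha)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(list(alpha = alpha, scale = scale), class = "stable_spec")
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 2)
    stop("alpha must be a single number in (0, 2]", call. = FALSE)
  invisible(alpha)
}

#' Network configuration
#'
#' Describes an N-unit network with i.i.d. symmetric alpha-stable weights of
#' scale sigma = gain / N^(1/alpha); the gain g is the control parameter of
#' the quiescent-to-chaotic transition.
#'
#' @param n_units number of units N (positive integer).
#' @param alpha stability index in (0, 2].
#' @param gain gain g >= 0.
#' @param seed optional integer seed making weight draws reproducible.
#' @return an object of class `network_config` with the induced `scale`.
#' @export
network_config <- function(n_units, alpha, gain, seed = NULL) {
  stopifnot(is.numeric(n_units), length(n_units) == 1L, n_units >= 1,
            n_units == round(n_units))
  check_alpha(alpha)
  stopifnot(is.numeric(gain), length(gain) == 1L, gain >= 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(n_units = as.integer(n_units), alpha = alpha, gain = gain,
                 scale = gain / n_units^(1 / alpha), seed = seed),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> N = %d, alpha = %g, gain = %g (scale = %g)\n",
              x$n_units, x$alpha, x$gain, x$scale))
  invisible(x)
}

#' Sample symmetric alpha-stable variates
#'
#' Exact Chambers-Mallows-Stuck sampling of centered symmetric alpha-stable
#' variates with characteristic function exp(-|scale * k|^alpha).  The
#' alpha = 1 branch reduces to the tangent of a uniform angle (standard
#' Cauchy); alpha = 2 yields N(0, 2 scale^2).  Draws come from the current R
#' random stream.
#'
#' @param n number of draws.
#' @param alpha stability index in (0, 2].
#' @param scale scale sigma >= 0 (0 gives the point mass at 0).
#' @return numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' var(rstable(1e4, alpha = 2))  # close to 2
#' @export
rstable <- function(n, alpha, scale = 1) {
  check_alpha(alpha)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale >= 0)
  if (scale == 0) return(numeric(n))
  scale * cpp_rstable(n, alpha)
}

#' Draw a network weight matrix
#'
#' Samples the N x N matrix of i.i.d. symmetric alpha-stable weights with
#' scale gain / N^(1/alpha).  If `config$seed` is set, the draw is performed
#' on a stream seeded from it (and the caller's stream is untouched), so
#' identical configurations yield bit-identical matrices.
#'
#' Extreme draws are kept by default: the heavy-tail phenomenology is driven
#' by rare outlier weights ("mega-synapses").  An optional magnitude clip is
#' available for sensitivity analyses.
#'
#' @param config a [network_config()].
#' @param clip optional positive threshold; entries with |w| > clip are set
#'   to sign(w) * clip.  Default `NULL` (no clipping).
#' @return N x N numeric matrix.
#' @export
sample_weight_matrix <- function(config, clip = NULL) {
  stopifnot(inherits(config, "network_config"))
  n <- config$n_units
  w <- with_seed(config$seed,
                 matrix(rstable(n * n, config$alpha, config$scale), n, n))
  if (!is.null(clip)) {
    stopifnot(is.numeric(clip), clip > 0)
    w[w > clip] <- clip
    w[w < -clip] <- -clip
  }
  w
}

#' Empirical characteristic function
#'
#' Estimates `E[exp(i k X)] = E[cos(kX)] + i E[sin(kX)]` at each requested k
#' from a sample, with Monte-Carlo standard errors of the real and imaginary
#' parts.  Used to verify the stable-law contract exp(-|sigma k|^alpha).
#'
#' @param samples nonempty numeric vector.
#' @param k_values numeric vector of characteristic-function arguments.
#' @return data frame with columns `k`, `real`, `imag`, `se_real`, `se_imag`
#'   and a complex column `estimate`.
#' @export
empirical_cf <- function(samples, k_values) {
  if (length(samples) == 0) stop("empty sample list")
  stopifnot(is.numeric(samples), is.numeric(k_values))
  n <- length(samples)
  res <- vapply(k_values, function(k) {
    cs <- cos(k * samples)
    sn <- sin(k * samples)
    c(mean(cs), mean(sn),
      if (n > 1) sd(cs) / sqrt(n) else 0,
      if (n > 1) sd(sn) / sqrt(n) else 0)
  }, numeric(4))
  out <- data.frame(k = k_values, real = res[1, ], imag = res[2, ],
                    se_real = res[3, ], se_imag = res[4, ])
  out$estimate <- complex(real = out$real, imaginary = out$imag)
  out
}
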