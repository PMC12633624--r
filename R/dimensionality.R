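#' Steady-state empirical covariance of network activity
#'
#' Mean-centered covariance of the last `retain` recorded states (divisor
#' retain - 1), with the symmetric eigenvalue decomposition attached.  Tiny
#' negative eigenvalues from roundoff are clipped to zero.  Well-conditioned
#' estimates want more retained steps than units (K > N); a warning — not an
#' error — is raised otherwise.
#'
#' @param trajectory an `rnn_trajectory`, or a time-by-units state matrix.
#' @param retain number of final steps K to keep (>= 2; default all rows).
#' @return a `covariance_summary`: `matrix` (N x N), `eigenvalues`
#'   (nonincreasing, >= 0), `n_samples` (= retain), `mean_state`.
#' @export
empirical_covariance <- function(trajectory, retain = NULL) {
  states <- if (inherits(trajectory, "rnn_trajectory")) trajectory$states
            else as.matrix(trajectory)
  if (is.null(retain)) retain <- nrow(states)
  if (retain < 2) stop("retain must be at least 2")
  if (retain > nrow(states)) stop("retain exceeds the trajectory length")
  x <- states[(nrow(states) - retain + 1):nrow(states), , drop = FALSE]
  if (retain <= ncol(x))
    warning("retained steps (", retain, ") do not exceed the number of ",
            "units (", ncol(x), "); covariance will be rank-deficient")
  s <- cov(x)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    warning("covariance has a substantially negative eigenvalue")
  ev <- pmax(ev, 0)
  structure(list(matrix = s, eigenvalues = ev, n_samples = as.integer(retain),
                 mean_state = colMeans(x)),
            class = "covariance_summary")
}

#' Participation ratio
#'
#' PR = (sum lambda)^2 / sum lambda^2 over covariance eigenvalues: the
#' effective number of orthogonal directions carrying variance, ranging from
#' 1 (all variance in one mode) to N (uniform variance).  Eigenvalues below
#' 1e-12 times the largest are clipped to zero first; an all-zero spectrum
#' (no variance at all) is undefined and raises an error.
#'
#' @param x nonnegative eigenvalue vector, or a `covariance_summary`.
#' @return the participation ratio.
#' @export
participation_ratio <- function(x) {
  ev <- if (inherits(x, "covariance_summary")) x$eigenvalues else x
  stopifnot(is.numeric(ev), length(ev) >= 1, all(ev >= 0))
  top <- max(ev)
  if (top == 0) stop("all eigenvalues are zero: participation ratio undefined")
  ev[ev < 1e-12 * top] <- 0
  sum(ev)^2 / sum(ev^2)
}
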