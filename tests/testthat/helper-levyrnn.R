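# Shared fixtures built in code.

# Haar-ish random orthogonal matrix from the QR of a Gaussian matrix,
# sign-fixed so R has positive diagonal.
random_orthogonal <- function(n) {
  qrd <- qr(matrix(rnorm(n * n), n, n))
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))), n)
}

# Central finite-difference Jacobian of one network step.
fd_jacobian <- function(state, weights, input = NULL, h = 1e-6) {
  n <- length(state)
  jac <- matrix(0, n, n)
  for (j in seq_len(n)) {
    up <- dn <- state
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    jac[, j] <- (step_rnn(up, weights, input) - step_rnn(dn, weights, input)) /
      (2 * h)
  }
  jac
}

# Two-pass textbook covariance (independent oracle).
two_pass_cov <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  crossprod(xc) / (nrow(x) - 1)
}
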