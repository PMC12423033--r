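# Independent univariate variational-mode-decomposition oracle.
# Deliberately written as a plain scalar-loop implementation (single
# channel, explicit per-bin loops where cheap enough) so it shares no code
# with the package solver; used to pin down the C = 1 behavior.
vmd_oracle <- function(x, K, alpha = 1000, tau = 0, tol = 1e-7,
                       max_iter = 500, mirror = TRUE) {
  n <- length(x)
  if (mirror) {
    h <- floor(n / 2)
    x_ext <- c(rev(x[1:h]), x, rev(x[(n - h + 1):n]))
  } else {
    x_ext <- x
  }
  Tn <- length(x_ext)
  f_hat <- fft(x_ext)
  n_pos <- floor(Tn / 2) + 1L
  freqs <- (0:(n_pos - 1)) / Tn
  fx <- f_hat[1:n_pos]

  omega <- if (K == 1) 0 else seq(0, 0.25, length.out = K)
  u_hat <- matrix(0 + 0i, K, n_pos)
  lam <- rep(0 + 0i, n_pos)
  it <- 0
  repeat {
    it <- it + 1
    diff_acc <- 0
    for (k in 1:K) {
      others <- rep(0 + 0i, n_pos)
      for (j in 1:K) if (j != k) others <- others + u_hat[j, ]
      new_u <- (fx - others + lam / 2) / (1 + 2 * alpha * (freqs - omega[k])^2)
      p <- Abs(new_u)^2
      if (sum(p) > 0) omega[k] <- sum(freqs * p) / sum(p)
      diff_acc <- diff_acc + sum(Abs(new_u - u_hat[k, ])^2) /
        (sum(Abs(u_hat[k, ])^2) + .Machine$double.eps)
      u_hat[k, ] <- new_u
    }
    if (tau > 0) {
      tot <- rep(0 + 0i, n_pos)
      for (k in 1:K) tot <- tot + u_hat[k, ]
      lam <- lam + tau * (fx - tot)
    }
    if (diff_acc <= tol || it >= max_iter) break
  }

  modes <- matrix(0, K, n)
  for (k in 1:K) {
    spec <- rep(0 + 0i, Tn)
    spec[1:n_pos] <- u_hat[k, ]
    if (Tn %% 2 == 0) {
      spec[n_pos] <- Re(spec[n_pos])
      for (j in 2:(n_pos - 1)) spec[Tn - j + 2] <- Conj(spec[j])
    } else {
      for (j in 2:n_pos) spec[Tn - j + 2] <- Conj(spec[j])
    }
    ut <- Re(fft(spec, inverse = TRUE)) / Tn
    modes[k, ] <- if (mirror) ut[(floor(n / 2) + 1):(floor(n / 2) + n)] else ut
  }
  ord <- order(omega)
  list(omega = omega[ord], modes = modes[ord, , drop = FALSE], iterations = it)
}

Abs <- Mod # modulus of complex values; alias keeps the oracle readable

# two-tone univariate fixture used in several oracle comparisons
two_tone <- function(f1, f2, a1 = 1, a2 = 1, n = 800, dt = 0.72,
                     phase1 = 0, phase2 = 0) {
  t <- (seq_len(n) - 1) * dt
  a1 * cos(2 * pi * f1 * t + phase1) + a2 * cos(2 * pi * f2 * t + phase2)
}
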