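# Independent reference implementations used as oracles. These are written
# as plain elementwise loops, deliberately sharing no code with the package
# internals they check.

# one LSTM cell update, scalar arithmetic over units
scalar_lstm_step <- function(p, h_prev, c_prev, x) {
  H <- length(h_prev)
  z <- c(h_prev, x)
  h <- numeric(H); cc <- numeric(H)
  for (u in seq_len(H)) {
    af <- sum(p$W_f[u, ] * z) + p$b_f[u]
    ai <- sum(p$W_i[u, ] * z) + p$b_i[u]
    ao <- sum(p$W_o[u, ] * z) + p$b_o[u]
    ag <- sum(p$W_c[u, ] * z) + p$b_c[u]
    f <- 1 / (1 + exp(-af)); i <- 1 / (1 + exp(-ai)); o <- 1 / (1 + exp(-ao))
    g <- tanh(ag)
    cc[u] <- f * c_prev[u] + i * g
    h[u] <- o * tanh(cc[u])
  }
  list(h = h, C = cc)
}

# full bidirectional layer by scalar loops
scalar_bilstm_layer <- function(pf, pb, seqm) {
  T_ <- nrow(seqm); H <- pf$hidden
  out <- matrix(NA_real_, T_, 2 * H)
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(T_)) {
    st <- scalar_lstm_step(pf, h, cc, seqm[t, ])
    h <- st$h; cc <- st$C
    out[t, 1:H] <- h
  }
  h <- numeric(H); cc <- numeric(H)
  for (t in rev(seq_len(T_))) {
    st <- scalar_lstm_step(pb, h, cc, seqm[t, ])
    h <- st$h; cc <- st$C
    out[t, H + (1:H)] <- h
  }
  out
}

random_cell <- function(hidden, input) {
  W <- function() matrix(rnorm(hidden * (hidden + input), sd = 0.6), hidden)
  lstm_cell_params(W(), W(), W(), W(),
                   rnorm(hidden), rnorm(hidden), rnorm(hidden), rnorm(hidden))
}

# natural cubic spline by a dense linear solve for the knot second
# derivatives (no Thomas recursion), then direct piecewise evaluation
dense_natural_spline <- function(xk, yk, xout) {
  n <- length(xk)
  h <- diff(xk)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((yk[i + 1] - yk[i]) / h[i] - (yk[i] - yk[i - 1]) / h[i - 1])
  }
  M <- solve(A, rhs)
  vapply(xout, function(x) {
    i <- max(1, min(n - 1, findInterval(x, xk, rightmost.closed = TRUE)))
    a <- (xk[i + 1] - x) / h[i]; b <- (x - xk[i]) / h[i]
    a * yk[i] + b * yk[i + 1] +
      ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1]) * h[i]^2 / 6
  }, numeric(1))
}

# generalized eigenproblem S_A w = lambda (S_A + S_B) w via a plain
# non-symmetric eigensolve of (S_A + S_B)^-1 S_A
dense_csp_oracle <- function(SA, SB) {
  e <- eigen(solve(SA + SB) %*% SA)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord], vectors = Re(e$vectors)[, ord])
}

cosine_abs <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
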