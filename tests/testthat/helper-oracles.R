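# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (triple loops, scalar arithmetic) so they share no
# code path with the implementation they check.

naive_conv1d <- function(input, kernels, bias) {
  L <- nrow(input); C <- ncol(input)
  K <- dim(kernels)[1]; F <- dim(kernels)[3]
  out <- matrix(0, L - K + 1, F)
  for (t in seq_len(L - K + 1))
    for (f in seq_len(F)) {
      acc <- bias[f]
      for (m in seq_len(K))
        for (c in seq_len(C))
          acc <- acc + input[t + m - 1, c] * kernels[m, c, f]
      out[t, f] <- acc
    }
  out
}

naive_lstm_step <- function(params, x_t, h_prev, c_prev) {
  U <- length(h_prev)
  hx <- c(h_prev, x_t)
  sig <- function(z) 1 / (1 + exp(-z))
  f <- i <- o <- g <- cc <- h <- numeric(U)
  for (u in seq_len(U)) {
    f[u] <- sig(sum(params$W_f[u, ] * hx) + params$b_f[u])
    i[u] <- sig(sum(params$W_i[u, ] * hx) + params$b_i[u])
    g[u] <- tanh(sum(params$W_c[u, ] * hx) + params$b_c[u])
    cc[u] <- f[u] * c_prev[u] + i[u] * g[u]
    o[u] <- sig(sum(params$W_o[u, ] * hx) + params$b_o[u])
    h[u] <- o[u] * tanh(cc[u])
  }
  list(h = h, c = cc)
}

random_lstm_params <- function(U, D) {
  m <- function() matrix(rnorm(U * (U + D)), U, U + D)
  list(W_f = m(), W_i = m(), W_o = m(), W_c = m(),
       b_f = rnorm(U), b_i = rnorm(U), b_o = rnorm(U), b_c = rnorm(U))
}

naive_confusion <- function(y_true, y_pred) {
  lv <- stage_levels()
  m <- matrix(0L, 5, 5, dimnames = list(lv, lv))
  for (i in seq_along(y_true))
    m[as.character(y_true[i]), as.character(y_pred[i])] <-
      m[as.character(y_true[i]), as.character(y_pred[i])] + 1L
  m
}

count_zero_crossings_oracle <- function(x) {
  s <- sign(x); s <- s[s != 0]; sum(diff(s) != 0)
}
count_extrema_oracle <- function(x) {
  d <- diff(x); s <- sign(d); s <- s[s != 0]; sum(diff(s) != 0)
}

# small architecture used where the full canonical network would be slow
tiny_config <- function(n_classes = 5) {
  model_config(input_len = 60, input_channels = 2, lstm_units = 8,
               lstm_layers = 2, conv_specs = list(c(8, 5), c(8, 5)),
               pool_size = 3, fc_sizes = c(16, 8), n_classes = n_classes,
               dropout_conv = 0.2, dropout_fc = 0.5)
}

welch_peak_hz <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 5,
                          plot = FALSE, taper = 0, detrend = TRUE)
  sp$freq[which.max(sp$spec)]
}
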