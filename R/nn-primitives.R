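# Reference (double-precision, pure R) network primitives.  These define
# the numerical semantics of the stager; the compiled training engine is
# cross-checked against them in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Rectified linear unit, `f(x) = max(0, x)`
#' @param x Numeric.
#' @return Numeric of the same shape.
#' @export
relu <- function(x) pmax(x, 0)

#' Softmax over the rows of a matrix (or a single vector)
#' @param x Numeric matrix (rows are examples) or vector.
#' @return Matrix/vector of probabilities; rows sum to one.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Valid (unpadded) 1-D cross-correlation
#'
#' `output[t, f] = bias[f] + sum_{m, c} input[t + m - 1, c] * kernels[m, c, f]`
#' -- the sliding weighted sum used by convolutional layers, applied
#' without kernel flipping (cross-correlation) and without padding, stride
#' one.
#'
#' @param input Numeric matrix `L x C` (time by channels).
#' @param kernels Numeric array `K x C x F` (taps by input channels by
#'   filters).
#' @param bias Numeric vector of length `F`.
#' @return Numeric matrix `(L - K + 1) x F`.
#' @examples
#' conv1d_valid(matrix(1:4), array(c(1, 1), c(2, 1, 1)), 0)  # 3, 5, 7
#' @export
conv1d_valid <- function(input, kernels, bias = NULL) {
  input <- as.matrix(input)
  if (length(dim(kernels)) != 3)
    stop("kernels must be a K x C x F array", call. = FALSE)
  K <- dim(kernels)[1]; C <- dim(kernels)[2]; F <- dim(kernels)[3]
  L <- nrow(input)
  if (ncol(input) != C)
    stop(sprintf("input has %d channels but kernels expect %d",
                 ncol(input), C), call. = FALSE)
  if (K > L) stop("kernel longer than input", call. = FALSE)
  if (is.null(bias)) bias <- numeric(F)
  if (length(bias) != F) stop("bias length must equal filter count",
                              call. = FALSE)
  Lo <- L - K + 1L
  # im2col: row t holds the K x C window starting at t
  M <- matrix(0, Lo, K * C)
  for (m in seq_len(K))
    M[, (m - 1L) * C + seq_len(C)] <- input[(m - 1L) + seq_len(Lo), ,
                                            drop = FALSE]
  W <- matrix(aperm(kernels, c(2, 1, 3)), nrow = K * C)  # row = (m-1)*C + c
  sweep(M %*% W, 2, bias, `+`)
}

#' One LSTM cell step
#'
#' The gated recurrence: forget gate `f = sigmoid(W_f [h, x] + b_f)`,
#' input gate `i = sigmoid(W_i [h, x] + b_i)`, candidate
#' `g = tanh(W_c [h, x] + b_c)`, cell state `c = f * c_prev + i * g`,
#' output gate `o = sigmoid(W_o [h, x] + b_o)`, hidden state
#' `h = o * tanh(c)` (elementwise products).
#'
#' @param params List with matrices `W_f, W_i, W_o, W_c` (`U x (U + D)`,
#'   acting on the concatenation `[h_prev, x_t]`) and bias vectors
#'   `b_f, b_i, b_o, b_c` (length `U`).
#' @param x_t Input vector (length `D`).
#' @param h_prev,c_prev Previous hidden and cell state (length `U`).
#' @return List with `h` and `c` (length `U`).
#' @examples
#' p <- list(W_f = matrix(0, 2, 3), W_i = matrix(0, 2, 3),
#'           W_o = matrix(0, 2, 3), W_c = matrix(0, 2, 3),
#'           b_f = c(0, 0), b_i = c(0, 0), b_o = c(0, 0), b_c = c(0, 0))
#' lstm_cell_step(p, x_t = 1, h_prev = c(0, 0), c_prev = c(1, 2))$c  # 0.5, 1
#' @export
lstm_cell_step <- function(params, x_t, h_prev, c_prev) {
  hx <- c(h_prev, x_t)
  U <- length(h_prev)
  for (nm in c("W_f", "W_i", "W_o", "W_c")) {
    W <- params[[nm]]
    if (!is.matrix(W) || nrow(W) != U || ncol(W) != length(hx))
      stop(nm, " must be a ", U, " x ", length(hx), " matrix", call. = FALSE)
  }
  f <- sigmoid(drop(params$W_f %*% hx) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% hx) + params$b_i)
  g <- tanh(drop(params$W_c %*% hx) + params$b_c)
  cc <- f * c_prev + i * g
  o <- sigmoid(drop(params$W_o %*% hx) + params$b_o)
  list(h = o * tanh(cc), c = cc)
}

#' Softmax-weighted pooling of an LSTM hidden-state sequence
#'
#' `alpha = softmax(scores)`; output `y = sum_i alpha[i] * h[i, ]`.  An
#' optional alternative to last-step pooling of the LSTM branch (off in
#' the canonical configuration).
#'
#' @param h_sequence Numeric matrix `T x U` of hidden states.
#' @param scores Numeric vector of length `T`.
#' @return Numeric vector of length `U`.
#' @export
attention_pool <- function(h_sequence, scores) {
  h_sequence <- as.matrix(h_sequence)
  stopifnot(nrow(h_sequence) >= 1, length(scores) == nrow(h_sequence))
  a <- drop(softmax(scores))
  drop(crossprod(h_sequence, a))
}
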