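# Parameter initialization and the reference forward pass.

GLOROT <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an untrained stager model
#'
#' Allocates and seeds all trainable parameters for a configuration:
#' per-layer LSTM input/recurrent weights and biases (gate order
#' input/forget/candidate/output, forget bias initialized to 1),
#' convolution kernels and biases with batch-normalization scale/shift and
#' running statistics, fully connected layers, and a zero-initialized
#' softmax layer (so an untrained model outputs uniform class
#' probabilities).  Weights use Glorot-uniform initialization and are
#' deterministic given `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Object of class `stager_params`: named list of numeric arrays.
#' @export
build_model <- function(config, seed = 1) {
  trace <- shape_trace(config)  # validates the architecture
  seed <- as.integer(seed)
  local_seed(seed)
  U <- config$lstm_units
  p <- list()
  din <- config$input_channels
  for (l in seq_len(config$lstm_layers)) {
    p[[sprintf("lstm%d_Wx", l)]] <- GLOROT(din, 4 * U)
    p[[sprintf("lstm%d_Uh", l)]] <- GLOROT(U, 4 * U)
    b <- numeric(4 * U)
    b[U + seq_len(U)] <- 1  # forget-gate bias
    p[[sprintf("lstm%d_b", l)]] <- b
    din <- U
  }
  cin <- config$input_channels
  for (i in seq_along(config$conv_specs)) {
    cs <- config$conv_specs[[i]]   # (filters, kernel)
    p[[sprintf("conv%d_K", i)]] <- GLOROT(cs[2] * cin, cs[1])
    p[[sprintf("conv%d_b", i)]] <- numeric(cs[1])
    p[[sprintf("conv%d_gamma", i)]] <- rep(1, cs[1])
    p[[sprintf("conv%d_beta", i)]] <- numeric(cs[1])
    p[[sprintf("conv%d_rmean", i)]] <- numeric(cs[1])
    p[[sprintf("conv%d_rvar", i)]] <- rep(1, cs[1])
    cin <- cs[1]
  }
  flat <- trace_dim(trace, "concatenate")
  din <- flat
  for (i in seq_along(config$fc_sizes)) {
    p[[sprintf("fc%d_W", i)]] <- GLOROT(din, config$fc_sizes[i])
    p[[sprintf("fc%d_b", i)]] <- numeric(config$fc_sizes[i])
    din <- config$fc_sizes[i]
  }
  p$out_W <- matrix(0, din, config$n_classes)
  p$out_b <- numeric(config$n_classes)
  if (config$attention_pool) p$att_w <- numeric(U)
  structure(p, class = "stager_params", config = config, seed = seed)
}

BN_EPS <- 1e-5

# Reference forward pass of one epoch (matrix T x C, already at the model
# rate and gain).  Inference semantics: batch norm uses running statistics,
# dropout inactive.  Returns class scores (softmax probabilities) and,
# optionally, the realized per-layer output dimensions.
forward_one_ref <- function(params, config, x, return_trace = FALSE) {
  U <- config$lstm_units
  dims <- list(list(layer = "input", dim = dim(x)))
  # LSTM branch
  z <- x
  hseq <- NULL
  for (l in seq_len(config$lstm_layers)) {
    Wx <- params[[sprintf("lstm%d_Wx", l)]]
    Uh <- params[[sprintf("lstm%d_Uh", l)]]
    b <- params[[sprintf("lstm%d_b", l)]]
    h <- numeric(U); cc <- numeric(U)
    hs <- matrix(0, nrow(z), U)
    for (t in seq_len(nrow(z))) {
      g <- drop(z[t, ] %*% Wx) + drop(h %*% Uh) + b
      i_g <- sigmoid(g[seq_len(U)])
      f_g <- sigmoid(g[U + seq_len(U)])
      c_g <- tanh(g[2 * U + seq_len(U)])
      o_g <- sigmoid(g[3 * U + seq_len(U)])
      cc <- f_g * cc + i_g * c_g
      h <- o_g * tanh(cc)
      hs[t, ] <- h
    }
    hseq <- hs
    z <- hs
    dims[[length(dims) + 1L]] <- list(layer = sprintf("lstm%d", l),
                                      dim = if (l < config$lstm_layers)
                                        dim(hs) else U)
  }
  feat_lstm <- if (config$attention_pool)
    attention_pool(hseq, drop(hseq %*% params$att_w))
  else hseq[nrow(hseq), ]
  # convolutional branch
  a <- x
  for (i in seq_along(config$conv_specs)) {
    cs <- config$conv_specs[[i]]
    Km <- params[[sprintf("conv%d_K", i)]]       # (k*Cin) x F
    Karr <- array(0, c(cs[2], ncol(a), cs[1]))
    for (m in seq_len(cs[2]))
      Karr[m, , ] <- Km[(m - 1L) * ncol(a) + seq_len(ncol(a)), ]
    z1 <- conv1d_valid(a, Karr, params[[sprintf("conv%d_b", i)]])
    # batch normalization (inference: running statistics), then ReLU
    z1 <- sweep(sweep(z1, 2, params[[sprintf("conv%d_rmean", i)]], `-`), 2,
                sqrt(params[[sprintf("conv%d_rvar", i)]] + BN_EPS), `/`)
    z1 <- sweep(sweep(z1, 2, params[[sprintf("conv%d_gamma", i)]], `*`), 2,
                params[[sprintf("conv%d_beta", i)]], `+`)
    z1 <- relu(z1)
    dims[[length(dims) + 1L]] <- list(layer = sprintf("conv%d", i),
                                      dim = dim(z1))
    P <- nrow(z1) %/% config$pool_size
    pooled <- matrix(0, P, ncol(z1))
    for (p_ in seq_len(P)) {
      rows <- (p_ - 1L) * config$pool_size + seq_len(config$pool_size)
      pooled[p_, ] <- apply(z1[rows, , drop = FALSE], 2, max)
    }
    a <- pooled
    dims[[length(dims) + 1L]] <- list(layer = sprintf("pool%d", i),
                                      dim = dim(pooled))
  }
  flat <- as.vector(t(a))   # index (p-1)*F + f
  dims[[length(dims) + 1L]] <- list(layer = "flatten", dim = length(flat))
  feat <- c(feat_lstm, flat)
  dims[[length(dims) + 1L]] <- list(layer = "concatenate", dim = length(feat))
  for (i in seq_along(config$fc_sizes)) {
    feat <- relu(drop(feat %*% params[[sprintf("fc%d_W", i)]]) +
                   params[[sprintf("fc%d_b", i)]])
    dims[[length(dims) + 1L]] <- list(layer = sprintf("fc%d", i),
                                      dim = length(feat))
  }
  pr <- drop(softmax(drop(feat %*% params$out_W) + params$out_b))
  dims[[length(dims) + 1L]] <- list(layer = "softmax", dim = length(pr))
  if (return_trace) list(prob = pr, dims = dims) else pr
}

# Reference forward over an array T x C x N -> N x n_classes matrix.
forward_reference <- function(params, config, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  t(apply(x, 3, function(m) forward_one_ref(params, config, m)))
}

#' Realized per-layer shapes of a forward pass
#'
#' Runs the reference forward pass on one (zero) input epoch and reports
#' the realized output dimensions of every layer, for comparison with the
#' statically computed [shape_trace()].
#'
#' @param params A [build_model()] parameter set.
#' @param config The matching [model_config()].
#' @return Data frame with columns `layer` and `shape`.
#' @export
realized_trace <- function(params, config) {
  x <- matrix(0, config$input_len, config$input_channels)
  dims <- forward_one_ref(params, config, x, return_trace = TRUE)$dims
  data.frame(layer = vapply(dims, `[[`, "", "layer"),
             shape = vapply(dims, function(d)
               paste(d$dim, collapse = " x "), ""))
}
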