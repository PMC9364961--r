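#' Network architecture configuration
#'
#' Hyperparameters of the parallel CNN-LSTM stager.  The canonical
#' configuration takes a 300 x 2 input (a 30-s two-channel epoch at the
#' 10 Hz model rate), runs a two-layer 64-unit LSTM branch (first layer
#' emitting the full 300 x 64 sequence, second emitting its final
#' 64-vector) in parallel with a convolutional branch
#' (conv 64 filters x kernel 5 -> max-pool 3 -> conv 32 x 5 -> max-pool 3
#' -> flatten 992), concatenates both branches (1,056), and finishes with
#' fully connected layers of 64 and 32 units and a five-way softmax.
#' Convolutions are unpadded with stride 1; pooling uses stride equal to
#' the pool size with floor division; each convolution is followed by
#' batch normalization before the ReLU.
#'
#' @param input_len Temporal input length (canonical 300).
#' @param input_channels Number of channels (canonical 2: EEG, EOG).
#' @param lstm_units Hidden units per LSTM layer (canonical 64).
#' @param lstm_layers Number of stacked LSTM layers (canonical 2).
#' @param conv_specs List of `c(filters, kernel_len)` pairs.
#' @param pool_size Max-pool width (= stride).
#' @param fc_sizes Fully connected layer widths.
#' @param n_classes Output classes (5 sleep stages).
#' @param dropout_conv Dropout probability after each convolution (0.20).
#' @param dropout_fc Dropout probability after each FC layer (0.50).
#' @param attention_pool Use softmax-weighted pooling of the LSTM hidden
#'   sequence instead of the final hidden state (off canonically).
#' @return Object of class `stager_config`.
#' @examples
#' shape_trace(model_config())
#' @export
model_config <- function(input_len = 300, input_channels = 2,
                         lstm_units = 64, lstm_layers = 2,
                         conv_specs = list(c(64, 5), c(32, 5)),
                         pool_size = 3, fc_sizes = c(64, 32), n_classes = 5,
                         dropout_conv = 0.20, dropout_fc = 0.50,
                         attention_pool = FALSE) {
  stopifnot(input_len >= 1, input_channels >= 1, lstm_units >= 1,
            lstm_layers >= 1, pool_size >= 1, n_classes >= 2,
            dropout_conv >= 0, dropout_conv < 1,
            dropout_fc >= 0, dropout_fc < 1,
            length(conv_specs) >= 1,
            all(vapply(conv_specs, length, 0L) == 2L))
  structure(list(input_len = as.integer(input_len),
                 input_channels = as.integer(input_channels),
                 lstm_units = as.integer(lstm_units),
                 lstm_layers = as.integer(lstm_layers),
                 conv_specs = lapply(conv_specs, as.integer),
                 pool_size = as.integer(pool_size),
                 fc_sizes = as.integer(fc_sizes),
                 n_classes = as.integer(n_classes),
                 dropout_conv = dropout_conv, dropout_fc = dropout_fc,
                 attention_pool = isTRUE(attention_pool)),
            class = "stager_config")
}

#' Per-layer output dimensions of a configuration
#'
#' Computes, without instantiating any parameters, the ordered list of
#' layer output shapes implied by the composition rules: unpadded stride-1
#' convolution (`L - kernel + 1`), max-pooling with stride equal to pool
#' size (`floor(L / pool)`), flatten (`L * filters`), concatenation of the
#' flattened convolutional features with the LSTM feature vector, then the
#' fully connected widths and the class count.  For the canonical
#' configuration this reproduces 296/98/94/31, flatten 992, concatenate
#' 1,056, 64, 32, 5.
#'
#' @param config A [model_config()].
#' @return Object of class `shape_trace`: data frame with columns `layer`
#'   and `shape` (shapes as `"L x F"` strings) plus a `dims` list attribute.
#' @export
shape_trace <- function(config) {
  stopifnot(inherits(config, "stager_config"))
  dims <- list()
  add <- function(name, d) dims[[length(dims) + 1L]] <<- list(layer = name,
                                                             dim = d)
  add("input", c(config$input_len, config$input_channels))
  for (l in seq_len(config$lstm_layers)) {
    if (l < config$lstm_layers)
      add(sprintf("lstm%d", l), c(config$input_len, config$lstm_units))
    else
      add(sprintf("lstm%d", l), config$lstm_units)
  }
  L <- config$input_len
  for (i in seq_along(config$conv_specs)) {
    cs <- config$conv_specs[[i]]
    if (cs[2] > L)
      stop(sprintf("conv%d: kernel length %d exceeds temporal length %d",
                   i, cs[2], L), call. = FALSE)
    L <- L - cs[2] + 1L
    add(sprintf("conv%d", i), c(L, cs[1]))
    L <- L %/% config$pool_size
    if (L <= 0)
      stop(sprintf("pool%d: temporal length collapsed to zero", i),
           call. = FALSE)
    add(sprintf("pool%d", i), c(L, cs[1]))
  }
  flat <- L * config$conv_specs[[length(config$conv_specs)]][1]
  add("flatten", flat)
  add("concatenate", flat + config$lstm_units)
  for (i in seq_along(config$fc_sizes)) add(sprintf("fc%d", i),
                                            config$fc_sizes[i])
  add("softmax", config$n_classes)
  df <- data.frame(
    layer = vapply(dims, `[[`, "", "layer"),
    shape = vapply(dims, function(d) paste(d$dim, collapse = " x "), ""))
  attr(df, "dims") <- lapply(dims, `[[`, "dim")
  class(df) <- c("shape_trace", "data.frame")
  df
}

#' @export
print.shape_trace <- function(x, ...) {
  cat("Layer output dimensions:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %s\n", x$layer[i], x$shape[i]))
  invisible(x)
}

# convenience lookup: named flat sizes used in several places
trace_dim <- function(trace, layer) {
  d <- attr(trace, "dims")[[match(layer, trace$layer)]]
  d
}
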