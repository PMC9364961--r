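#' Training schedule
#'
#' The stochastic-gradient-descent regimen: minibatch SGD on categorical
#' cross-entropy, initial learning rate 0.015 decaying 0.1-fold every 20
#' epochs, batch size 10, 100 epochs -- the canonical schedule.  No
#' momentum and no early stopping.
#'
#' @param epochs Number of training epochs.
#' @param batch_size Minibatch size.
#' @param lr_init Initial learning rate.
#' @param lr_decay_factor Multiplier applied every `lr_decay_every` epochs.
#' @param lr_decay_every Decay period (epochs).
#' @param bn_momentum Running-statistics momentum of batch normalization.
#' @param seed Integer seed driving shuffling, dropout and initialization.
#' @return Object of class `train_schedule`.
#' @export
train_schedule <- function(epochs = 100, batch_size = 10, lr_init = 0.015,
                           lr_decay_factor = 0.1, lr_decay_every = 20,
                           bn_momentum = 0.1, seed = 1) {
  stopifnot(epochs >= 0, batch_size >= 1, lr_init > 0,
            lr_decay_factor > 0, lr_decay_factor <= 1, lr_decay_every >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "train_schedule")
}

#' Learning rate at a given (0-based) epoch
#'
#' `lr(e) = lr_init * lr_decay_factor ^ floor(e / lr_decay_every)` -- with
#' the canonical schedule, 0.015 at epochs 0-19, 0.0015 at 20-39, and so
#' on.
#'
#' @param schedule A [train_schedule()].
#' @param epoch Integer vector of 0-based epoch numbers.
#' @return Numeric vector of learning rates.
#' @examples
#' lr_at_epoch(train_schedule(), c(0, 20, 40))
#' @export
lr_at_epoch <- function(schedule, epoch) {
  schedule$lr_init *
    schedule$lr_decay_factor^(epoch %/% schedule$lr_decay_every)
}

# Normalize training/prediction input to list(x = T x C x N array,
# y = integer codes or NULL, meta).
prepare_input <- function(data, config, require_labels = FALSE) {
  if (is.list(data) && !is.null(data$x) && is.array(data$x)) {
    inp <- data
  } else if (is.array(data) && length(dim(data)) == 3) {
    inp <- list(x = data, y = NULL, meta = NULL)
  } else if (is.list(data) && length(data) &&
             inherits(data[[1]], "epoch_record")) {
    model_fs <- config$input_len / EPOCH_SECONDS
    inp <- as_model_input(data, model_fs_hz = model_fs)
  } else stop("data must be a list of epoch_record or an as_model_input() result",
              call. = FALSE)
  d <- dim(inp$x)
  if (d[1] != config$input_len || d[2] != config$input_channels)
    stop(sprintf("input shape %d x %d does not conform to the %d x %d model input",
                 d[1], d[2], config$input_len, config$input_channels),
         call. = FALSE)
  if (require_labels) {
    if (is.null(inp$y) || anyNA(inp$y))
      stop("training requires a stage label for every epoch", call. = FALSE)
  }
  inp
}

#' Fit the parallel CNN-LSTM sleep stager
#'
#' The main fitting function.  Takes stage-labelled 30-s EEG/EOG epochs,
#' decimates them to the model input rate, and trains the parallel
#' CNN-LSTM fusion network by minibatch stochastic gradient descent on
#' categorical cross-entropy with a step-decayed learning rate.  Training
#' is deterministic given the schedule seed (single-threaded BLAS
#' assumed).
#'
#' @param data List of labelled [epoch_record()] (or the result of
#'   [as_model_input()]).
#' @param config Architecture, a [model_config()].
#' @param schedule Optimization regimen, a [train_schedule()].
#' @param validation Optional held-out data (same forms as `data`) scored
#'   after every epoch.
#' @param seed Seed for parameter initialization, shuffling and dropout;
#'   defaults to the schedule seed.
#' @param verbose Print per-epoch progress.
#' @return Object of class `sleep_stager` with elements `params`,
#'   `config`, `schedule`, `history` (per-epoch data frame with columns
#'   epoch, lr, train_loss, train_acc, val_loss, val_acc) and `seed`.
#' @examples
#' \donttest{
#' recs <- generate_dataset(2, 1, 30, fs_hz = 100, seed = 7)
#' fit <- sleep_stager(recs, schedule = train_schedule(epochs = 2, seed = 7))
#' predict(fit, recs[1:5])
#' }
#' @export
sleep_stager <- function(data, config = model_config(),
                         schedule = train_schedule(), validation = NULL,
                         seed = schedule$seed, verbose = FALSE) {
  stopifnot(inherits(config, "stager_config"),
            inherits(schedule, "train_schedule"))
  if (config$attention_pool)
    stop("the compiled trainer uses last-step pooling; attention pooling is available in the reference forward pass only",
         call. = FALSE)
  inp <- prepare_input(data, config, require_labels = TRUE)
  params <- build_model(config, seed)
  obj <- structure(
    list(params = params, config = config, schedule = schedule,
         history = data.frame(epoch = integer(0), lr = numeric(0),
                              train_loss = numeric(0),
                              train_acc = numeric(0),
                              val_loss = numeric(0), val_acc = numeric(0)),
         seed = seed, n_train = dim(inp$x)[3], call = match.call()),
    class = "sleep_stager")
  if (schedule$epochs == 0) return(obj)
  val <- if (!is.null(validation))
    prepare_input(validation, config, require_labels = TRUE)
  cs <- config$conv_specs
  res <- cpp_train(
    unclass(params), inp$x, as.integer(inp$y) - 1L, unclass(config),
    vapply(cs, `[`, 0L, 1), vapply(cs, `[`, 0L, 2), config$fc_sizes,
    schedule$epochs, schedule$batch_size, schedule$lr_init,
    schedule$lr_decay_factor, schedule$lr_decay_every,
    schedule$bn_momentum, seed,
    if (is.null(validation)) NULL else val$x,
    if (is.null(validation)) NULL else as.integer(val$y) - 1L,
    verbose)
  obj$params <- structure(res$params, class = "stager_params",
                          config = config, seed = seed)
  obj$history <- res$history
  obj
}

#' Predict sleep stages for new epochs
#'
#' @param object A fitted [sleep_stager()] model.
#' @param newdata Epoch records or model-input tensor.
#' @param type `"stage"` (factor of predicted stages), `"prob"`
#'   (matrix of class probabilities), or `"both"`.
#' @param method `"engine"` (compiled, single precision) or `"reference"`
#'   (pure R, double precision).
#' @param ... Unused.
#' @return See `type`; the predicted stage is always the row-wise argmax
#'   of the probability matrix.  Inference is deterministic (dropout
#'   inactive, batch normalization on running statistics).
#' @export
predict.sleep_stager <- function(object, newdata,
                                 type = c("stage", "prob", "both"),
                                 method = c("engine", "reference"), ...) {
  type <- match.arg(type)
  method <- match.arg(method)
  inp <- prepare_input(newdata, object$config)
  cs <- object$config$conv_specs
  prob <- if (method == "engine")
    cpp_predict(unclass(object$params), inp$x, unclass(object$config),
                vapply(cs, `[`, 0L, 1), vapply(cs, `[`, 0L, 2),
                object$config$fc_sizes)
  else forward_reference(object$params, object$config, inp$x)
  colnames(prob) <- stage_levels()[seq_len(object$config$n_classes)]
  stage <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                  levels = colnames(prob))
  switch(type, stage = stage, prob = prob,
         both = list(stage = stage, prob = prob))
}

#' @export
print.sleep_stager <- function(x, ...) {
  cat("Parallel CNN-LSTM sleep stager\n")
  cat(sprintf("  input %d x %d, LSTM %d x %d units, conv [%s], pool %d, fc [%s], %d classes\n",
              x$config$input_len, x$config$input_channels,
              x$config$lstm_layers, x$config$lstm_units,
              paste(vapply(x$config$conv_specs, function(cs)
                sprintf("%dx%d", cs[1], cs[2]), ""), collapse = ", "),
              x$config$pool_size,
              paste(x$config$fc_sizes, collapse = ", "),
              x$config$n_classes))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epoch(s) on %d epochs of data; final train loss %.4f, accuracy %.3f\n",
                nrow(x$history), x$n_train, last$train_loss, last$train_acc))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.sleep_stager <- function(object, ...) {
  print(object)
  npar <- sum(vapply(unclass(object$params), length, 0L))
  cat(sprintf("  %d trainable parameters\n", npar))
  cat(sprintf("  schedule: %d epochs, batch %d, lr %g (x%g every %d), seed %d\n",
              object$schedule$epochs, object$schedule$batch_size,
              object$schedule$lr_init, object$schedule$lr_decay_factor,
              object$schedule$lr_decay_every, object$seed))
  if (nrow(object$history)) {
    cat("  last epochs:\n")
    print(utils::tail(object$history, 3), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.sleep_stager <- function(object, ...) object$params

#' @export
plot.sleep_stager <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("untrained model: nothing to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", main = "loss", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "accuracy", ...)
  if (!all(is.na(h$val_acc)))
    graphics::lines(h$epoch, h$val_acc, lty = 2)
  invisible(x)
}

#' Save / load a fitted stager checkpoint
#'
#' Single-file archive embedding the architecture configuration, the
#' schedule and all parameters, with a format version tag.
#'
#' @param object A `sleep_stager` model.
#' @param path File path.
#' @return `load_stager` returns the restored `sleep_stager` object.
#' @export
save_stager <- function(object, path) {
  stopifnot(inherits(object, "sleep_stager"))
  saveRDS(list(format = "sleepstager-checkpoint", version = 1L,
               model = object), path)
  invisible(path)
}

#' @rdname save_stager
#' @export
load_stager <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "sleepstager-checkpoint"))
    stop("not a sleepstager checkpoint: ", path, call. = FALSE)
  x$model
}
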