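#' Default pipeline configuration
#'
#' A nested list covering every tunable of the end-to-end pipeline:
#' generation (subject/night/epoch counts, sampling rate), the hypnogram
#' proportions, the architecture, the resampling policy, the training
#' schedule, evaluation options and the global seed.  Round-trips
#' losslessly through YAML; unknown keys in a user file are rejected by
#' name.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "sleepstager-run",
    simulate = list(n_subjects = 4L, nights_per_subject = 1L,
                    epochs_per_night = 120L, fs_hz = 100),
    split = list(n_test_subjects = 1L),
    resample = list(enabled = TRUE, cap_per_stage_per_night = 200L),
    model = list(input_len = 300L, input_channels = 2L, lstm_units = 64L,
                 lstm_layers = 2L, conv_filters = c(64L, 32L),
                 conv_kernels = c(5L, 5L), pool_size = 3L,
                 fc_sizes = c(64L, 32L), n_classes = 5L,
                 dropout_conv = 0.2, dropout_fc = 0.5),
    schedule = list(epochs = 10L, batch_size = 10L, lr_init = 0.015,
                    lr_decay_factor = 0.1, lr_decay_every = 20L),
    evaluate = list(report_prefix = "metrics"),
    write_edf = FALSE,
    verbose = TRUE)
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && is.list(cfg[[nm]]))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Read and validate a pipeline configuration file (YAML)
#'
#' Values omitted from the file take their defaults; keys not present in
#' [default_run_config()] are rejected before any computation.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  check_config_keys(user, cfg)
  merge_cfg <- function(base, upd) {
    for (nm in names(upd))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_cfg(base[[nm]], upd[[nm]]) else upd[[nm]]
    base
  }
  merge_cfg(cfg, user)
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...)))
}

#' Run the full simulate / split / resample / train / evaluate pipeline
#'
#' Generates a synthetic dataset, holds out the last `n_test_subjects`
#' subjects, resamples the training epochs, trains the CNN-LSTM stager,
#' scores the held-out subjects, and writes a checkpoint, per-epoch
#' training curves (CSV), the evaluation report and per-night hypnogram
#' sidecars into `config$out_dir`.
#'
#' @param config Configuration list (see [default_run_config()] /
#'   [read_run_config()]).
#' @return Invisible list with the fitted model, the confusion matrix,
#'   the report metrics and the output directory.
#' @export
run_pipeline <- function(config = default_run_config()) {
  check_config_keys(config, default_run_config())
  v <- isTRUE(config$verbose)
  seed <- config$seed
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  sm <- config$simulate
  pipeline_log(v, "simulate", "%d subject(s) x %d night(s) x %d epoch(s), fs %g Hz, seed %d",
               sm$n_subjects, sm$nights_per_subject, sm$epochs_per_night,
               sm$fs_hz, seed)
  records <- generate_dataset(sm$n_subjects, sm$nights_per_subject,
                              sm$epochs_per_night, sm$fs_hz, seed = seed)
  hyps <- attr(records, "hypnograms")
  for (nm in names(hyps))
    write_hypnogram(hyps[[nm]], file.path(config$out_dir,
                                          paste0("hypnogram_", nm, ".txt")))
  if (isTRUE(config$write_edf)) {
    sids <- vapply(records, `[[`, "", "subject_id")
    nids <- vapply(records, `[[`, 1L, "night_id")
    for (nm in names(hyps)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      sel <- sids == parts[1] & nids == as.integer(parts[2])
      write_edf(records[sel], file.path(config$out_dir,
                                        paste0("night_", nm, ".edf")))
    }
  }

  subjects <- unique(vapply(records, `[[`, "", "subject_id"))
  ntest <- config$split$n_test_subjects
  if (ntest >= length(subjects))
    stop("n_test_subjects must leave at least one training subject",
         call. = FALSE)
  plan <- split_plan(utils::head(subjects, length(subjects) - ntest),
                     utils::tail(subjects, ntest))
  sp <- split_by_subject(records, plan)
  pipeline_log(v, "split", "%d train / %d test subjects (%d / %d epochs)",
               length(plan$train_subjects), length(plan$test_subjects),
               length(sp$train), length(sp$test))

  train_recs <- sp$train
  if (isTRUE(config$resample$enabled)) {
    train_recs <- resample_epochs(
      train_recs,
      resample_policy(config$resample$cap_per_stage_per_night),
      seed = derive_seed(seed, 101))
    pipeline_log(v, "resample", "%d -> %d training epochs (cap %d)",
                 length(sp$train), length(train_recs),
                 config$resample$cap_per_stage_per_night)
  }

  mc <- config$model
  model_cfg <- model_config(
    input_len = mc$input_len, input_channels = mc$input_channels,
    lstm_units = mc$lstm_units, lstm_layers = mc$lstm_layers,
    conv_specs = Map(c, mc$conv_filters, mc$conv_kernels),
    pool_size = mc$pool_size, fc_sizes = mc$fc_sizes,
    n_classes = mc$n_classes, dropout_conv = mc$dropout_conv,
    dropout_fc = mc$dropout_fc)
  sc <- config$schedule
  schedule <- train_schedule(epochs = sc$epochs, batch_size = sc$batch_size,
                             lr_init = sc$lr_init,
                             lr_decay_factor = sc$lr_decay_factor,
                             lr_decay_every = sc$lr_decay_every,
                             seed = derive_seed(seed, 202))
  pipeline_log(v, "train", "%d epochs, batch %d, lr %g, seed %d",
               schedule$epochs, schedule$batch_size, schedule$lr_init,
               schedule$seed)
  fit <- sleep_stager(train_recs, model_cfg, schedule,
                      seed = schedule$seed, verbose = v)
  save_stager(fit, file.path(config$out_dir, "checkpoint.rds"))
  utils::write.csv(fit$history,
                   file.path(config$out_dir, "training_curves.csv"),
                   row.names = FALSE)

  if (!length(sp$test)) {
    pipeline_log(v, "evaluate", "no held-out subjects; skipping")
    return(invisible(list(model = fit, confusion = NULL, report = NULL,
                          out_dir = config$out_dir)))
  }
  pred <- predict(fit, sp$test)
  truth <- vapply(sp$test, `[[`, "", "stage")
  cm <- confusion(truth, pred)
  rep <- stage_report(cm, file.path(config$out_dir,
                                    config$evaluate$report_prefix))
  pipeline_log(v, "evaluate", "held-out accuracy %.3f, MF1 %.3f",
               rep$accuracy, rep$macro_f1)
  invisible(list(model = fit, confusion = cm, report = rep,
                 out_dir = config$out_dir))
}
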