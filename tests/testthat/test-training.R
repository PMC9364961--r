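make_records <- function(subjects, nights = 1, epochs = 4, stages = NULL) {
  out <- list()
  i <- 0
  for (s in subjects) for (k in seq_len(nights)) for (e in seq_len(epochs)) {
    i <- i + 1
    st <- if (is.null(stages)) stage_levels()[(e - 1) %% 5 + 1] else
      stages[(i - 1) %% length(stages) + 1]
    out[[i]] <- epoch_record(matrix(0, 30, 2), fs_hz = 1, stage = st,
                             subject_id = s, night_id = k, epoch_index = e)
  }
  out
}

test_that("subject-level splitting partitions whole subjects in order", {
  subj <- sprintf("s%02d", 1:30)
  recs <- make_records(subj, epochs = 3)
  plan <- split_plan(subj[7:30], subj[1:6])
  sp <- split_by_subject(recs, plan)
  expect_length(unique(vapply(sp$train, `[[`, "", "subject_id")), 24)
  expect_length(unique(vapply(sp$test, `[[`, "", "subject_id")), 6)
  expect_length(intersect(vapply(sp$train, `[[`, "", "subject_id"),
                          vapply(sp$test, `[[`, "", "subject_id")), 0)

  # within-subject temporal order preserved
  for (part in sp) {
    df <- data.frame(s = vapply(part, `[[`, "", "subject_id"),
                     e = vapply(part, `[[`, 1L, "epoch_index"))
    for (s in unique(df$s))
      expect_false(is.unsorted(df$e[df$s == s], strictly = TRUE))
  }

  # degenerate plan: no test subjects
  sp2 <- split_by_subject(recs, split_plan(subj))
  expect_length(sp2$train, length(recs))
  expect_length(sp2$test, 0)

  expect_error(split_by_subject(recs, split_plan("s01", "s02")),
               "not covered")
  expect_error(split_plan(c("a", "b"), "b"), "disjoint")
})

test_that("resampling caps and balances per (night, stage)", {
  # adversarial night: 500 N2 epochs, cap 200
  recs <- make_records("s01", epochs = 500, stages = "N2")
  out <- resample_epochs(recs, resample_policy(200), seed = 1)
  expect_length(out, 200)
  expect_length(unique(vapply(out, `[[`, 1L, "epoch_index")), 200)

  # minority stage is oversampled up to the cap, duplicates allowed
  recs2 <- make_records("s01", epochs = 50, stages = "N1")
  out2 <- resample_epochs(recs2, resample_policy(200), seed = 1)
  expect_length(out2, 200)
  expect_lte(length(unique(vapply(out2, `[[`, 1L, "epoch_index"))), 50)

  # N2 is never oversampled
  recs3 <- make_records("s01", epochs = 50, stages = "N2")
  expect_length(resample_epochs(recs3, resample_policy(200), seed = 1), 50)

  # cap 1 leaves exactly one record per (night, stage) group
  recs4 <- make_records(c("s01", "s02"), nights = 2, epochs = 10)
  out4 <- resample_epochs(recs4, resample_policy(1), seed = 2)
  key <- vapply(out4, function(r)
    paste(r$subject_id, r$night_id, r$stage), "")
  expect_equal(as.integer(table(key)), rep(1L, length(unique(key))))

  # property: cap respected for random policies and seeds
  set.seed(41)
  for (r in 1:5) {
    cap <- sample(1:30, 1)
    recs5 <- make_records("s01", nights = 2, epochs = sample(20:60, 1))
    out5 <- resample_epochs(recs5, resample_policy(cap), seed = r)
    key <- vapply(out5, function(x)
      paste(x$subject_id, x$night_id, x$stage), "")
    expect_true(all(table(key) <= cap))
  }

  expect_identical(
    vapply(resample_epochs(recs2, resample_policy(200), seed = 5),
           `[[`, 1L, "epoch_index"),
    vapply(resample_epochs(recs2, resample_policy(200), seed = 5),
           `[[`, 1L, "epoch_index"))
})

test_that("learning-rate schedule follows the closed-form step decay", {
  sch <- train_schedule()
  expect_equal(lr_at_epoch(sch, c(0, 20, 40)),
               c(0.015, 0.0015, 0.00015))
  expect_equal(lr_at_epoch(sch, 0:99),
               0.015 * 0.1^(0:99 %/% 20))
  sch2 <- train_schedule(lr_init = 0.1, lr_decay_factor = 0.5,
                         lr_decay_every = 3)
  expect_equal(lr_at_epoch(sch2, c(2, 3, 7)), c(0.1, 0.05, 0.025))
})

test_that("validation folds partition nights evenly", {
  recs <- make_records(sprintf("s%02d", 1:24), nights = 2, epochs = 2)
  folds <- validation_folds(recs, 12)
  expect_length(folds, 12)
  nights_of <- function(part)
    unique(vapply(part, function(r)
      paste(r$subject_id, r$night_id), ""))
  holdouts <- lapply(folds, function(f) nights_of(f$holdout))
  expect_true(all(vapply(holdouts, length, 0L) == 4))
  expect_length(unique(unlist(holdouts)), 48)        # disjoint and covering
  for (f in folds)
    expect_length(intersect(nights_of(f$fit), nights_of(f$holdout)), 0)

  expect_error(validation_folds(recs, 1), "2 folds")
  expect_error(validation_folds(recs, 49), "cannot make")
})

test_that("training optimizes a separable toy problem deterministically", {
  # linearly separable two-class toy: opposite mean offsets under mild noise
  cfg <- tiny_config(n_classes = 2)
  set.seed(55)
  n <- 120
  x <- array(rnorm(60 * 2 * n, sd = 0.2), c(60, 2, n))
  y <- rep(c("W", "N1"), length.out = n)
  for (i in seq_len(n))
    x[, , i] <- x[, , i] + (if (y[i] == "W") 0.8 else -0.8)
  inp <- list(x = x, y = stage_factor(y))
  sch <- train_schedule(epochs = 30, batch_size = 10, seed = 99)
  fit <- sleep_stager(inp, cfg, sch)
  expect_true(all(diff(fit$history$train_loss[1:5]) < 0))
  # final accuracy on the training data (inference mode, dropout off)
  expect_gt(mean(as.character(predict(fit, inp)) ==
                   as.character(inp$y)), 0.95)

  # bit-reproducible given the seed
  fit2 <- sleep_stager(inp, cfg, sch)
  expect_identical(fit$history, fit2$history)
  expect_identical(unclass(fit$params), unclass(fit2$params))

  # 0-epoch schedule returns the untouched initialization
  fit0 <- sleep_stager(inp, cfg, train_schedule(epochs = 0, seed = 99))
  expect_identical(unclass(fit0$params),
                   unclass(build_model(cfg, seed = 99)))
  expect_equal(nrow(fit0$history), 0)
})

test_that("per-epoch validation curves are recorded when requested", {
  cfg <- tiny_config(n_classes = 2)
  set.seed(77)
  mk <- function(n) {
    x <- array(rnorm(60 * 2 * n, sd = 0.3), c(60, 2, n))
    y <- rep(c("W", "N1"), length.out = n)
    for (i in seq_len(n))
      x[, 1, i] <- x[, 1, i] + (if (y[i] == "W") 1 else -1)
    list(x = x, y = stage_factor(y))
  }
  fit <- sleep_stager(mk(40), cfg,
                      train_schedule(epochs = 3, batch_size = 10,
                                     seed = 1),
                      validation = mk(20))
  expect_false(anyNA(fit$history$val_loss))
  expect_false(anyNA(fit$history$val_acc))
  expect_equal(nrow(fit$history), 3)
})
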