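test_that("confusion counts true/predicted pairs in stage order", {
  y <- stage_factor(c("W", "N2", "REM", "N2"))
  cm <- confusion(y, y)
  expect_s3_class(cm, "stage_confusion")
  expect_equal(diag(cm), c(W = 1L, N1 = 0L, N2 = 2L, N3 = 0L, REM = 1L))
  expect_equal(sum(cm), 4)

  cm1 <- confusion("W", "N1")
  expect_equal(sum(cm1), 1)
  expect_equal(cm1["W", "N1"], 1L)

  set.seed(8)
  yt <- stage_factor(sample(0:4, 200, TRUE))
  yp <- stage_factor(sample(0:4, 200, TRUE))
  expect_equal(unclass(confusion(yt, yp)), naive_confusion(yt, yp),
               ignore_attr = TRUE)

  expect_error(confusion(c("W", "N1"), "W"), "equal lengths")
})

test_that("per-class metrics implement one-vs-rest PRE/REC/F1", {
  # hand example: TP = 8, FP = 2, FN = 2 for class W
  m <- matrix(0L, 5, 5, dimnames = list(stage_levels(), stage_levels()))
  m["W", "W"] <- 8L; m["N1", "W"] <- 2L; m["W", "N2"] <- 2L
  m["N1", "N1"] <- 5L; m["N2", "N2"] <- 5L; m["N3", "N3"] <- 5L
  m["REM", "REM"] <- 5L
  cm <- structure(m, class = c("stage_confusion", "matrix"))
  pc <- per_class_metrics(cm)
  expect_equal(pc$precision[pc$stage == "W"], 0.8)
  expect_equal(pc$recall[pc$stage == "W"], 0.8)
  expect_equal(pc$f1[pc$stage == "W"], 0.8)

  # perfect diagonal
  cmp <- confusion(stage_factor(rep(0:4, 3)), stage_factor(rep(0:4, 3)))
  pcp <- per_class_metrics(cmp)
  expect_true(all(pcp$precision == 1 & pcp$recall == 1 & pcp$f1 == 1))
  expect_equal(accuracy(cmp), 1)
  expect_equal(macro_f1(cmp), 1)

  # brute-force binarization oracle on random matrices
  set.seed(23)
  for (r in 1:20) {
    yt <- stage_factor(sample(0:4, 150, TRUE))
    yp <- stage_factor(sample(0:4, 150, TRUE))
    cm <- confusion(yt, yp)
    pc <- per_class_metrics(cm)
    for (k in seq_along(stage_levels())) {
      st <- stage_levels()[k]
      tp <- sum(yt == st & yp == st)
      fp <- sum(yt != st & yp == st)
      fn <- sum(yt == st & yp != st)
      pre <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
      expect_equal(pc$precision[k], pre)
      expect_equal(pc$recall[k], rec)
      expect_equal(pc$f1[k], f1)
    }
    expect_equal(accuracy(cm), mean(yt == yp))
    expect_equal(macro_f1(cm), mean(pc$f1))
  }
})

test_that("accuracy and macro F1 handle degenerate and uniform cases", {
  u <- confusion(stage_factor(rep(0:4, each = 5)),
                 stage_factor(rep(0:4, times = 5)))
  expect_equal(accuracy(u), 0.2)   # uniform 5x5 matrix of ones

  # absent class contributes F1 = 0 to the macro mean (documented default)
  yt <- stage_factor(c("W", "W", "N1", "N2", "N3"))
  yp <- stage_factor(c("W", "W", "N1", "N2", "N3"))
  cm <- confusion(yt, yp)
  expect_equal(macro_f1(cm), 4 / 5)
  expect_equal(macro_f1(cm, include_empty = FALSE), 1)

  # mean of constant F1s is that constant
  expect_equal(macro_f1(u), per_class_metrics(u)$f1[1])
})

test_that("metrics are bounded and invariant to joint permutation", {
  set.seed(31)
  yt <- stage_factor(sample(0:4, 300, TRUE))
  yp <- stage_factor(sample(0:4, 300, TRUE))
  cm <- confusion(yt, yp)
  pc <- per_class_metrics(cm)
  expect_true(all(pc$precision >= 0 & pc$precision <= 1))
  expect_true(all(pc$recall >= 0 & pc$recall <= 1))
  expect_true(all(pc$f1 >= 0 & pc$f1 <= 1))
  expect_true(accuracy(cm) >= 0 && accuracy(cm) <= 1)
  expect_true(macro_f1(cm) >= 0 && macro_f1(cm) <= 1)

  o <- sample(300)
  expect_identical(unclass(confusion(yt[o], yp[o])), unclass(cm))
})

test_that("stage report round-trips through its CSV files", {
  set.seed(5)
  yt <- stage_factor(sample(0:4, 120, TRUE))
  yp <- yt
  yp[1:10] <- stage_factor(sample(0:4, 10, TRUE))
  cm <- confusion(yt, yp)
  prefix <- file.path(tempdir(), "report_test")
  rep <- stage_report(cm, prefix)

  summ <- utils::read.csv(paste0(prefix, "_summary.csv"))
  expect_equal(names(summ), c("W", "N1", "N2", "N3", "REM", "Accuracy",
                              "MF1"))
  expect_equal(as.numeric(summ[1, 1:5]),
               100 * per_class_metrics(cm)$f1)
  expect_equal(summ$Accuracy, 100 * accuracy(cm))

  per <- utils::read.csv(paste0(prefix, "_per_stage.csv"))
  expect_equal(per$f1_pct, 100 * per_class_metrics(cm)$f1)

  cmat <- utils::read.csv(paste0(prefix, "_confusion.csv"), row.names = 1)
  expect_equal(unname(as.matrix(cmat)), unclass(cm), ignore_attr = TRUE)

  # perfect predictions report 100 everywhere
  rp <- stage_report(confusion(yt, yt), file.path(tempdir(), "perfect"))
  expect_equal(as.numeric(rp$summary[1, 1:6]), rep(100, 6))
})
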