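#' Confusion matrix over the five sleep stages
#'
#' `counts[i, j]` is the number of epochs whose true stage is `i` and
#' predicted stage is `j`, in the fixed order W, N1, N2, N3, REM.
#'
#' @param y_true,y_pred Stage labels (anything [stage_factor()] accepts),
#'   equal nonzero lengths.
#' @return Object of class `stage_confusion` (5 x 5 integer matrix,
#'   rows = true, columns = predicted).
#' @examples
#' confusion(c("W", "N2"), c("W", "N3"))
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- stage_factor(y_true)
  y_pred <- stage_factor(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal lengths", call. = FALSE)
  if (!length(y_true)) stop("no epochs to score", call. = FALSE)
  m <- table(true = y_true, predicted = y_pred)
  structure(matrix(as.integer(m), 5, 5,
                   dimnames = list(true = stage_levels(),
                                   predicted = stage_levels())),
            class = c("stage_confusion", "matrix"))
}

#' @export
print.stage_confusion <- function(x, ...) {
  cat("Stage confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest for each stage: precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, F1 the harmonic mean `2 * PRE * REC / (PRE + REC)`.
#' Degenerate cases are defined as zero: a stage never predicted has
#' precision 0, a stage absent from the truth has recall 0, and F1 is 0
#' whenever precision + recall is 0.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame with columns `stage`, `precision`, `recall`, `f1`
#'   (fractions in `[0, 1]`).
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "stage_confusion"))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  pre <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(pre + rec > 0, 2 * pre * rec / (pre + rec), 0)
  data.frame(stage = stage_levels(), precision = unname(pre),
             recall = unname(rec), f1 = unname(f1))
}

#' Overall accuracy: sum of per-class true positives over total epochs
#'
#' @param cm A [confusion()] matrix.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "stage_confusion"))
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / tot
}

#' Macro F1: unweighted mean of the per-stage F1 scores
#'
#' @param cm A [confusion()] matrix.
#' @param include_empty Average F1 over all five stages even when a stage
#'   is absent from the truth (its F1 counts as 0); if `FALSE`, absent
#'   stages are dropped from the mean.
#' @return Fraction in `[0, 1]`.
#' @export
macro_f1 <- function(cm, include_empty = TRUE) {
  m <- per_class_metrics(cm)
  if (!include_empty) {
    present <- rowSums(cm) > 0
    m <- m[present, , drop = FALSE]
  }
  mean(m$f1)
}

#' Write a staging performance report
#'
#' Emits a per-stage metric table and the overall accuracy / macro-F1,
#' both machine-readable (CSV) and human-readable (text).  Percentages
#' are used in the report files; the programmatic metrics stay fractions.
#' The summary row is ordered W, N1, N2, N3, REM, Accuracy (per-stage F1
#' percentages followed by overall accuracy), plus MF1.
#'
#' @param cm A [confusion()] matrix.
#' @param prefix Output path prefix; writes `<prefix>_per_stage.csv`,
#'   `<prefix>_summary.csv`, `<prefix>_confusion.csv` and
#'   `<prefix>_report.txt`.
#' @return Invisible list with `per_stage`, `summary`, `accuracy`,
#'   `macro_f1` and the written file paths.
#' @export
stage_report <- function(cm, prefix) {
  m <- per_class_metrics(cm)
  acc <- accuracy(cm)
  mf1 <- macro_f1(cm)
  per_stage <- data.frame(stage = m$stage,
                          precision_pct = 100 * m$precision,
                          recall_pct = 100 * m$recall,
                          f1_pct = 100 * m$f1)
  summ <- as.data.frame(as.list(stats::setNames(100 * m$f1, m$stage)))
  summ$Accuracy <- 100 * acc
  summ$MF1 <- 100 * mf1
  files <- paste0(prefix, c("_per_stage.csv", "_summary.csv",
                            "_confusion.csv", "_report.txt"))
  utils::write.csv(per_stage, files[1], row.names = FALSE)
  utils::write.csv(summ, files[2], row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(cm)), files[3])
  con <- file(files[4], "w")
  on.exit(close(con))
  writeLines(c("Sleep staging performance",
               sprintf("  overall accuracy: %.2f%%", 100 * acc),
               sprintf("  macro F1 (MF1):   %.2f%%", 100 * mf1), "",
               "  per-stage (percent):",
               sprintf("    %-4s precision %6.2f  recall %6.2f  F1 %6.2f",
                       m$stage, 100 * m$precision, 100 * m$recall,
                       100 * m$f1)), con)
  invisible(list(per_stage = per_stage, summary = summ, accuracy = acc,
                 macro_f1 = mf1, files = files))
}
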