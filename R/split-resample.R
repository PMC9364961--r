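#' Subject-level split plan
#'
#' Train/test partitioning is by whole subject -- never by epoch -- so the
#' temporal sequence of each subject's night is never interrupted and no
#' subject leaks across the boundary.
#'
#' @param train_subjects,test_subjects Character vectors of subject ids
#'   (disjoint).
#' @return Object of class `split_plan`.
#' @export
split_plan <- function(train_subjects, test_subjects = character(0)) {
  train_subjects <- as.character(train_subjects)
  test_subjects <- as.character(test_subjects)
  if (length(intersect(train_subjects, test_subjects)))
    stop("train and test subject sets must be disjoint", call. = FALSE)
  structure(list(train_subjects = train_subjects,
                 test_subjects = test_subjects), class = "split_plan")
}

#' Split epoch records by subject
#'
#' @param records List of [epoch_record()].
#' @param plan A [split_plan()] covering every subject present.
#' @return List with `train` and `test` record lists; within-subject
#'   epoch order is preserved.
#' @export
split_by_subject <- function(records, plan) {
  stopifnot(inherits(plan, "split_plan"))
  sids <- vapply(records, `[[`, "", "subject_id")
  unknown <- setdiff(unique(sids),
                     c(plan$train_subjects, plan$test_subjects))
  if (length(unknown))
    stop("subjects not covered by the split plan: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  list(train = records[sids %in% plan$train_subjects],
       test = records[sids %in% plan$test_subjects])
}

#' Class-imbalance resampling policy
#'
#' Per (night, stage) epoch-count cap: groups exceeding the cap are
#' sampled down without replacement; groups below the cap whose stage is
#' in `oversample_stages` are sampled up (with replacement) to the cap.
#' The canonical policy caps every night's stages at 200 epochs,
#' oversampling the minority stages W, N1, N3 and REM and undersampling
#' the dominant N2.
#'
#' @param cap_per_stage_per_night Cap (>= 1).
#' @param oversample_stages Stages replicated up to the cap.
#' @param undersample_stages Stages expected to exceed the cap
#'   (informational; any group over the cap is downsampled).
#' @return Object of class `resample_policy`.
#' @export
resample_policy <- function(cap_per_stage_per_night = 200,
                            oversample_stages = c("W", "N1", "N3", "REM"),
                            undersample_stages = "N2") {
  stopifnot(cap_per_stage_per_night >= 1)
  structure(list(cap_per_stage_per_night =
                   as.integer(cap_per_stage_per_night),
                 oversample_stages =
                   as.character(stage_factor(oversample_stages)),
                 undersample_stages =
                   as.character(stage_factor(undersample_stages))),
            class = "resample_policy")
}

#' Resample training epochs per (night, stage)
#'
#' @param records Labelled [epoch_record()] list.
#' @param policy A [resample_policy()].
#' @param seed Integer seed; the resample is deterministic given it.
#' @return Resampled record list, grouped by subject/night/stage with
#'   within-group epoch order preserved (oversampled duplicates repeat
#'   original records).
#' @export
resample_epochs <- function(records, policy = resample_policy(), seed = 1) {
  stopifnot(inherits(policy, "resample_policy"))
  local_seed(seed)
  key <- vapply(records, function(r)
    paste(r$subject_id, r$night_id, r$stage, sep = "\r"), "")
  cap <- policy$cap_per_stage_per_night
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    st <- records[[idx[1]]]$stage
    if (length(idx) > cap) {
      idx <- sort(sample(idx, cap))
    } else if (length(idx) < cap && st %in% policy$oversample_stages) {
      idx <- sort(c(idx, sample(idx, cap - length(idx), replace = TRUE)))
    }
    out <- c(out, records[idx])
  }
  out
}

#' Night-level validation folds
#'
#' Partitions the training nights into `n_folds` disjoint folds (sizes as
#' equal as possible, remainder spread over the leading folds); each fold
#' can serve as the held-out validation subset during training.
#'
#' @param records Labelled [epoch_record()] list.
#' @param n_folds Number of folds (>= 2, <= number of nights).
#' @return List of `n_folds` elements, each `list(fit = ..., holdout = ...)`
#'   of record lists; folds are disjoint and cover all nights.
#' @export
validation_folds <- function(records, n_folds) {
  nights <- unique(vapply(records, function(r)
    paste(r$subject_id, r$night_id, sep = "\r"), ""))
  if (n_folds < 2)
    stop("at least 2 folds are required (one fold would leave no fit set)",
         call. = FALSE)
  if (n_folds > length(nights))
    stop(sprintf("cannot make %d folds from %d nights", n_folds,
                 length(nights)), call. = FALSE)
  sizes <- rep(length(nights) %/% n_folds, n_folds)
  extra <- length(nights) %% n_folds
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  splits <- split(nights, rep(seq_len(n_folds), times = sizes))
  nk <- vapply(records, function(r)
    paste(r$subject_id, r$night_id, sep = "\r"), "")
  lapply(splits, function(hold) {
    list(fit = records[!(nk %in% hold)], holdout = records[nk %in% hold])
  })
}
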