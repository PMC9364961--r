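#' Hypnogram model
#'
#' Night-level stage-sequence model: target per-stage time fractions and
#' mean bout (run) lengths in epochs.  Defaults take the midpoint of the
#' classical clinical ranges -- N1 5-10%, N2 44-55%, N3 10-20% -- with REM
#' at the low end (22%) of its printed range and W absorbing the remainder.
#' Runs are geometric with the stated means, scheduled against per-stage
#' epoch quotas so the realized time-in-stage fractions match
#' `proportions` up to quota rounding for every seed.
#'
#' @param proportions Named numeric vector over the five stages; normalized
#'   internally.
#' @param mean_bout_epochs Named numeric vector of mean run lengths
#'   (epochs, all >= 1).
#' @param transition_bias Optional named non-negative multiplier on
#'   successor weights.
#' @return Object of class `hypnogram_model`.
#' @export
hypnogram_model <- function(
    proportions = c(W = 0.055, N1 = 0.075, N2 = 0.495, N3 = 0.155, REM = 0.22),
    mean_bout_epochs = c(W = 3, N1 = 3, N2 = 10, N3 = 8, REM = 8),
    transition_bias = c(W = 1, N1 = 1, N2 = 1, N3 = 1, REM = 1)) {
  lv <- stage_levels()
  stopifnot(setequal(names(proportions), lv),
            setequal(names(mean_bout_epochs), lv),
            all(proportions >= 0), all(mean_bout_epochs >= 1),
            all(transition_bias >= 0))
  if (sum(proportions) <= 0)
    stop("stage proportions must not all be zero", call. = FALSE)
  structure(list(proportions = proportions[lv] / sum(proportions),
                 mean_bout_epochs = mean_bout_epochs[lv],
                 transition_bias = transition_bias[lv]),
            class = "hypnogram_model")
}

#' Generate a run-length-structured hypnogram
#'
#' @param n_epochs Number of 30-s epochs (>= 1).
#' @param model A [hypnogram_model()].
#' @param seed Integer seed; the output is deterministic given
#'   `(n_epochs, model, seed)`.
#' @return Stage factor of length `n_epochs`.
#' @examples
#' h <- generate_hypnogram(100, seed = 1)
#' table(h)
#' @export
generate_hypnogram <- function(n_epochs, model = hypnogram_model(), seed = 1) {
  stopifnot(n_epochs >= 1)
  lv <- stage_levels()
  p <- model$proportions
  mb <- model$mean_bout_epochs
  # entry rate proportional to time share / mean bout length
  entry <- p / mb * model$transition_bias
  if (sum(entry) <= 0) stop("degenerate hypnogram model", call. = FALSE)
  local_seed(seed)
  # quota-based run scheduling: every stage owns a per-night epoch quota
  # (proportion x n); runs draw geometric lengths with the stated means,
  # truncated at the owner's remaining quota, and the next run's stage is
  # drawn with probability proportional to remaining quota / mean bout.
  # Per-stage fractions then match the targets up to quota rounding for
  # every seed, not just in expectation.
  remaining <- round(p * n_epochs)
  remaining[which.max(remaining)] <- remaining[which.max(remaining)] +
    (n_epochs - sum(remaining))
  out <- character(0)
  while (length(out) < n_epochs) {
    w <- entry * (remaining > 0) * pmax(remaining, 0) / (p * n_epochs + 1)
    if (sum(w) <= 0) w <- pmax(remaining, 0)
    cur <- sample(seq_along(lv), 1, prob = w)
    len <- min(1L + stats::rgeom(1, prob = min(1, 1 / mb[cur])),
               remaining[cur])
    out <- c(out, rep(lv[cur], len))
    remaining[cur] <- remaining[cur] - len
  }
  stage_factor(out[seq_len(n_epochs)])
}
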