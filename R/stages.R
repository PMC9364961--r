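#' Sleep stage labels
#'
#' The five-stage AASM scoring scheme used throughout the package:
#' W (wake), N1 and N2 (light sleep), N3 (deep sleep) and REM (rapid eye
#' movement sleep).  Stages are represented as a factor with levels in this
#' fixed order; the integer code of a stage is its position minus one
#' (W = 0, ..., REM = 4) and the code/name mapping is stable across the
#' whole package.
#'
#' @return Character vector of the five stage names, in canonical order.
#' @examples
#' stage_levels()
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

#' Coerce to a stage factor
#'
#' Accepts stage names, integer codes 0-4, or an existing factor and returns
#' a factor with the canonical five levels.  Unknown stage tokens (for
#' example the pre-AASM "N4") are an error.
#'
#' @param x Character, integer (0-4) or factor.
#' @return Factor with levels `stage_levels()`.
#' @examples
#' stage_factor(c("W", "REM", "N2"))
#' stage_factor(c(0L, 4L))
#' @export
stage_factor <- function(x) {
  lv <- stage_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (any(is.na(x)) || any(x < 0 | x > 4) || any(x != floor(x)))
      stop("integer stage codes must be whole numbers in 0..4", call. = FALSE)
    return(factor(lv[x + 1L], levels = lv))
  }
  bad <- setdiff(unique(x[!is.na(x)]), lv)
  if (length(bad))
    stop("unknown sleep stage token(s): ", paste(bad, collapse = ", "),
         " (five-stage AASM scheme: ", paste(lv, collapse = ", "), ")",
         call. = FALSE)
  factor(x, levels = lv)
}

#' Integer code of a stage (W = 0 ... REM = 4)
#' @param x Anything `stage_factor()` accepts.
#' @return Integer vector of codes.
#' @export
stage_code <- function(x) as.integer(stage_factor(x)) - 1L

#' Canonical EEG rhythm bands
#'
#' The four clinical scalp-EEG oscillation bands, in Hz: delta 0.5-4,
#' theta 4-8, alpha 8-13, beta 13-30.
#'
#' @return Named list of `c(low, high)` frequency pairs (Hz).
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

# epoch duration in seconds -- the atomic unit of sleep scoring
EPOCH_SECONDS <- 30
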