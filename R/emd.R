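# Empirical mode decomposition and Hilbert instantaneous-frequency
# analysis of sleep EEG.

# indices of local maxima / minima (strict neighbours; plateaus take the
# first sample of the plateau)
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  # collapse exact ties so plateaus register as single extrema
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  idx <- nz[c(diff(s[nz]) != 0, FALSE)]
  turn <- idx[s[idx] != 0]
  mx <- turn[s[turn] > 0] + 1L
  mn <- turn[s[turn] < 0] + 1L
  list(max = mx, min = mn)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

# cubic-spline envelope through extrema, mirror-extending `next` extrema at
# each end to tame spline end effects
spline_envelope <- function(x, idx, n, nmirror = 2) {
  if (length(idx) < 2) return(rep(mean(x[idx]), n))
  k <- min(nmirror, length(idx) - 1)
  left_i <- 2 - idx[seq_len(k) + 1]          # mirror about sample 1
  right_i <- 2 * n - idx[length(idx) - seq_len(k)]
  xi <- c(left_i, idx, right_i)
  yi <- c(x[idx[seq_len(k) + 1]], x[idx], x[idx[length(idx) - seq_len(k)]])
  f <- stats::splinefun(xi, yi, method = "fmm")
  f(seq_len(n))
}

is_imf_like <- function(h) {
  ex <- local_extrema(h)
  ne <- length(ex$max) + length(ex$min)
  abs(ne - count_zero_crossings(h)) <= 1
}

#' Empirical mode decomposition
#'
#' Standard sifting: cubic-spline envelopes through the local maxima and
#' minima (mirror-extended at the boundaries), iterated mean-envelope
#' subtraction until the Cauchy standard-deviation criterion drops below
#' `stop_sd` and the candidate satisfies the IMF extrema/zero-crossing
#' property, then the intrinsic mode function (IMF) is removed and sifting
#' repeats on the remainder until `max_imfs` is reached or the remainder is
#' monotone.  The returned components reconstruct the input exactly:
#' `rowSums(imfs) + residual == signal` up to floating-point error.
#'
#' @param signal Numeric vector (length >= 16, finite).
#' @param fs_hz Sampling rate (Hz), carried on the result.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param stop_sd Cauchy criterion threshold
#'   (`sum((h_prev - h)^2) / sum(h_prev^2) < stop_sd`).
#' @param max_sift Maximum sifting iterations per IMF.
#' @return Object of class `imf_set`: list with `imfs` (matrix, one column
#'   per IMF; zero columns for monotone input), `residual`, `fs_hz`.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 2, by = 0.01))
#' d <- emd(x, fs_hz = 100)
#' ncol(d$imfs)
#' @export
emd <- function(signal, fs_hz, max_imfs = 8, stop_sd = 0.2, max_sift = 50) {
  stopifnot(length(signal) >= 16, all(is.finite(signal)))
  n <- length(signal)
  res <- signal
  imfs <- list()
  for (k in seq_len(max_imfs)) {
    ex <- local_extrema(res)
    if (length(ex$max) + length(ex$min) < 3) break  # monotone-ish remainder
    h <- res
    for (it in seq_len(max_sift)) {
      ex <- local_extrema(h)
      if (length(ex$max) < 2 || length(ex$min) < 2) break
      upper <- spline_envelope(h, ex$max, n)
      lower <- spline_envelope(h, ex$min, n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_crit < stop_sd && is_imf_like(h)) break
    }
    # a candidate that cannot be sifted into a valid IMF (typically a
    # low-extrema residual trend) stays in the residual
    if (!is_imf_like(h)) break
    imfs[[k]] <- h
    res <- res - h
  }
  structure(list(
    imfs = if (length(imfs)) do.call(cbind, imfs) else
      matrix(numeric(0), nrow = n, ncol = 0),
    residual = res, fs_hz = fs_hz), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) of length %d @ %g Hz\n",
              ncol(x$imfs), nrow(x$imfs), x$fs_hz))
  invisible(x)
}

# analytic signal via the frequency-domain Hilbert construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

phase_unwrap <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  p[1] + c(0, cumsum(d))
}

#' Hilbert instantaneous frequency of a (near-mono-component) signal
#'
#' Builds the analytic signal by the Hilbert transform and differentiates
#' the unwrapped phase; the first and last 5% of samples are trimmed to
#' discard transform edge effects.  Negative values (phase-unwrapping
#' noise) are clamped to zero; the number clamped is reported as attribute
#' `"n_clamped"`.
#'
#' @param imf Numeric vector, typically one IMF from [emd()].
#' @param fs_hz Sampling rate (Hz).
#' @param trim Fraction trimmed at each edge.
#' @return Numeric vector of instantaneous frequencies (Hz), one per
#'   retained inter-sample interval; empty (with attribute
#'   `"degenerate" = TRUE`) for an all-zero input.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 10, by = 0.01))
#' stats::median(instantaneous_frequency(x, 100))
#' @export
instantaneous_frequency <- function(imf, fs_hz, trim = 0.05) {
  if (all(imf == 0)) {
    out <- numeric(0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- analytic_signal(imf)
  ph <- phase_unwrap(Arg(z))
  f <- diff(ph) * fs_hz / (2 * pi)
  n <- length(f)
  lo <- max(1L, ceiling(trim * n))
  hi <- min(n, floor((1 - trim) * n))
  f <- f[lo:hi]
  ncl <- sum(f < 0)
  f[f < 0] <- 0
  attr(f, "n_clamped") <- ncl
  f
}

#' Relative band energy of a signal
#'
#' Periodogram band powers over the requested bands, normalized by the
#' total power in the union of the bands (fractions sum to one).
#'
#' @param signal Numeric vector.
#' @param fs_hz Sampling rate (Hz).
#' @param bands Named list of `c(low, high)` pairs (Hz), within `(0, fs/2]`.
#' @return Named numeric vector of unitless fractions summing to 1.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 3, by = 0.01))
#' relative_band_energy(x, 100)
#' @export
relative_band_energy <- function(signal, fs_hz, bands = eeg_bands()) {
  stopifnot(length(bands) >= 1)
  lims <- vapply(bands, range, numeric(2))
  if (any(lims[1, ] <= 0) || any(lims[2, ] > fs_hz / 2))
    stop("bands must lie within (0, fs/2]", call. = FALSE)
  n <- length(signal)
  X <- stats::fft(signal)
  nf <- floor(n / 2)
  freqs <- (seq_len(nf)) * fs_hz / n     # positive frequencies, DC excluded
  pow <- Mod(X[seq_len(nf) + 1L])^2
  e <- vapply(bands, function(b)
    sum(pow[freqs > b[1] & freqs <= b[2]]), 0)
  tot <- sum(e)
  if (tot <= 0) stop("signal has zero power in the requested bands",
                     call. = FALSE)
  e / tot
}

#' Per-stage instantaneous-frequency histograms of the first IMFs
#'
#' For each stage present in `epochs`, decomposes the EEG channel of every
#' epoch, computes the Hilbert instantaneous frequency of the first
#' `n_imfs` IMFs, pools the frequency samples per IMF across the stage's
#' epochs, and bins them into normalized probability-density histograms
#' (the per-stage spectral fingerprint of sleep EEG).
#'
#' @param epochs List of [epoch_record()] (labelled).
#' @param n_imfs Number of leading IMFs to analyze (canonical 4).
#' @param bins Number of uniform bins.
#' @param range_hz Histogram range (Hz); default the 0.5-30 Hz clinical
#'   band extended to zero.
#' @param channel Channel analyzed (default EEG).
#' @return Named list (one entry per stage present) of lists of
#'   `freq_histogram` objects (fields `bin_edges`, `densities`); stages with
#'   zero epochs are omitted with a message.
#' @export
stage_frequency_histograms <- function(epochs, n_imfs = 4, bins = 50,
                                       range_hz = c(0, 30), channel = 1) {
  stopifnot(length(epochs) >= 1, n_imfs >= 1)
  labs <- vapply(epochs, function(r) r$stage[1], "")
  out <- list()
  for (st in stage_levels()) {
    sel <- which(labs == st)
    if (!length(sel)) {
      message("stage ", st, " has no epochs; omitted from histogram mapping")
      next
    }
    pools <- vector("list", n_imfs)
    for (i in sel) {
      rec <- epochs[[i]]
      d <- emd(rec$samples[, channel], rec$fs_hz, max_imfs = n_imfs)
      for (k in seq_len(min(n_imfs, ncol(d$imfs)))) {
        f <- instantaneous_frequency(d$imfs[, k], rec$fs_hz)
        pools[[k]] <- c(pools[[k]], f[f >= range_hz[1] & f <= range_hz[2]])
      }
    }
    out[[st]] <- lapply(pools, function(v) freq_histogram(v, bins, range_hz))
  }
  out
}

# normalized probability-density histogram over fixed uniform bins
freq_histogram <- function(values, bins, range_hz) {
  edges <- seq(range_hz[1], range_hz[2], length.out = bins + 1)
  if (!length(values)) {
    dens <- rep(0, bins)
  } else {
    h <- graphics::hist(values, breaks = edges, plot = FALSE)
    dens <- h$density
    dens[is.na(dens)] <- 0
  }
  structure(list(bin_edges = edges, densities = dens),
            class = "freq_histogram")
}

#' @export
plot.freq_histogram <- function(x, main = "instantaneous frequency", ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::barplot(x$densities, names.arg = round(mids, 1), space = 0,
                    xlab = "frequency (Hz)", ylab = "density", main = main,
                    ...)
  invisible(x)
}
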