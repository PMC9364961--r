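# -- seeding ------------------------------------------------------------

# Set the R RNG to `seed` for the rest of the calling function, restoring
# the caller-visible RNG state on exit.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  restore <- function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
  do.call(base::on.exit, list(as.call(list(restore)), add = TRUE),
          envir = envir)
  set.seed(as.integer(seed %% 2147483647))
  invisible(NULL)
}

# Deterministic sub-seed derived from a base seed and indices, < 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647)
  primes <- c(7919, 104729, 1299709, 15485863)
  for (i in seq_along(idx))
    s <- (s * 31 + idx[i] * primes[((i - 1) %% 4) + 1]) %% 2147483629
  as.integer(s)
}

# -- epoch record -------------------------------------------------------

#' Construct a 30-second epoch record
#'
#' @param samples Numeric matrix, `n_samples x n_channels` (microvolts),
#'   `n_samples` must equal `fs_hz * 30`; canonical channels are
#'   `c("EEG", "EOG")`.
#' @param fs_hz Sampling rate, Hz.
#' @param stage Stage label (or `NA` for unscored epochs).
#' @param subject_id,night_id,epoch_index Provenance identifiers.
#' @return Object of class `epoch_record`.
#' @export
epoch_record <- function(samples, fs_hz, stage = NA, subject_id = "s1",
                         night_id = 1L, epoch_index = 1L) {
  samples <- as.matrix(samples)
  if (nrow(samples) != fs_hz * EPOCH_SECONDS)
    stop("epoch must contain exactly fs_hz * 30 samples", call. = FALSE)
  if (anyNA(samples)) stop("epoch contains missing values", call. = FALSE)
  if (is.null(colnames(samples)))
    colnames(samples) <- c("EEG", "EOG")[seq_len(ncol(samples))]
  structure(list(samples = samples, fs_hz = fs_hz,
                 stage = if (is.na(stage[1])) NA else
                   as.character(stage_factor(stage)),
                 subject_id = as.character(subject_id),
                 night_id = as.integer(night_id),
                 epoch_index = as.integer(epoch_index)),
            class = "epoch_record")
}

#' @export
print.epoch_record <- function(x, ...) {
  cat(sprintf("<epoch_record> %d x %d @ %g Hz, stage %s, subject %s night %d epoch %d\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              if (is.na(x$stage[1])) "?" else x$stage,
              x$subject_id, x$night_id, x$epoch_index))
  invisible(x)
}

# -- event waveforms ----------------------------------------------------

# Render one transient event as a numeric vector of length round(dur * fs).
event_waveform <- function(kind, dur, amp, fs, freq = NA) {
  n <- max(2L, round(dur * fs))
  tt <- (seq_len(n) - 1) / fs
  switch(kind,
    spindle = {
      env <- exp(-0.5 * ((tt - dur / 2) / (dur / 6))^2)
      amp * env * sin(2 * pi * freq * tt)
    },
    k_complex = {
      # biphasic: negative sharp wave then positive, per clinical morphology
      half <- dur / 2
      ifelse(tt < half,
             -amp * sin(pi * tt / half),
             amp * sin(pi * (tt - half) / half))
    },
    sawtooth = {
      env <- 0.5 - 0.5 * cos(2 * pi * tt / dur)  # Hann envelope
      phase <- (freq * tt) %% 1
      amp * env * (2 * phase - 1)
    },
    blink = ,
    rapid_eye_movement = {
      # derivative-of-Gaussian biphasic pulse, peak amplitude `amp`
      s <- dur / 6
      tc <- tt - dur / 2
      amp * (tc / s) * exp(0.5 - 0.5 * (tc / s)^2)
    },
    stop("unknown event kind: ", kind))
}

# random-phase band-limited noise: unit-variance signal whose spectrum is
# confined to [f1, f2] Hz -- the rendering of one EEG rhythm component
band_noise <- function(n, fs, f1, f2) {
  nf <- n %/% 2
  freqs <- seq_len(nf) * fs / n
  sel <- which(freqs >= f1 & freqs <= f2)
  if (!length(sel)) sel <- which.min(abs(freqs - (f1 + f2) / 2))
  X <- complex(n)
  ph <- stats::runif(length(sel), 0, 2 * pi)
  X[1 + sel] <- exp(1i * ph)
  X[n + 1 - sel] <- Conj(X[1 + sel])
  x <- Re(stats::fft(X, inverse = TRUE))
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# -- epoch synthesis ----------------------------------------------------

#' Generate one synthetic 30-s EEG/EOG epoch
#'
#' Renders each oscillatory component of the stage specification as
#' randomized-phase band-limited noise spanning the component's frequency
#' band (scaled so its RMS matches a sinusoid of the drawn peak amplitude;
#' amplitude drawn uniformly in the component range, weights renormalized
#' across components), injects transient events at Poisson counts, and
#' adds Gaussian broadband noise.  The EOG channel carries an
#' attenuated copy of the oscillatory EEG background (volume conduction)
#' plus its own events and noise.  Output is deterministic given
#' `(spec, fs_hz, seed)`.
#'
#' @param spec A [stage_spec()].
#' @param fs_hz Sampling rate (Hz); must be at least twice the highest
#'   configured component/event frequency (Nyquist).
#' @param seed Integer seed.
#' @param subject_id,night_id,epoch_index Provenance passed through to the
#'   record.
#' @return An [epoch_record()] with two channels (EEG, EOG).
#' @examples
#' ep <- generate_epoch(default_stage_specs()$N3, fs_hz = 100, seed = 42)
#' dim(ep$samples)
#' @export
generate_epoch <- function(spec, fs_hz = 100, seed = 1, subject_id = "s1",
                           night_id = 1L, epoch_index = 1L) {
  stopifnot(inherits(spec, "stage_spec"))
  fmax <- max(vapply(spec$components, `[[`, 0, "band_high_hz"))
  ev_f <- vapply(spec$events, function(e)
    if (is.na(e$freq_high_hz)) 0 else e$freq_high_hz, 0)
  fmax <- max(fmax, ev_f)
  if (fs_hz < 2 * fmax)
    stop(sprintf(paste0("sampling rate %g Hz violates the Nyquist limit for ",
                        "configured frequencies up to %g Hz (need fs >= %g)"),
                 fs_hz, fmax, 2 * fmax), call. = FALSE)
  local_seed(seed)
  n <- as.integer(fs_hz * EPOCH_SECONDS)
  tt <- (seq_len(n) - 1) / fs_hz

  w <- vapply(spec$components, `[[`, 0, "weight")
  wn <- if (sum(w) > 0) w / sum(w) else w
  osc <- numeric(n)
  amps <- numeric(length(spec$components))
  for (i in seq_along(spec$components)) {
    co <- spec$components[[i]]
    amps[i] <- stats::runif(1, co$amp_low_uv, co$amp_high_uv)
    if (wn[i] == 0) next
    osc <- osc + wn[i] * (amps[i] / sqrt(2)) *
      band_noise(n, fs_hz, co$band_low_hz, co$band_high_hz)
  }

  eeg <- osc
  eog <- 0.3 * osc
  # events scale with the epoch's realized background amplitude
  base_amp <- sum(wn * amps)
  for (ev in spec$events) {
    k <- stats::rpois(1, ev$rate_per_epoch)
    if (k == 0) next
    for (j in seq_len(k)) {
      dur <- stats::runif(1, ev$duration_s[1], ev$duration_s[2])
      f <- if (is.na(ev$freq_low_hz)) NA else
        stats::runif(1, ev$freq_low_hz, ev$freq_high_hz)
      start <- stats::runif(1, 0, EPOCH_SECONDS - dur)
      wav <- event_waveform(ev$kind, dur, ev$amp_scale * base_amp, fs_hz, f)
      i0 <- 1L + as.integer(round(start * fs_hz))
      idx <- i0:min(n, i0 + length(wav) - 1L)
      wav <- wav[seq_along(idx)]
      if (ev$target_channel == "EEG") eeg[idx] <- eeg[idx] + wav
      else eog[idx] <- eog[idx] + wav
    }
  }
  if (spec$noise_sd_uv > 0) {
    eeg <- eeg + stats::rnorm(n, 0, spec$noise_sd_uv)
    eog <- eog + stats::rnorm(n, 0, spec$noise_sd_uv)
  }
  epoch_record(cbind(EEG = eeg, EOG = eog), fs_hz, spec$stage,
               subject_id, night_id, epoch_index)
}

#' Generate a stage-labelled synthetic dataset
#'
#' Generates whole "nights": a run-length-structured hypnogram per night,
#' then one epoch per hypnogram entry.  Per-subject sub-seeding makes any
#' subject's data reproducible in isolation.
#'
#' @param n_subjects,nights_per_subject,epochs_per_night Counts (>= 1).
#' @param fs_hz Sampling rate for generation (Hz).
#' @param seed Integer master seed.
#' @param specs Stage specifications, as from [default_stage_specs()].
#' @param model Hypnogram model, as from [hypnogram_model()].
#' @return List of [epoch_record()]; the per-night hypnograms are attached
#'   as attribute `"hypnograms"` (named `subject.night`).
#' @export
generate_dataset <- function(n_subjects, nights_per_subject, epochs_per_night,
                             fs_hz = 100, seed = 1,
                             specs = default_stage_specs(),
                             model = hypnogram_model()) {
  stopifnot(n_subjects >= 1, nights_per_subject >= 1, epochs_per_night >= 1)
  records <- vector("list", n_subjects * nights_per_subject * epochs_per_night)
  hyps <- list()
  r <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    for (k in seq_len(nights_per_subject)) {
      hseed <- derive_seed(seed, s, k)
      hyp <- generate_hypnogram(epochs_per_night, model, seed = hseed)
      hyps[[paste0(sid, ".", k)]] <- hyp
      for (e in seq_len(epochs_per_night)) {
        r <- r + 1L
        st <- as.character(hyp[e])
        records[[r]] <- generate_epoch(
          specs[[st]], fs_hz, seed = derive_seed(seed, s, k, e),
          subject_id = sid, night_id = k, epoch_index = e)
      }
    }
  }
  attr(records, "hypnograms") <- hyps
  records
}

# -- decimation to the model input rate ---------------------------------

# Anti-aliased integer-factor decimation: zero-phase FFT low-pass with a
# brick-wall cutoff at 90% of the post-decimation Nyquist, then subsample.
decimate_signal <- function(x, factor) {
  if (factor == 1) return(x)
  n <- length(x)
  keep <- floor(0.9 * n / (2 * factor))   # highest retained bin
  X <- stats::fft(x)
  zero <- seq.int(keep + 2L, n - keep)    # bins above cutoff (both sides)
  X[zero] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y[seq.int(1L, n, by = factor)]
}

#' Convert epoch records to the model input tensor
#'
#' Decimates each channel to the model sampling rate (canonical 10 Hz, so a
#' 30-s epoch becomes 300 samples) with an anti-aliasing low-pass, and
#' applies a fixed amplitude gain so typical EEG amplitudes land in a range
#' friendly to the network nonlinearity.
#'
#' @param records List of [epoch_record()].
#' @param model_fs_hz Target sampling rate (Hz).
#' @param gain Amplitude scale applied after decimation (per microvolt).
#' @return List with `x` (array `n_samples x n_channels x n_epochs`),
#'   `y` (stage factor, `NA` where unscored), and `meta` (data frame of
#'   subject/night/epoch).
#' @export
as_model_input <- function(records, model_fs_hz = 10, gain = 0.01) {
  stopifnot(length(records) >= 1)
  fs <- records[[1]]$fs_hz
  if (fs %% model_fs_hz != 0)
    stop("record sampling rate must be an integer multiple of the model rate",
         call. = FALSE)
  q <- as.integer(fs / model_fs_hz)
  tlen <- as.integer(model_fs_hz * EPOCH_SECONDS)
  nc <- ncol(records[[1]]$samples)
  x <- array(0, dim = c(tlen, nc, length(records)))
  for (i in seq_along(records)) {
    s <- records[[i]]$samples
    for (ch in seq_len(nc)) x[, ch, i] <- decimate_signal(s[, ch], q) * gain
  }
  y <- stage_factor(vapply(records, function(r)
    if (is.na(r$stage[1])) NA_character_ else r$stage, ""))
  meta <- data.frame(
    subject_id = vapply(records, `[[`, "", "subject_id"),
    night_id = vapply(records, `[[`, 1L, "night_id"),
    epoch_index = vapply(records, `[[`, 1L, "epoch_index"))
  list(x = x, y = y, meta = meta)
}
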