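#' Oscillatory component of a stage specification
#'
#' One narrowband rhythm contributing to the EEG of a sleep stage: a
#' frequency band, an amplitude range and a unitless mixing weight.
#' Weights across the components of a stage need not sum to one; they are
#' renormalized at synthesis time.
#'
#' @param band_low_hz,band_high_hz Band edges in Hz, `band_low_hz < band_high_hz`.
#' @param amp_low_uv,amp_high_uv Peak amplitude range in microvolts.
#' @param weight Non-negative mixing proportion.
#' @return Object of class `osc_component`.
#' @export
osc_component <- function(band_low_hz, band_high_hz, amp_low_uv, amp_high_uv,
                          weight = 1) {
  stopifnot(band_low_hz < band_high_hz, amp_low_uv <= amp_high_uv, weight >= 0)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 amp_low_uv = amp_low_uv, amp_high_uv = amp_high_uv,
                 weight = weight),
            class = "osc_component")
}

#' Transient event of a stage specification
#'
#' Short waveforms injected on top of the oscillatory background: sleep
#' spindles (12-14 Hz bursts), K-complexes (biphasic, negative-then-positive,
#' duration above 0.5 s), REM sawtooth waves (2-7 Hz), and the two ocular
#' events rendered on the EOG channel (blinks and rapid eye movements).
#' Event counts per 30-s epoch are Poisson with mean `rate_per_epoch`.
#'
#' @param kind One of `"spindle"`, `"k_complex"`, `"sawtooth"`, `"blink"`,
#'   `"rapid_eye_movement"`.
#' @param duration_s Length-2 range (seconds) from which each event's
#'   duration is drawn.
#' @param rate_per_epoch Expected number of events per 30-s epoch.
#' @param freq_low_hz,freq_high_hz Intra-burst oscillation band (spindle and
#'   sawtooth events only; ignored otherwise).
#' @param target_channel `"EEG"` or `"EOG"`.
#' @param amp_scale Event amplitude as a multiple of the stage's mean
#'   background amplitude.
#' @return Object of class `transient_event`.
#' @export
transient_event <- function(kind, duration_s, rate_per_epoch,
                            freq_low_hz = NA_real_, freq_high_hz = NA_real_,
                            target_channel = "EEG", amp_scale = 1.5) {
  kind <- match.arg(kind, c("spindle", "k_complex", "sawtooth", "blink",
                            "rapid_eye_movement"))
  stopifnot(length(duration_s) == 2, all(duration_s > 0),
            rate_per_epoch >= 0, target_channel %in% c("EEG", "EOG"))
  if (kind == "k_complex" && duration_s[1] <= 0.5)
    stop("K-complex duration must exceed 0.5 s", call. = FALSE)
  structure(list(kind = kind, duration_s = duration_s,
                 rate_per_epoch = rate_per_epoch,
                 freq_low_hz = freq_low_hz, freq_high_hz = freq_high_hz,
                 target_channel = target_channel, amp_scale = amp_scale),
            class = "transient_event")
}

#' Per-stage generative specification
#'
#' @param stage Stage name (see [stage_levels()]).
#' @param components List of [osc_component()] (at least one).
#' @param events List of [transient_event()] (possibly empty).
#' @param noise_sd_uv Standard deviation of additive Gaussian broadband
#'   noise, microvolts.  Default: 10% of the dominant component's mean
#'   amplitude.
#' @return Object of class `stage_spec`.
#' @export
stage_spec <- function(stage, components, events = list(), noise_sd_uv = NULL) {
  stage <- as.character(stage_factor(stage))
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "osc_component")),
            all(vapply(events, inherits, TRUE, "transient_event")))
  if (is.null(noise_sd_uv)) {
    dom <- components[[which.max(vapply(components, `[[`, 0, "weight"))]]
    noise_sd_uv <- 0.1 * mean(c(dom$amp_low_uv, dom$amp_high_uv))
  }
  stopifnot(noise_sd_uv >= 0)
  structure(list(stage = stage, components = components, events = events,
                 noise_sd_uv = noise_sd_uv),
            class = "stage_spec")
}

#' Default per-stage generative specifications
#'
#' Encodes the classical spectral picture of the five AASM stages:
#' * **W** — uninterrupted alpha (8-13 Hz, 20-100 uV) with some beta,
#'   frequent blinks on the EOG;
#' * **N1** — theta (4-8 Hz, 20-150 uV) dominant, alpha content reduced
#'   below half;
#' * **N2** — theta background with emerging delta, plus sleep spindles
#'   (12-14 Hz) and K-complexes;
#' * **N3** — high-amplitude slow delta (0.5-2 Hz, 20-200 uV) dominant;
#' * **REM** — theta with irregular alpha, sawtooth waves (2-7 Hz) and
#'   rapid eye movements on the EOG.
#'
#' @return Named list mapping stage name to [stage_spec()].
#' @examples
#' specs <- default_stage_specs()
#' specs$W$components[[1]]$band_low_hz   # 8
#' @export
default_stage_specs <- function() {
  list(
    W = stage_spec("W",
      components = list(
        osc_component(8, 13, 20, 100, weight = 0.8),
        osc_component(13, 30, 5, 20, weight = 0.2)),
      events = list(
        transient_event("blink", duration_s = c(0.2, 0.4),
                        rate_per_epoch = 5, target_channel = "EOG",
                        amp_scale = 2))),
    N1 = stage_spec("N1",
      components = list(
        osc_component(4, 8, 20, 150, weight = 0.75),
        osc_component(8, 13, 20, 100, weight = 0.25))),
    N2 = stage_spec("N2",
      components = list(
        osc_component(4, 8, 20, 150, weight = 0.75),
        osc_component(0.5, 4, 20, 200, weight = 0.1),
        osc_component(8, 13, 20, 100, weight = 0.15)),
      events = list(
        transient_event("spindle", duration_s = c(0.5, 1.5),
                        rate_per_epoch = 3, freq_low_hz = 12,
                        freq_high_hz = 14),
        transient_event("k_complex", duration_s = c(0.6, 1.0),
                        rate_per_epoch = 1.5))),
    N3 = stage_spec("N3",
      components = list(
        osc_component(0.5, 2, 20, 200, weight = 0.85),
        osc_component(4, 8, 20, 150, weight = 0.15))),
    REM = stage_spec("REM",
      components = list(
        osc_component(4, 8, 20, 150, weight = 0.6),
        osc_component(8, 13, 20, 100, weight = 0.2)),
      events = list(
        transient_event("sawtooth", duration_s = c(1, 2.5),
                        rate_per_epoch = 4, freq_low_hz = 2,
                        freq_high_hz = 7),
        transient_event("rapid_eye_movement", duration_s = c(0.15, 0.3),
                        rate_per_epoch = 10, target_channel = "EOG",
                        amp_scale = 2)))
  )
}

# mean background amplitude of a stage: weight-normalized mean of the
# component amplitude midpoints -- the unit for event amplitude scaling
stage_mean_amplitude <- function(spec) {
  w <- vapply(spec$components, `[[`, 0, "weight")
  if (sum(w) == 0) return(0)
  mids <- vapply(spec$components,
                 function(co) mean(c(co$amp_low_uv, co$amp_high_uv)), 0)
  sum(w / sum(w) * mids)
}
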