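test_that("default stage specs encode the canonical per-stage rhythms", {
  specs <- default_stage_specs()
  expect_setequal(names(specs), stage_levels())

  # wake: uninterrupted alpha 8-13 Hz at 20-100 uV
  wa <- specs$W$components[[1]]
  expect_equal(c(wa$band_low_hz, wa$band_high_hz), c(8, 13))
  expect_equal(c(wa$amp_low_uv, wa$amp_high_uv), c(20, 100))

  # deep sleep: dominant slow delta 0.5-2 Hz with weight above 0.2
  n3 <- specs$N3$components[[1]]
  expect_equal(c(n3$band_low_hz, n3$band_high_hz), c(0.5, 2))
  expect_gt(n3$weight, 0.2)

  # N1 keeps alpha below half
  n1w <- vapply(specs$N1$components, `[[`, 0, "weight")
  alpha_i <- which(vapply(specs$N1$components, `[[`, 0, "band_low_hz") == 8)
  expect_lt(n1w[alpha_i] / sum(n1w), 0.5)

  # N2 carries spindles (12-14 Hz) and K-complexes; REM carries sawtooth
  n2_kinds <- vapply(specs$N2$events, `[[`, "", "kind")
  expect_setequal(n2_kinds, c("spindle", "k_complex"))
  sp <- specs$N2$events[[match("spindle", n2_kinds)]]
  expect_equal(c(sp$freq_low_hz, sp$freq_high_hz), c(12, 14))
  rem_kinds <- vapply(specs$REM$events, `[[`, "", "kind")
  expect_true("sawtooth" %in% rem_kinds)
  st <- specs$REM$events[[match("sawtooth", rem_kinds)]]
  expect_equal(c(st$freq_low_hz, st$freq_high_hz), c(2, 7))

  # constructor contract: every stage has components and a valid spec
  for (s in specs) {
    expect_s3_class(s, "stage_spec")
    expect_gte(length(s$components), 1)
    for (co in s$components) {
      expect_lt(co$band_low_hz, co$band_high_hz)
      expect_lte(co$amp_low_uv, co$amp_high_uv)
      expect_gte(co$weight, 0)
    }
  }
})

test_that("type constructors enforce their invariants", {
  expect_error(osc_component(8, 4, 20, 100), "band_low_hz")
  expect_error(transient_event("k_complex", c(0.3, 0.5), 1), "0.5 s")
  expect_error(stage_spec("W", list()), "length")
  expect_error(stage_factor("N4"), "unknown sleep stage")
  expect_equal(stage_code(c("W", "REM")), c(0L, 4L))
  expect_equal(levels(stage_factor(0:4)), c("W", "N1", "N2", "N3", "REM"))
})

test_that("generate_epoch renders the configured spectrum deterministically", {
  specs <- default_stage_specs()
  ep1 <- generate_epoch(specs$W, fs_hz = 100, seed = 7)
  ep2 <- generate_epoch(specs$W, fs_hz = 100, seed = 7)
  expect_identical(ep1$samples, ep2$samples)
  expect_equal(dim(ep1$samples), c(3000, 2))
  expect_false(anyNA(ep1$samples))

  ep3 <- generate_epoch(specs$W, fs_hz = 100, seed = 8)
  expect_false(identical(ep1$samples, ep3$samples))

  # wake epochs peak in the alpha band
  expect_true(welch_peak_hz(ep1$samples[, "EEG"], 100) >= 8)
  expect_true(welch_peak_hz(ep1$samples[, "EEG"], 100) <= 13)

  # zero-amplitude spec yields an all-zero epoch
  zspec <- stage_spec("W", list(osc_component(8, 13, 20, 100, weight = 0)),
                      noise_sd_uv = 0)
  expect_true(all(generate_epoch(zspec, 100, seed = 1)$samples == 0))

  # Nyquist violation is rejected
  expect_error(generate_epoch(specs$W, fs_hz = 20, seed = 1), "Nyquist")
})

test_that("spectral fidelity: each stage's dominant band wins the periodogram", {
  specs <- default_stage_specs()
  dominant <- list(W = "alpha", N1 = "theta", N2 = "theta", N3 = "delta",
                   REM = "theta")
  for (st in names(dominant)) {
    wins <- 0L
    for (k in 1:20) {
      ep <- generate_epoch(specs[[st]], 100, seed = 1000 + k)
      re <- relative_band_energy(ep$samples[, "EEG"], 100)
      if (names(which.max(re)) == dominant[[st]]) wins <- wins + 1L
    }
    expect_gte(wins, 19)
  }
})

test_that("hypnograms follow the configured proportions and run structure", {
  h <- generate_hypnogram(1000, seed = 5)
  frac <- table(h) / 1000
  expect_lt(abs(frac[["N2"]] - 0.495), 0.08)

  # printed clinical ranges hold for the defaults
  p <- hypnogram_model()$proportions
  expect_true(p[["N1"]] >= 0.05 && p[["N1"]] <= 0.10)
  expect_true(p[["N2"]] >= 0.44 && p[["N2"]] <= 0.55)
  expect_true(p[["N3"]] >= 0.10 && p[["N3"]] <= 0.20)

  # degenerate distribution
  m <- hypnogram_model(proportions = c(W = 1, N1 = 0, N2 = 0, N3 = 0,
                                       REM = 0))
  expect_true(all(generate_hypnogram(50, m, seed = 1) == "W"))
  expect_error(hypnogram_model(proportions = c(W = 0, N1 = 0, N2 = 0,
                                               N3 = 0, REM = 0)),
               "zero")
  expect_identical(generate_hypnogram(200, seed = 9),
                   generate_hypnogram(200, seed = 9))
})

test_that("generate_dataset indexes, labels and reproduces records", {
  recs <- generate_dataset(2, 1, 10, fs_hz = 100, seed = 3)
  expect_length(recs, 20)
  expect_setequal(unique(vapply(recs, `[[`, "", "subject_id")),
                  c("s01", "s02"))

  # stage labels equal the hypnogram at each epoch index
  hyps <- attr(recs, "hypnograms")
  for (r in recs)
    expect_equal(r$stage,
                 as.character(hyps[[paste0(r$subject_id, ".",
                                           r$night_id)]][r$epoch_index]))

  recs2 <- generate_dataset(2, 1, 10, fs_hz = 100, seed = 3)
  expect_identical(lapply(recs, `[[`, "samples"),
                   lapply(recs2, `[[`, "samples"))
})

test_that("model-rate conversion decimates with anti-aliasing", {
  # a 2 Hz tone survives decimation to 10 Hz; a 20 Hz tone is removed
  tt <- seq(0, 30 - 1 / 100, by = 1 / 100)
  lo <- sin(2 * pi * 2 * tt)
  hi <- sin(2 * pi * 20 * tt)
  rec <- epoch_record(cbind(EEG = lo + hi, EOG = lo), fs_hz = 100,
                      stage = "W")
  inp <- as_model_input(list(rec))
  expect_equal(dim(inp$x), c(300, 2, 1))
  dec <- inp$x[, 1, 1] / 0.01
  expect_gt(stats::sd(dec), 0.5)                       # low tone retained
  expect_equal(welch_peak_hz(dec, 10), 2, tolerance = 0.2)
  hi_only <- epoch_record(cbind(EEG = hi, EOG = hi), 100, "W")
  expect_lt(stats::sd(as_model_input(list(hi_only))$x[, 1, 1] / 0.01),
            0.05)                                      # high tone removed
})
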