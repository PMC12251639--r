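# Synthetic BVP generator: beat timing, HRV-band modulation, waveform
# rendering, event implantation and dataset assembly.

test_that("unmodulated beat train has constant unit IBIs", {
  spec <- session_spec(duration_s = 60, hr_base = 60, seed = 1)
  beats <- generate_beat_times(spec)
  expect_length(beats, 60)
  expect_equal(diff(beats), rep(1, 59))
})

test_that("a single HF band leaves the sinusoid's RMS in the IBI sd", {
  spec <- session_spec(duration_s = 300, hr_base = 60,
                       bands = list(list(freq = 0.25, amplitude = 0.05,
                                         phase = 0)), seed = 2)
  ibis <- diff(generate_beat_times(spec))
  expect_equal(sd(ibis), 0.05 / sqrt(2), tolerance = 0.1)
})

test_that("beat generation is deterministic and strictly increasing", {
  spec <- session_spec(duration_s = 120, hr_base = 72,
                       bands = default_bands(c(0.3, 1.2, 2.5)),
                       event_chunks = c(2L, 7L), seed = 3)
  b1 <- generate_beat_times(spec)
  b2 <- generate_beat_times(spec)
  expect_identical(b1, b2)
  expect_true(all(diff(b1) > 0))
})

test_that("IBI spectrum peaks at the modulation frequency", {
  f0 <- 0.1
  spec <- session_spec(duration_s = 600, hr_base = 60,
                       bands = list(list(freq = f0, amplitude = 0.04,
                                         phase = 0)), seed = 4)
  beats <- generate_beat_times(spec)
  ibis <- diff(beats)
  # resample the IBI series on a uniform 2 Hz grid before the FFT
  grid <- seq(0, max(beats) - 1, by = 0.5)
  y <- approx(beats[-1], ibis, xout = grid, rule = 2)$y
  y <- y - mean(y)
  spec_pow <- Mod(fft(y))^2
  freqs <- (seq_along(y) - 1) / (length(y) * 0.5)
  half <- 2:(length(y) %/% 2)
  peak <- freqs[half][which.max(spec_pow[half])]
  expect_lt(abs(peak - f0), 1 / (length(y) * 0.5) + 1e-9)
})

test_that("rendered waveform has the right length and peak placement", {
  spec <- session_spec(duration_s = 60, hr_base = 60, seed = 5)
  w <- render_waveform(generate_beat_times(spec), spec)
  expect_length(w, 1800)
  spec1 <- session_spec(duration_s = 10, hr_base = 60, seed = 5)
  w1 <- render_waveform(2.0, spec1)
  expect_lte(abs(which.max(w1) - 1 - 2 * 30), 2)
  expect_error(render_waveform(11, spec1), "duration")
})

test_that("event gain raises in-event peak heights by the configured factor", {
  spec <- session_spec(duration_s = 86, hr_base = 60, noise_sd = 0,
                       artifact_rate = 0, event_chunks = c(5L, 12L),
                       event_hr_surge = 0, event_gain = 1.5, seed = 6)
  w <- render_waveform(generate_beat_times(spec), spec)
  idx <- seq_along(w) - 1
  inside <- floor(idx / 128) %in% spec$event_chunks
  ratio <- max(w[inside]) / max(w[!inside])
  expect_equal(ratio, 1.5, tolerance = 0.05)
})

test_that("saliency masks mirror the event chunk set", {
  spec0 <- session_spec(duration_s = 90, hr_base = 70, seed = 7)
  expect_equal(implant_saliency(spec0), integer(spec0$n_chunks))
  spec3 <- session_spec(duration_s = 90, hr_base = 70,
                        event_chunks = c(2L, 5L, 9L), seed = 7)
  m <- implant_saliency(spec3)
  expect_length(m, spec3$n_chunks)
  expect_equal(sum(m), 3L)
  expect_equal(which(m == 1L) - 1L, c(2L, 5L, 9L))
})

test_that("the HR surge inside event chunks matches the spec within 2 bpm", {
  set.seed(123)
  surges <- replicate(10, {
    ev <- sort(sample(0:19, 3))
    spec <- session_spec(duration_s = 86, hr_base = 70,
                         event_chunks = ev, event_hr_surge = 20,
                         seed = sample.int(1e6, 1))
    beats <- generate_beat_times(spec)
    ibis <- diff(beats)
    inside <- pulsemil:::in_event_chunk(beats[-length(beats)], spec) &
      pulsemil:::in_event_chunk(beats[-1], spec)
    mean(60 / ibis[inside]) - mean(60 / ibis[!inside])
  })
  expect_lt(abs(mean(surges) - 20), 2)
})

test_that("invalid specs are rejected", {
  expect_error(session_spec(60, fs = 25), "fs")
  expect_error(session_spec(60, hr_base = 20), "hr_base")
  expect_error(session_spec(60, hr_base = 60, event_chunks = 99L), "event_chunks")
  expect_error(session_spec(60, hr_base = 60,
                            bands = list(list(freq = 0.1, amplitude = 0.9,
                                              phase = 0))), "amplitude")
})

test_that("generate_dataset honours class balance, labels and determinism", {
  ds <- generate_dataset(40, 0.5, c(2, 3), duration_s = 43, seed = 9)
  lab <- binarize_rating(ds$manifest$rating_arousal)
  expect_equal(sum(lab == "high"), 20)
  # high-arousal iff events implanted, low-arousal masks all zero
  for (i in seq_len(40)) {
    id <- ds$manifest$session_id[i]
    if (lab[i] == "high") {
      expect_gte(sum(ds$masks[[id]]), 2)
      expect_lte(sum(ds$masks[[id]]), 3)
    } else {
      expect_equal(sum(ds$masks[[id]]), 0L)
    }
  }
  ds2 <- generate_dataset(40, 0.5, c(2, 3), duration_s = 43, seed = 9)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$waveforms, ds2$waveforms)
  expect_error(generate_dataset(40, 0.5, c(2, 99), duration_s = 43, seed = 9),
               "event_count_range")
  expect_error(generate_dataset(1, 0.5, c(1, 1)), "at least 2")
})

test_that("short-window HR inside event chunks stochastically dominates", {
  ds <- generate_dataset(50, 0.5, c(3, 3), duration_s = 86, seed = 10)
  hr_in <- c(); hr_out <- c()
  for (id in names(ds$specs)) {
    spec <- ds$specs[[id]]
    beats <- generate_beat_times(spec)
    ibis <- diff(beats)
    mids <- (beats[-1] + beats[-length(beats)]) / 2
    inside <- pulsemil:::in_event_chunk(mids, spec)
    hr_in <- c(hr_in, 60 / ibis[inside])
    hr_out <- c(hr_out, 60 / ibis[!inside])
  }
  expect_lt(wilcox.test(hr_in, hr_out, alternative = "greater")$p.value, 0.01)
})
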