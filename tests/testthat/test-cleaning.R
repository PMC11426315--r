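# High-pass filtering, normalization, spectral gating, BBR screening.

test_that("zero-phase Butterworth high-pass rejects DC and low bands", {
  cfg <- cleaning_config(hp_cutoff_hz = 2000)
  dc <- waveform(rep(0.5, RATE), RATE)
  expect_lt(max(abs(highpass(dc, cfg)$samples)), 1e-4)

  # tone one octave above cutoff: essentially untouched
  hi <- tone_wave(4000, 1)
  out <- highpass(hi, cfg)
  gain_db <- 20 * log10(interior_amplitude(out$samples) /
                          interior_amplitude(hi$samples))
  expect_lt(abs(gain_db), 1)

  # tone at the cutoff: -3 dB per pass, -6 dB after forward-backward
  at <- tone_wave(2000, 1)
  out_at <- highpass(at, cfg)
  gain_at <- 20 * log10(interior_amplitude(out_at$samples) /
                          interior_amplitude(at$samples))
  expect_equal(gain_at, -6.0206, tolerance = 0.35)

  expect_error(highpass(tone_wave(100, 0.5, rate = 8000),
                        cleaning_config(hp_cutoff_hz = 5000)), "Nyquist")
  expect_equal(length(out$samples), length(hi$samples))
})

test_that("peak normalization hits the target exactly and is pure gain", {
  w <- waveform(c(0.5, -0.25, 0.1), 1000)
  out <- normalize_peak(w, -1)
  expect_equal(peak_dbfs(out), -1, tolerance = 1e-9)
  expect_equal(max(abs(out$samples)), 10^(-1 / 20), tolerance = 1e-12)
  # closed form: gain = 10^(-1/20) / 0.5
  expect_equal(out$samples, w$samples * 10^(-1 / 20) / 0.5,
               tolerance = 1e-12)

  already <- waveform(w$samples * 10^(-1 / 20) / 0.5, 1000)
  expect_equal(normalize_peak(already, -1)$samples, already$samples,
               tolerance = 1e-12)
  expect_error(normalize_peak(waveform(numeric(10), 1000)), "silent")
})

test_that("spectral gate attenuates noise but preserves strong tones", {
  cfg <- cleaning_config(gate_reduction_db = 10)
  set.seed(5)
  noise <- noise_wave(1.5, sd = 0.05)
  ref_noise <- noise_wave(1.5, sd = 0.05)
  gated <- spectral_gate(noise, cfg, noise_sample = ref_noise)
  reduction_db <- 20 * log10(rms(noise) / rms(gated))
  expect_gte(reduction_db, cfg$gate_reduction_db - 3)

  # strong 5 kHz tone 30 dB over the noise floor: bin preserved within 1 dB
  tone <- tone_wave(5000, 1.5, amp = 0.05 * 10^(30 / 20))
  mix <- waveform(tone$samples + noise$samples[seq_along(tone$samples)],
                  RATE)
  gated_mix <- spectral_gate(mix, cfg, noise_sample = ref_noise)
  bin_db_before <- band_energy_db(mix, 4900, 5100)
  bin_db_after <- band_energy_db(gated_mix, 4900, 5100)
  expect_lt(abs(bin_db_after - bin_db_before), 1)

  z <- waveform(numeric(2 * RATE), RATE)
  expect_identical(spectral_gate(z, cfg)$samples, z$samples)
  expect_error(spectral_gate(waveform(rnorm(100), RATE), cfg), "shorter")
  # energy never increases
  expect_lte(sum(gated_mix$samples^2), sum(mix$samples^2))
})

test_that("BBR compares in-band song and background power", {
  rate <- 8000
  t <- (0:(3 * rate - 1)) / rate
  a <- 0.2
  x <- a * sin(2 * pi * 1000 * t)
  w <- waveform(x, rate)
  flat <- estimate_bbr(w, time_interval(1, 2), c(800, 1200))
  expect_equal(flat$ratio_db, 0, tolerance = 0.1)
  expect_false(flat$remove)

  # song second 10x the RMS of the rest -> +20 dB
  x2 <- x
  x2[(rate + 1):(2 * rate)] <- 10 * x2[(rate + 1):(2 * rate)]
  loud <- estimate_bbr(waveform(x2, rate), time_interval(1, 2), c(800, 1200))
  expect_equal(loud$ratio_db, 20, tolerance = 0.2)

  # song 10 dB quieter than background and quieter still -> flagged
  x3 <- x
  x3[(rate + 1):(2 * rate)] <- x3[(rate + 1):(2 * rate)] / 10^(15 / 20)
  quiet <- estimate_bbr(waveform(x3, rate), time_interval(1, 2),
                        c(800, 1200))
  expect_true(quiet$remove)
  expect_lt(quiet$ratio_db, -10)

  # gain invariance
  g <- estimate_bbr(waveform(3 * x2, rate), time_interval(1, 2),
                    c(800, 1200))
  expect_equal(g$ratio_db, loud$ratio_db, tolerance = 1e-9)
})

test_that("the cleaning chain keeps in-band song energy and strips rumble", {
  set.seed(21)
  song <- synth_song(song_spec(seed = 3), RATE)
  n <- length(song$samples)
  t <- (0:(n - 1)) / RATE
  rumble <- 0.4 * sin(2 * pi * 80 * t) + 0.2 * sin(2 * pi * 160 * t)
  hiss <- rnorm(n, 0, 0.004)
  dirty <- waveform(song$samples + rumble + hiss, RATE)
  cleaned <- clean_segment(dirty)

  in_band_in <- band_energy_db(normalize_peak(song, -1), 3400, 6100)
  in_band_out <- band_energy_db(cleaned, 3400, 6100)
  expect_lt(abs(in_band_out - in_band_in), 2)
  out_band_drop <- band_energy_db(dirty, 20, 300) -
    band_energy_db(cleaned, 20, 300)
  expect_gt(out_band_drop, 20)

  expect_error(clean_segment(waveform(numeric(RATE), RATE)), "silent")

  # second pass over already-clean audio changes RMS by < 1 dB
  twice <- clean_segment(cleaned)
  expect_lt(abs(20 * log10(rms(twice) / rms(cleaned))), 1)
})
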