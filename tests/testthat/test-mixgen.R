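# Background stitching, augmentation, ratio control, and the mixture
# generator's exact-stems contract.

test_that("stitching is seeded, exact-length, and convex at joins", {
  rate <- 1000
  long <- waveform(sin(2 * pi * 5 * (0:(20 * rate - 1)) / rate) * 0.4, rate)
  out <- stitch_background(list(long), 5, seed = 3)
  expect_length(out$samples, 5 * rate)
  # a single long piece yields a contiguous excerpt
  lag <- xcorr_lag(waveform(out$samples, rate),
                   waveform(long$samples, rate))
  excerpt <- long$samples[round(lag * rate) + seq_len(5 * rate)]
  expect_equal(out$samples, excerpt, tolerance = 1e-12)

  a <- waveform(rep(0.2, 2 * rate), rate)
  b <- waveform(rep(0.8, 2 * rate), rate)
  st <- stitch_background(list(a, b), 7, seed = 5)
  expect_true(all(st$samples >= 0.2 - 1e-12 & st$samples <= 0.8 + 1e-12))

  s1 <- stitch_background(list(a, b), 7, seed = 11)
  s2 <- stitch_background(list(a, b), 7, seed = 11)
  expect_identical(s1$samples, s2$samples)
  expect_error(stitch_background(list(), 5), "empty")
})

test_that("time stretch and pitch shift do what their names say", {
  song <- synth_song(song_spec(seed = 6), RATE)
  st <- time_stretch(song, 1.2)
  expect_equal(length(st$samples), round(length(song$samples) * 1.2))
  # pitch preserved under stretch: exact check on a tone, band check on
  # the multi-component song
  tn <- tone_wave(2000, 1)
  expect_lt(abs(dominant_freq(time_stretch(tn, 1.3)) - 2000), 10)
  in_band <- function(w) {
    xb <- songsep:::bandpass_fft(w$samples, w$rate, 3400, 6100)
    sum(xb^2) / sum(w$samples^2)
  }
  expect_gt(in_band(st), 0.8)

  ps <- pitch_shift(tone_wave(2000, 1), 1)
  expect_equal(length(ps$samples), RATE)
  expect_lt(abs(dominant_freq(ps) - 2000 * 2^(1 / 12)), 6)

  ranges_id <- augmentation_ranges(time_stretch = c(1, 1), gain = c(1, 1),
                                   pitch_shift_semitones = c(0, 0))
  out <- augment_song(song, ranges_id, seed = 1)
  expect_gt(stats::cor(out$wave$samples, song$samples), 0.99)

  g <- augment_song(song, augmentation_ranges(
    time_stretch = c(1, 1), gain = c(0.15, 0.15),
    pitch_shift_semitones = c(0, 0)), seed = 2)
  expect_equal(rms(g$wave), 0.15 * rms(song), tolerance = 1e-6)
  expect_equal(g$params$gain, 0.15)
})

test_that("realized_ratio is the stem RMS ratio", {
  rate <- 1000
  s <- waveform(rnorm(rate, 0, 0.1), rate)
  b <- waveform(rnorm(rate, 0, 0.1), rate)
  b <- waveform(b$samples * rms(s) / rms(b), rate)
  expect_equal(realized_ratio(s, b), 1, tolerance = 1e-12)
  expect_equal(realized_ratio(waveform(s$samples / 2, rate), b), 0.5,
               tolerance = 1e-12)
  expect_error(realized_ratio(s, waveform(numeric(rate), rate)), "silent")
})

make_banks <- function(rate = RATE) {
  songs <- list(
    list(wave = synth_song(song_spec(seed = 1), rate), class = "A_hook"),
    list(wave = synth_song(song_spec(has_hook = FALSE, seed = 2), rate),
         class = "A_nohook"),
    list(wave = synth_song(song_spec(song_type = "B", seed = 3), rate),
         class = "B"))
  bgs <- lapply(1:2, function(i) synth_background(
    background_spec(duration_s = 12, seed = i), rate))
  list(songs = songs, bgs = bgs)
}

test_that("generated examples satisfy exact stem additivity and ratios", {
  bk <- make_banks()
  ex <- generate_example(bk$songs, bk$bgs,
                         mix_spec(duration_s = 8, n_songs = 3,
                                  target_ratio = 0.05, seed = 10))
  expect_identical(ex$mixture$samples,
                   ex$song_stem$samples + ex$background_stem$samples)
  expect_equal(ex$realized_ratio, 0.05, tolerance = 1e-6)
  expect_equal(nrow(ex$events), 3)
  expect_true(all(ex$events$end_s <= 8 + 1e-9))

  # no songs: mixture is exactly the background bed
  ex0 <- generate_example(bk$songs, bk$bgs,
                          mix_spec(duration_s = 8, songs_per_min = 0,
                                   seed = 4))
  expect_identical(ex0$song_stem$samples, numeric(8 * RATE))
  expect_identical(ex0$mixture$samples, ex0$background_stem$samples)

  # end-to-end seed determinism
  exa <- generate_example(bk$songs, bk$bgs,
                          mix_spec(duration_s = 8, n_songs = 2, seed = 21))
  exb <- generate_example(bk$songs, bk$bgs,
                          mix_spec(duration_s = 8, n_songs = 2, seed = 21))
  expect_identical(exa$mixture$samples, exb$mixture$samples)
  expect_identical(exa$events, exb$events)
})

test_that("class weights drive song-type frequencies", {
  bk <- make_banks()
  counts <- c(A_hook = 0, A_nohook = 0)
  n_ex <- 30
  for (i in seq_len(n_ex)) {
    ex <- generate_example(
      bk$songs, bk$bgs,
      mix_spec(duration_s = 8, n_songs = 20,
               class_weights = c(A_hook = 1, A_nohook = 5), seed = 100 + i))
    tab <- table(ex$events$class)
    for (nm in names(counts))
      counts[nm] <- counts[nm] + ifelse(nm %in% names(tab), tab[[nm]], 0)
  }
  n <- sum(counts)
  p_hat <- counts[["A_nohook"]] / n
  se <- sqrt(5 / 6 * 1 / 6 / n)
  expect_lt(abs(p_hat - 5 / 6), 3 * se)
})

test_that("background attenuation schedule fires at its probabilities", {
  bk <- make_banks()
  gains <- vapply(1:200, function(i) generate_example(
    bk$songs, bk$bgs,
    mix_spec(duration_s = 0.5, songs_per_min = 0, seed = 1000 + i))$bg_gain,
    numeric(1))
  expect_setequal(unique(gains), c(1, 0.1, 0.05))
  # each rare branch fires with probability 0.05; 3-sigma binomial check
  for (g in c(0.1, 0.05)) {
    p_hat <- mean(gains == g)
    expect_lt(abs(p_hat - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  }
})
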