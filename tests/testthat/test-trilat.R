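# Forest impulse responses, scene rendering, TDOA estimation, and the
# trilateration solver.

test_that("free-field impulse response is a single 1/d tap at d/c", {
  ir <- simulate_forest_ir(c(34.3, 0, 1.5), c(0, 0, 1.5),
                           forest_ir_config(n_trees = 0), rate = 22050)
  nz <- which(ir$samples != 0)
  expect_length(nz, 1)
  expect_equal((nz - 1) / 22050, 0.1, tolerance = 1 / 22050)
  expect_equal(ir$samples[nz], 1 / 34.3, tolerance = 1e-12)
  expect_error(simulate_forest_ir(c(1, 1, 1), c(1, 1, 1),
                                  forest_ir_config()), "coincide")
})

test_that("echoes always arrive after the direct path and grow with trees", {
  src <- c(8, 3, 1.5); mic <- c(0, 0, 1.5)
  direct_tap <- round(sqrt(sum((src - mic)^2)) / 343 * 22050) + 1
  for (sd in 1:5) {
    ir <- simulate_forest_ir(src, mic,
                             forest_ir_config(n_trees = 200, seed = sd),
                             rate = 22050)
    expect_equal(min(which(ir$samples != 0)), direct_tap)
  }
  echo_energy <- function(nt) mean(vapply(1:8, function(sd) {
    ir <- simulate_forest_ir(src, mic,
                             forest_ir_config(n_trees = nt, seed = sd),
                             22050)$samples
    sum(ir^2) - ir[direct_tap]^2
  }, numeric(1)))
  e <- vapply(c(50, 200, 800), echo_energy, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("scene rendering respects geometry and the target ratio", {
  song <- synth_song(song_spec(seed = 5), 22050)
  mics <- default_mic_array()

  # bird equidistant from mics 2 and 3: identical song components
  ch <- render_scene(song, NULL, c(5, 5, 1.5), mics,
                     forest_ir_config(n_trees = 0))
  sc <- attr(ch, "song_channels")
  expect_equal(sc[[2]]$samples, sc[[3]]$samples, tolerance = 1e-9)

  # no trees: channel k is the song delayed by d_k/c and scaled 1/d_k
  pos <- c(3, 7, 1.5)
  ch2 <- render_scene(song, NULL, pos, mics, forest_ir_config(n_trees = 0))
  d1 <- sqrt(sum((pos - c(0, 0, 1.5))^2))
  lagd <- round(d1 / 343 * 22050)
  got <- ch2[[1]]$samples[lagd + seq_along(song$samples)]
  expect_equal(got, song$samples / d1, tolerance = 1e-9)

  # background added identically across channels at the channel-1 ratio
  bg <- synth_background(background_spec(duration_s = 2, seed = 6), 22050)
  ch3 <- render_scene(song, bg, pos, mics, forest_ir_config(n_trees = 0),
                      ratio = 0.5)
  s1 <- attr(ch3, "song_channels")[[1]]
  b <- attr(ch3, "background")
  expect_equal(rms(s1) / rms(b), 0.5, tolerance = 1e-9)
  expect_equal(ch3[[1]]$samples - s1$samples,
               ch3[[2]]$samples - attr(ch3, "song_channels")[[2]]$samples,
               tolerance = 1e-12)
})

test_that("TDOAs recover pure channel shifts to the sample", {
  x <- noise_wave(0.5, seed = 7)
  same <- estimate_tdoas(list(x, x, x))
  expect_equal(same, c(0, 0))
  shifted <- waveform(c(numeric(50), x$samples[1:(length(x$samples) - 50)]),
                      RATE)
  td <- estimate_tdoas(list(x, shifted, x))
  expect_equal(td[1], 50 / RATE, tolerance = 1e-12)
  expect_equal(td[2], 0)
  expect_error(estimate_tdoas(list(x)), "two channels")
})

test_that("trilateration inverts exact TDOAs and centers zero TDOAs", {
  mics <- default_mic_array()
  c_s <- mics$speed_of_sound
  forward <- function(p) {
    d <- function(m) sqrt(sum((c(p, 1.5) - m)^2))
    c(d(mics$positions[2, ]) - d(mics$positions[1, ]),
      d(mics$positions[3, ]) - d(mics$positions[1, ])) / c_s
  }
  est <- trilaterate(forward(c(3, 7)), mics)
  expect_lt(sqrt(sum((est - c(3, 7))^2)), 0.05)

  center <- trilaterate(c(0, 0), mics)
  expect_equal(as.numeric(center), c(5, 5), tolerance = 1e-6)

  # quantized TDOAs (integer samples at 22,050 Hz) stay near-exact
  q <- round(forward(c(-4, 6)) * 22050) / 22050
  est_q <- trilaterate(q, mics)
  expect_lt(sqrt(sum((est_q - c(-4, 6))^2)), 0.5)
})

test_that("noise-free trials localize to within the quantization floor", {
  res <- run_trilat_trials(12, ratio_grid = NULL, seed = 3)
  expect_equal(nrow(res$trials), 12)
  expect_lt(res$summary$mean_error_m[res$summary$ratio == "all"], 0.5)
  # all birds sampled within 10 m of some microphone
  mics <- default_mic_array()$positions
  for (i in 1:12) {
    dd <- sqrt((mics[, 1] - res$trials$true_x[i])^2 +
                 (mics[, 2] - res$trials$true_y[i])^2)
    expect_lte(min(dd), 10)
  }
})

test_that("oracle separation beats the identity baseline at ratio 0.05", {
  id <- run_trilat_trials(10, ratio_grid = 0.05, separator = "identity",
                          seed = 4)
  or <- run_trilat_trials(10, ratio_grid = 0.05, separator = "oracle",
                          seed = 4)
  expect_lt(or$summary$mean_error_m[1], id$summary$mean_error_m[1])
})
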