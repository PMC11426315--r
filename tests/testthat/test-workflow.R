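# End-to-end dataset build, seed fan-out, config I/O, and a miniature
# evaluation battery run.

test_that("seed fan-out is deterministic, stage-separated, and in range", {
  a <- fanout_seed(42, "mixgen", 1)
  expect_identical(a, fanout_seed(42, "mixgen", 1))
  expect_false(a == fanout_seed(42, "mixgen", 2))
  expect_false(a == fanout_seed(42, "cleaning", 1))
  expect_false(a == fanout_seed(43, "mixgen", 1))
  seeds <- vapply(1:500, function(i) fanout_seed(7, "s", i), integer(1))
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 2))
  expect_gt(length(unique(seeds)), 495)
})

make_build_inputs <- function(rate = 22050, master_seed = 5) {
  # two 40-s "recordings": quiet site noise with two planted songs each
  recs <- list(); truths <- list()
  for (r in 1:2) {
    bg <- synth_background(background_spec(
      duration_s = 40, seed = fanout_seed(master_seed, "rec-bg", r)), rate)
    x <- bg$samples * 0.05
    starts <- c(8, 25) + r
    for (st in starts) {
      song <- synth_song(song_spec(
        seed = fanout_seed(master_seed, "rec-song", r * 10 + st)), rate)
      i <- round(st * rate) + seq_along(song$samples)
      x[i] <- x[i] + song$samples * 0.6
    }
    recs[[paste0("rec", r)]] <- waveform(x, rate)
    truths[[r]] <- data.frame(
      start_s = starts, end_s = starts + 1.2, is_target = TRUE)
  }
  score <- do.call(rbind, lapply(1:2, function(r)
    synth_score_table(truths[[r]], duration_s = 40, noise_sd = 0.02,
                      seed = fanout_seed(master_seed, "scores", r),
                      recording_id = paste0("rec", r))))
  list(recordings = recs, score_table = score)
}

test_that("run_dataset_build produces a consistent seeded dataset", {
  inp <- make_build_inputs()
  cfg <- pipeline_config(
    master_seed = 5, output_dir = tempfile("build_"),
    selection = list(k = 4, min_gap_s = 3, target_class = "target",
                     window_len_s = 3, buffer_s = 1.5),
    background = list(window_s = 1, total_s = 12, min_piece_s = 2),
    mixgen = list(n_examples = 2, duration_s = 10, songs_per_min = 12,
                  target_ratio = 0.5, ranges = augmentation_ranges()))
  out <- run_dataset_build(cfg, inp$recordings, inp$score_table)

  expect_gt(length(out$song_bank), 0)
  expect_gt(length(out$bg_bank), 0)
  expect_equal(nrow(out$manifest), 2)
  for (ex in out$examples) {
    expect_identical(ex$mixture$samples,
                     ex$song_stem$samples + ex$background_stem$samples)
    expect_equal(ex$realized_ratio, 0.5, tolerance = 1e-6)
  }
  expect_true(file.exists(file.path(cfg$output_dir, "manifest.jsonl")))
  expect_true(file.exists(file.path(cfg$output_dir, "cleaning_log.csv")))
  # every clip in the song bank is the buffered six-second extract
  expect_true(all(vapply(out$song_bank, function(s)
    abs(duration(s$wave) - 6) < 1e-6, logical(1))))

  # reruns with the same master seed are byte-identical
  cfg2 <- cfg; cfg2$output_dir <- tempfile("build_rerun_")
  out2 <- run_dataset_build(cfg2, inp$recordings, inp$score_table)
  expect_identical(out$examples[[1]]$mixture$samples,
                   out2$examples[[1]]$mixture$samples)
  m1 <- readLines(file.path(cfg$output_dir, "manifest.jsonl"))
  m2 <- readLines(file.path(cfg2$output_dir, "manifest.jsonl"))
  expect_identical(gsub("build_[^\"]*", "", m1),
                   gsub("build_rerun_[^\"]*", "", m2))
})

test_that("an all-negative score table aborts the build with a clear error", {
  inp <- make_build_inputs()
  dead <- inp$score_table
  dead$prob[dead$class == "target"] <- 0
  cfg <- pipeline_config(output_dir = tempfile("build_"),
                         selection = list(k = 4, min_gap_s = 3,
                                          target_class = "target",
                                          window_len_s = 3, buffer_s = 1.5))
  expect_error(run_dataset_build(cfg, inp$recordings, dead),
               "selection stage")
})

test_that("pipeline configs round trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("rate: 22050", "master_seed: 9", "selection:", "  k: 25",
               "mixgen:", "  n_examples: 1"), path)
  cfg <- read_pipeline_config(path)
  expect_equal(cfg$master_seed, 9)
  expect_equal(cfg$selection$k, 25)
  expect_equal(cfg$selection$min_gap_s, 3)     # untouched default
  expect_equal(cfg$mixgen$n_examples, 1)
})

test_that("a miniature evaluation battery runs end to end", {
  out_dir <- tempfile("eval_")
  res <- run_evaluation(out_dir, seed = 3, n_per_cell = 1,
                        ratios = c(0.05, 1), trilat_n = 4, timing_n = 2)
  expect_true(all(c("ratio_sweep", "song_type", "songs_per_min",
                    "doubled_background", "forest_ir", "feature_labeling",
                    "timing", "trilat_identity", "trilat_oracle",
                    "threshold_accuracy") %in% names(res)))
  for (nm in names(res))
    expect_true(file.exists(file.path(out_dir, paste0(nm, ".csv"))))
  expect_true(file.exists(file.path(out_dir, "summary.txt")))
  # oracle separation keeps positive SDR even at the hardest ratio and
  # high SDR at parity
  expect_true(all(res$ratio_sweep$sdr_db > 5))
  expect_gt(max(res$ratio_sweep$sdr_db), 20)
  expect_lte(res$timing$max_abs_us, res$timing$sample_period_us)
})
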