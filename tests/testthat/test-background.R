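# Positive-span masking, the rolling loudness metric, loudest-span mining.

test_that("mask_positive_segments returns the interval complement", {
  rate <- 100
  w <- waveform(seq_len(10 * rate) / 1000, rate)

  whole <- mask_positive_segments(w, data.frame(start_s = numeric(),
                                                end_s = numeric()))
  expect_length(whole, 1)
  expect_identical(whole[[1]]$wave$samples, w$samples)

  cut <- mask_positive_segments(w, data.frame(start_s = 2, end_s = 4))
  expect_length(cut, 2)
  expect_equal(cut[[1]]$offset_s, 0)
  expect_equal(duration(cut[[1]]$wave), 2)
  expect_equal(cut[[2]]$offset_s, 4)
  expect_equal(duration(cut[[2]]$wave), 6)
  expect_identical(c(cut[[1]]$wave$samples, cut[[2]]$wave$samples),
                   w$samples[c(1:(2 * rate), (4 * rate + 1):(10 * rate))])

  # overlapping positives merge rather than error
  m <- mask_positive_segments(w, data.frame(start_s = c(1, 2, 8),
                                            end_s = c(3, 5, 12)))
  expect_length(m, 2)
  expect_equal(m[[2]]$offset_s, 5)
  expect_equal(duration(m[[2]]$wave), 3)

  all_pos <- mask_positive_segments(w, data.frame(start_s = 0, end_s = 10))
  expect_length(all_pos, 0)
})

test_that("loudness metric is rolling-max of rolling-sum of |x|", {
  rate <- 100
  # naive oracle with explicit centered truncated windows
  naive_metric <- function(x, width) {
    n <- length(x)
    hl <- (width - 1) %/% 2; hr <- width - 1 - hl
    rsum <- vapply(seq_len(n), function(i)
      sum(abs(x[max(1, i - hl):min(n, i + hr)])), numeric(1))
    vapply(seq_len(n), function(i)
      max(rsum[max(1, i - hl):min(n, i + hr)]), numeric(1))
  }
  z <- waveform(numeric(3 * rate), rate)
  expect_identical(loudness_profile(z)$metric, numeric(3 * rate))

  set.seed(8)
  x <- rnorm(4 * rate)
  got <- loudness_profile(waveform(x, rate), window_s = 1)$metric
  expect_equal(got, naive_metric(x, rate), tolerance = 1e-9)

  # unit impulse: metric 1 on a ~2-window support, 0 elsewhere
  imp <- numeric(6 * rate)
  imp[3 * rate] <- 1
  m <- loudness_profile(waveform(imp, rate), window_s = 1)$metric
  expect_equal(max(m), 1)
  expect_equal(sum(m == 1), 2 * rate - 1, tolerance = 2)
  expect_true(all(m[m != 1] == 0))

  # constant input: c * window samples away from the edges
  const <- waveform(rep(0.3, 5 * rate), rate)
  mc <- loudness_profile(const, window_s = 1)$metric
  interior <- mc[(rate + 1):(4 * rate)]
  expect_equal(unique(round(interior, 9)), 0.3 * rate)
})

test_that("top_loudest picks the metric argmax region", {
  rate <- 100
  set.seed(3)
  quiet <- rnorm(60 * rate, 0, 0.01)
  quiet[(20 * rate + 1):(30 * rate)] <-
    quiet[(20 * rate + 1):(30 * rate)] + rnorm(10 * rate, 0, 0.5)
  w <- waveform(quiet, rate)
  iv <- top_loudest(w, loudness_profile(w), total_s = 10, min_piece_s = 2)
  expect_equal(nrow(iv), 1)
  expect_lt(abs(iv$start_s - 19.5), 1.5)      # burst plus rolling spread
  expect_lt(abs((iv$end_s - iv$start_s) - 10), 1 + 1e-9)

  # uniform audio: earliest seconds win (tie-break toward earlier time)
  u <- waveform(rep(0.2, 30 * rate), rate)
  ivu <- top_loudest(u, loudness_profile(u), total_s = 6, min_piece_s = 2)
  expect_equal(ivu$start_s[1], 0)
  expect_equal(sum(ivu$end_s - ivu$start_s), 6, tolerance = 1 + 1e-9)

  # total_s >= duration warns and returns everything
  expect_warning(all_iv <- top_loudest(u, loudness_profile(u), total_s = 40),
                 "whole")
  expect_equal(all_iv$end_s, 30)
})

test_that("top_loudest honors the totals and fragment-length invariants", {
  rate <- 50
  set.seed(14)
  for (case in 1:6) {
    x <- rnorm(40 * rate, 0, 0.02)
    # a few loud patches of varying width
    for (p in 1:sample(2:4, 1)) {
      at <- sample(1:(35 * rate), 1)
      len <- sample(c(1, 3, 6), 1) * rate
      x[at:(at + len - 1)] <- x[at:(at + len - 1)] + rnorm(len, 0, 0.6)
    }
    w <- waveform(x, rate)
    prof <- loudness_profile(w, window_s = 1)
    iv <- top_loudest(w, prof, total_s = 8, min_piece_s = 2)
    lens <- iv$end_s - iv$start_s
    expect_true(all(lens >= 2 - 1e-9))       # no fragment under 2 s
    expect_lte(sum(lens), 8 + 1 + 1e-9)       # within one window of total
    expect_gte(sum(lens), 8 - 1 - 1e-9)
    expect_true(all(diff(iv$start_s) > 0))
    if (nrow(iv) > 1) expect_true(all(iv$start_s[-1] >= iv$end_s[-nrow(iv)]))
    # selected region has higher metric than what was left out (allowing
    # merge/min-piece adjustments at the boundaries)
    sel <- logical(length(x))
    for (k in seq_len(nrow(iv)))
      sel[(round(iv$start_s[k] * rate) + 1):round(iv$end_s[k] * rate)] <- TRUE
    expect_gt(mean(prof$metric[sel]), mean(prof$metric[!sel]))
  }
})
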