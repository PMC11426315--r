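# Joint-probability scoring, top-k window selection, buffered extraction.

test_that("joint_score follows the independent product form", {
  expect_equal(joint_score(1.0), 1.0)
  expect_equal(joint_score(0.8, c(noise = 0.5)), 0.40)
  expect_equal(joint_score(0.0, c(a = 0.3, b = 0.9)), 0)
  expect_equal(joint_score(0.9, c(0.1, 0.2)), 0.9 * 0.9 * 0.8)
  expect_error(joint_score(1.2), "\\[0, 1\\]")
  expect_error(joint_score(0.5, c(x = -0.1)), "\\[0, 1\\]")
})

test_that("joint_score is monotone in each argument", {
  set.seed(42)
  for (k in 1:50) {
    p <- runif(1); others <- runif(3)
    base <- joint_score(p, others)
    expect_gte(joint_score(min(p + 0.1, 1), others), base)
    bump <- others; bump[2] <- min(bump[2] + 0.1, 1)
    expect_lte(joint_score(p, bump), base)
  }
})

make_score_df <- function(starts, target, other,
                          rec = "r1") {
  rbind(
    data.frame(recording_id = rec, start_s = starts, class = "target",
               prob = target),
    data.frame(recording_id = rec, start_s = starts, class = "other",
               prob = other))
}

test_that("joint_scores aggregates long tables per window", {
  df <- make_score_df(c(0, 1, 2), target = c(0.9, 0.5, 0.2),
                      other = c(0.1, 0.5, 0.9))
  js <- joint_scores(df)
  expect_equal(js$joint, c(0.9 * 0.9, 0.5 * 0.5, 0.2 * 0.1),
               tolerance = 1e-12)
  expect_equal(js$end_s - js$start_s, rep(3, 3))
})

test_that("rank_and_select keeps top-k with greedy gap suppression", {
  df <- data.frame(recording_id = "r1", start_s = c(0, 10, 20, 30, 40),
                   end_s = c(0, 10, 20, 30, 40) + 3,
                   joint = c(0.1, 0.9, 0.3, 0.7, 0.5))
  top2 <- rank_and_select(df, k = 2)
  expect_equal(top2$joint, c(0.9, 0.7))

  # overlapping 0.9 / 0.8 windows: only the stronger survives
  ov <- data.frame(recording_id = "r1", start_s = c(5, 6),
                   end_s = c(8, 9), joint = c(0.9, 0.8))
  expect_equal(rank_and_select(ov, k = 5, min_gap_s = 3)$start_s, 5)

  # same-score tie: earlier start wins
  tie <- data.frame(recording_id = "r1", start_s = c(12, 4),
                    end_s = c(15, 7), joint = c(0.6, 0.6))
  expect_equal(rank_and_select(tie, k = 1)$start_s, 4)

  # different recordings never suppress each other
  two <- data.frame(recording_id = c("a", "b"), start_s = c(0, 1),
                    end_s = c(3, 4), joint = c(0.9, 0.8))
  expect_equal(nrow(rank_and_select(two, k = 5, min_gap_s = 3)), 2)

  expect_equal(nrow(rank_and_select(df[0, ], k = 3)), 0)
})

test_that("rank_and_select matches a brute-force greedy trace", {
  set.seed(99)
  for (case in 1:20) {
    n <- sample(3:12, 1)
    df <- data.frame(recording_id = sample(c("a", "b"), n, replace = TRUE),
                     start_s = sample(0:30, n),
                     joint = round(runif(n), 2))
    df$end_s <- df$start_s + 3
    k <- sample(1:5, 1)
    got <- rank_and_select(df, k, min_gap_s = 3)
    # independent trace: sort, then scan keeping gap-compatible windows
    o <- order(-df$joint, df$start_s, df$recording_id)
    kept <- list()
    for (i in o) {
      ok <- TRUE
      for (j in seq_along(kept)) {
        prev <- kept[[j]]
        if (prev$recording_id == df$recording_id[i] &&
            abs(prev$start_s - df$start_s[i]) < 3) ok <- FALSE
      }
      if (ok) kept[[length(kept) + 1]] <- df[i, ]
      if (length(kept) >= k) break
    }
    want <- do.call(rbind, kept)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$joint, want$joint)
    expect_true(all(diff(got$joint) <= 0))
  }
})

test_that("extract_with_buffer pads to the exact buffered length", {
  rate <- 1000
  w <- waveform(seq_len(10 * rate) / (10 * rate), rate)
  clip <- extract_with_buffer(w, 4, 7, buffer_s = 1.5)
  expect_equal(duration(clip), 6)           # 3-s window + 2 * 1.5 s
  expect_identical(clip$samples, w$samples[(2.5 * rate + 1):(8.5 * rate)])

  nobuf <- extract_with_buffer(w, 4, 7, buffer_s = 0)
  expect_identical(nobuf$samples, w$samples[(4 * rate + 1):(7 * rate)])

  edge <- extract_with_buffer(w, 0, 3, buffer_s = 1.5)
  expect_equal(duration(edge), 6)
  expect_identical(edge$samples[1:(1.5 * rate)], numeric(1.5 * rate))
})

test_that("score tables round trip through CSV and JSON-lines", {
  df <- make_score_df(c(0, 1), target = c(0.9, 0.1), other = c(0.2, 0.3))
  csv <- tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE)
  expect_equal(read_score_table(csv)$prob, df$prob)

  jl <- tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(df)), function(i)
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), character(1)), jl)
  expect_equal(read_score_table(jl)$prob, df$prob)
})
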