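# Candidate-segment selection from sliding-window detector scores. A
# detector (BirdNET for the target species, a general audio tagger for
# everything else) is run externally over each recording with a 3-s window
# advanced 1 s at a time; this module consumes its per-window class
# probabilities, ranks windows by the joint probability of "target present
# and nothing else present", and extracts the top windows with a buffer.

#' Joint probability of target-only windows
#'
#' For one window with target probability `p_t` and other-class
#' probabilities `p_1..p_m`, the joint score is `p_t * prod(1 - p_j)`:
#' the probability that the window contains the target species and none of
#' the other categories, treating classes as independent.
#'
#' @param target_prob probability the window contains the target class.
#' @param other_probs numeric vector (possibly named, possibly empty) of
#'   other-class probabilities.
#' @return joint probability in `[0, 1]`.
#' @export
joint_score <- function(target_prob, other_probs = numeric()) {
  probs <- c(target_prob, other_probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  target_prob * prod(1 - other_probs)
}

#' Joint scores for a long-format score table
#'
#' @param scores data frame with columns `recording_id`, `start_s`, `class`,
#'   `prob` — one row per (window, class), the native output shape of
#'   window-classifier score dumps.
#' @param target_class name of the target class (default `"target"`).
#' @param window_len_s window length in seconds (default 3, the detector's
#'   analysis window).
#' @return data frame with one row per window: `recording_id`, `start_s`,
#'   `end_s`, `joint`.
#' @export
joint_scores <- function(scores, target_class = "target", window_len_s = 3) {
  need <- c("recording_id", "start_s", "class", "prob")
  if (!all(need %in% names(scores)))
    stop("score table needs columns: ", paste(need, collapse = ", "))
  if (any(scores$prob < 0 | scores$prob > 1))
    stop("all probabilities must lie in [0, 1]")
  key <- interaction(scores$recording_id, scores$start_s, drop = TRUE)
  is_t <- scores$class == target_class
  tgt <- tapply(ifelse(is_t, scores$prob, NA_real_), key,
                function(p) if (all(is.na(p))) 0 else max(p, na.rm = TRUE))
  oth <- tapply(ifelse(is_t, NA_real_, log1p(-pmin(scores$prob, 1 - 1e-15))),
                key, function(lp) sum(lp, na.rm = TRUE))
  ids <- tapply(as.character(scores$recording_id), key, `[`, 1L)
  sts <- tapply(scores$start_s, key, `[`, 1L)
  out <- data.frame(recording_id = as.vector(ids),
                    start_s = as.vector(sts),
                    end_s = as.vector(sts) + window_len_s,
                    joint = as.vector(tgt) * exp(as.vector(oth)),
                    stringsAsFactors = FALSE)
  out[order(out$recording_id, out$start_s), , drop = FALSE]
}

#' Rank windows and select the top k with overlap suppression
#'
#' Sorts windows by joint score (descending; ties broken by earlier start,
#' then recording id) and greedily keeps windows, skipping any whose start
#' lies within `min_gap_s` of an already-kept window from the same
#' recording. This de-duplicates overlapping windows of one song before
#' extraction.
#'
#' @param joint data frame from [joint_scores()] (columns `recording_id`,
#'   `start_s`, `end_s`, `joint`).
#' @param k maximum number of segments to keep (the workflow default used
#'   in the field campaign was 1500).
#' @param min_gap_s minimum start-to-start gap within a recording
#'   (default 3 s, one window length).
#' @return data frame of selected windows sorted by decreasing `joint`.
#' @export
rank_and_select <- function(joint, k, min_gap_s = 3) {
  if (k < 1) stop("k must be >= 1")
  if (!nrow(joint)) return(joint)
  o <- order(-joint$joint, joint$start_s, joint$recording_id)
  joint <- joint[o, , drop = FALSE]
  kept <- integer(0)
  starts_by_rec <- list()
  for (i in seq_len(nrow(joint))) {
    rec <- as.character(joint$recording_id[i])
    st <- joint$start_s[i]
    prev <- starts_by_rec[[rec]]
    if (!is.null(prev) && any(abs(prev - st) < min_gap_s)) next
    kept <- c(kept, i)
    starts_by_rec[[rec]] <- c(prev, st)
    if (length(kept) >= k) break
  }
  out <- joint[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a selected window with a buffer
#'
#' Slices `[start - buffer_s, end + buffer_s)` from the recording,
#' zero-padding at the recording edges so the result always has exactly
#' `window length + 2 * buffer_s` seconds (a 3-s window with the default
#' 1.5-s buffer yields a 6-s song clip).
#'
#' @param w the source recording, a [waveform()].
#' @param start_s,end_s the selected window, in seconds.
#' @param buffer_s buffer before and after (default 1.5 s).
#' @return a [waveform()].
#' @export
extract_with_buffer <- function(w, start_s, end_s, buffer_s = 1.5) {
  if (buffer_s < 0) stop("buffer_s must be >= 0")
  slice_wave(w, list(start_s = start_s - buffer_s, end_s = end_s + buffer_s),
             pad = TRUE)
}

#' Read a score table from CSV or JSON-lines
#'
#' @param path file path; `.csv` or `.jsonl`/`.json` (one object per line).
#' @return data frame with columns `recording_id`, `start_s`, `class`, `prob`.
#' @export
read_score_table <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    tbl <- jsonlite::stream_in(file(path), verbose = FALSE)
  }
  need <- c("recording_id", "start_s", "class", "prob")
  if (!all(need %in% names(tbl)))
    stop("score table needs columns: ", paste(need, collapse = ", "))
  tbl[, need]
}
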