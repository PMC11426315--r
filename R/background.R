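# Background-audio mining. Detector-positive spans are cut out of raw site
# recordings; each remaining hour is condensed to its loudest five minutes
# using a rolling-sum-then-rolling-max loudness metric, which keeps the
# interesting events (cars, voices, other species) and drops plain hiss.

#' Remove detector-positive spans from a recording
#'
#' Cuts the listed intervals out and returns the maximal kept pieces with
#' their original offsets. Overlapping or adjacent positive intervals are
#' merged before cutting.
#'
#' @param w a [waveform()].
#' @param positives data frame with `start_s`, `end_s` columns (or a list
#'   of [time_interval()]s).
#' @return list of `list(offset_s = , wave = )`, earliest first; empty list
#'   if the positives cover everything.
#' @export
mask_positive_segments <- function(w, positives) {
  stopifnot_waveform(w)
  n <- length(w$samples)
  iv <- normalize_intervals(positives)
  if (!nrow(iv))
    return(list(list(offset_s = 0, wave = w)))
  i0 <- pmax(0L, pmin(n, round(iv$start_s * w$rate)))
  i1 <- pmax(0L, pmin(n, round(iv$end_s * w$rate)))
  keep_from <- c(0L, i1)
  keep_to <- c(i0, n)
  out <- list()
  for (k in seq_along(keep_from)) {
    if (keep_to[k] > keep_from[k]) {
      out[[length(out) + 1L]] <- list(
        offset_s = keep_from[k] / w$rate,
        wave = waveform(w$samples[(keep_from[k] + 1L):keep_to[k]], w$rate))
    }
  }
  out
}

# sort + merge overlapping/adjacent [start_s, end_s) intervals
normalize_intervals <- function(positives) {
  if (is.data.frame(positives)) {
    st <- positives$start_s; en <- positives$end_s
  } else {
    st <- vapply(positives, `[[`, numeric(1), "start_s")
    en <- vapply(positives, `[[`, numeric(1), "end_s")
  }
  if (!length(st)) return(data.frame(start_s = numeric(), end_s = numeric()))
  o <- order(st)
  st <- st[o]; en <- en[o]
  ms <- st[1]; me <- en[1]
  out_s <- numeric(); out_e <- numeric()
  for (k in seq_along(st)[-1]) {
    if (st[k] <= me) me <- max(me, en[k])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- st[k]; me <- en[k] }
  }
  data.frame(start_s = c(out_s, ms), end_s = c(out_e, me))
}

#' Rolling loudness metric
#'
#' A one-second (by default) centered rolling summation over `abs(samples)`
#' smooths the waveform; a rolling maximum of the same width then spreads
#' each loud event over its neighborhood so selection does not fragment it
#' into slivers. Windows are truncated at the clip edges.
#'
#' @param w a [waveform()].
#' @param window_s rolling window in seconds (default 1).
#' @return list with `metric` (per-sample nonnegative values, same length
#'   as the audio) and `window_s`.
#' @export
loudness_profile <- function(w, window_s = 1) {
  stopifnot_waveform(w)
  if (!length(w$samples)) stop("empty audio")
  if (window_s <= 0) stop("window_s must be > 0")
  width <- max(1L, round(window_s * w$rate))
  m <- rolling_max(rolling_sum(abs(w$samples), width), width)
  list(metric = m, window_s = window_s)
}

#' Select the loudest spans of a recording
#'
#' Greedily marks the highest-metric samples until `total_s` seconds are
#' covered, merges adjacent selections into intervals, discards fragments
#' shorter than `min_piece_s`, and refills from the remaining eligible
#' samples until the total is met (or nothing eligible remains). Ties in
#' the metric are broken toward earlier times.
#'
#' @param w a [waveform()].
#' @param profile result of [loudness_profile()].
#' @param total_s total duration to keep (default 300 s — five minutes per
#'   hour of raw audio).
#' @param min_piece_s minimum fragment length (default 2 s).
#' @return data frame of disjoint sorted intervals (`start_s`, `end_s`).
#' @export
top_loudest <- function(w, profile, total_s = 300, min_piece_s = 2) {
  stopifnot_waveform(w)
  n <- length(w$samples)
  rate <- w$rate
  if (total_s * rate >= n) {
    warning("total_s >= recording duration; returning the whole recording")
    return(data.frame(start_s = 0, end_s = n / rate))
  }
  metric <- profile$metric
  need <- round(total_s * rate)
  min_len <- round(min_piece_s * rate)
  selected <- logical(n)
  eligible <- rep(TRUE, n)
  # quantize so cumulative-sum float noise cannot break exact ties; ties
  # then resolve toward earlier samples
  ord <- order(-signif(metric, 10), seq_len(n))
  repeat {
    deficit <- need - sum(selected)
    if (deficit <= 0) break
    cand <- ord[eligible[ord] & !selected[ord]]
    if (!length(cand)) break
    take <- cand[seq_len(min(deficit, length(cand)))]
    selected[take] <- TRUE
    # drop runs shorter than min_piece_s and bar their samples from refill
    r <- rle(selected)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$values & r$lengths < min_len)
    if (!length(short)) next
    for (k in short) {
      idx <- starts[k]:ends[k]
      selected[idx] <- FALSE
      eligible[idx] <- FALSE
    }
  }
  # the greedy refill can stall when every remaining high-metric sample
  # would form a sub-min_piece fragment; meet the total by growing the
  # kept runs outward (extension never creates a short piece)
  deficit <- need - sum(selected)
  if (deficit > 0 && !any(selected)) {
    cs <- c(0, cumsum(metric))
    block <- cs[(min_len + 1):(n + 1)] - cs[1:(n - min_len + 1)]
    b0 <- which.max(block)
    selected[b0:(b0 + min_len - 1L)] <- TRUE
    deficit <- need - sum(selected)
  }
  while (deficit > 0) {
    r <- rle(selected)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ks <- which(r$values)
    cand <- unique(c(starts[ks] - 1L, ends[ks] + 1L))
    cand <- cand[cand >= 1L & cand <= n & !selected[cand]]
    if (!length(cand)) break
    take <- min(length(cand), deficit)
    best <- cand[order(-signif(metric[cand], 10), cand)][seq_len(take)]
    selected[best] <- TRUE
    deficit <- deficit - take
  }
  r <- rle(selected)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_s = (starts[keep] - 1L) / rate, end_s = ends[keep] / rate)
}
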