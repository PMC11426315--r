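# Automated minimum/maximum song-frequency labeling: crop the clip around
# its energy center, compute a normalized log-magnitude spectrogram, run
# Canny edge detection, and read the band edges off the lowest and highest
# edge pixels. The same operator measures ground truth on the clean song,
# "before" on the mixture, and "after" on the separated estimate.

#' Configuration for band-edge labeling
#'
#' @param crop_s analysis crop length in seconds (default 3).
#' @param smooth_window_s moving-average window, in seconds, used to find
#'   the clip's energy center (default 0.5; zero-padded 'same' alignment).
#' @param nfft,hop spectrogram frame and hop in samples.
#' @param db_floor spectrogram floor in dB below the peak (default -25;
#'   a shallow floor keeps the band-edge measurement on the sounded part
#'   of the song and below the window's spectral-leakage skirt).
#' @param canny_sigma Gaussian blur in pixels for the edge detector.
#' @param canny_low,canny_high relative hysteresis thresholds.
#' @param min_freq_hz edge pixels below this frequency are ignored, which
#'   suppresses residual low-frequency rumble edges (default 500; set to 0
#'   to disable, e.g. on oracle-separated input).
#' @return an `edge_config` list.
#' @export
edge_config <- function(crop_s = 3, smooth_window_s = 0.5,
                        nfft = 1024, hop = 256, db_floor = -25,
                        canny_sigma = 1, canny_low = 0.1, canny_high = 0.3,
                        min_freq_hz = 500) {
  if (bitwAnd(nfft, nfft - 1L) != 0) stop("nfft must be a power of two")
  structure(as.list(environment()), class = "edge_config")
}

#' Crop a clip around its energy center
#'
#' The center is the argmax of the moving average of squared samples
#' (window `smooth_window_s`, zero-padded 'same' alignment); ties resolve
#' toward the clip middle. The crop is clamped so `crop_s` seconds fit
#' inside the clip; clips shorter than the crop are returned whole with a
#' warning.
#'
#' @param w a [waveform()].
#' @param cfg an [edge_config()].
#' @return a [waveform()] of `crop_s` seconds.
#' @export
center_trim <- function(w, cfg = edge_config()) {
  stopifnot_waveform(w)
  n <- length(w$samples)
  nc <- round(cfg$crop_s * w$rate)
  if (nc >= n) {
    if (nc > n) warning("clip shorter than crop_s; returning whole clip")
    return(w)
  }
  width <- max(1L, round(cfg$smooth_window_s * w$rate))
  ma <- rolling_sum(w$samples^2, width)   # zero-padded 'same' sum
  cands <- which(ma == max(ma))
  center <- cands[which.min(abs(cands - (n + 1) / 2))]
  half <- nc %/% 2
  c0 <- min(max(center - half, 0L), n - nc)
  waveform(w$samples[(c0 + 1L):(c0 + nc)], w$rate)
}

#' Label the minimum and maximum frequency of a song clip
#'
#' Normalized log-magnitude spectrogram of the energy-centered crop, Canny
#' edge map, then the band edges are the lowest and highest frequency bins
#' containing any edge pixel (at or above `min_freq_hz`).
#'
#' @param w a [waveform()].
#' @param cfg an [edge_config()].
#' @return list with `f_min_hz`, `f_max_hz`.
#' @export
label_band_edges <- function(w, cfg = edge_config()) {
  w <- center_trim(w, cfg)
  if (all(w$samples == 0)) stop("silent clip: no band edges")
  st <- stft(w, cfg$nfft, cfg$hop)
  mag_db <- 20 * log10(Mod(st$S) + 1e-12)
  mag_db <- pmax(mag_db - max(mag_db), cfg$db_floor)
  img <- (mag_db - cfg$db_floor) / (-cfg$db_floor)    # [0, 1]
  edges <- canny_edges(img, cfg$canny_sigma, cfg$canny_low, cfg$canny_high)
  freqs <- stft_freqs(cfg$nfft, w$rate)
  rows <- which(rowSums(edges) > 0)
  rows <- rows[freqs[rows] >= cfg$min_freq_hz]
  if (!length(rows)) stop("no edge pixels found: no detectable signal")
  list(f_min_hz = freqs[min(rows)], f_max_hz = freqs[max(rows)])
}

#' Build single-song labeling trials over a ratio grid
#'
#' Each trial is a clean synthetic song placed in the middle of a short
#' band-limited background bed at a prescribed birdsong-background ratio;
#' the trial carries the stems, so both the identity baseline and the
#' oracle separator can be evaluated on it.
#'
#' @param ratios birdsong-background ratios to cover; trials cycle through
#'   them (default the standard sweep grid).
#' @param n_per_ratio trials per ratio value (default 12).
#' @param rate sampling rate (default 22050).
#' @param duration_s trial clip duration (default 6 s).
#' @param bg_max_freq_hz background brick-wall limit; the default 2000 Hz
#'   keeps the background clear of the song band so the oracle mask is
#'   near-ideal (band-disjoint fixtures).
#' @param seed integer master seed.
#' @return list of trials: `clean`, `mixture`, `song_stem`,
#'   `background_stem` ([waveform()]s) plus `ratio`.
#' @export
make_feature_trials <- function(ratios = c(0.01, 0.02, 0.05, 0.1, 0.2,
                                           0.5, 1, 1.5, 2),
                                n_per_ratio = 12, rate = 22050,
                                duration_s = 6, bg_max_freq_hz = 2000,
                                seed = 1) {
  trials <- list()
  idx <- 0
  for (r in ratios) for (k in seq_len(n_per_ratio)) {
    idx <- idx + 1
    s_seed <- fanout_seed(seed, "feature-song", idx)
    b_seed <- fanout_seed(seed, "feature-bg", idx)
    song <- with_seed(s_seed, synth_song(song_spec(
      song_type = sample(c("A", "B"), 1),
      peak_freq_hz = stats::runif(1, 4500, 5500),
      has_hook = stats::runif(1) < 0.7, seed = s_seed), rate))
    bg <- synth_background(background_spec(
      duration_s = duration_s, max_freq_hz = bg_max_freq_hz,
      tonal_components = list(c(0.4 * bg_max_freq_hz, 0),
                              c(0.8 * bg_max_freq_hz, -3)),
      transient_rate_per_min = 0, seed = b_seed), rate)
    n <- length(bg$samples); m <- length(song$samples)
    at <- (n - m) %/% 2
    stem <- numeric(n)
    stem[at + seq_len(m)] <- song$samples
    stem <- stem * (r / (rms(stem) / rms(bg$samples)))
    trials[[idx]] <- list(
      clean = waveform(stem, rate),
      song_stem = waveform(stem, rate),
      background_stem = bg,
      mixture = waveform(stem + bg$samples, rate),
      ratio = r)
  }
  trials
}

#' Before/after frequency-labeling error study
#'
#' Measures ground-truth band edges on each trial's clean song, then
#' relabels the raw mixture ("before") and the separated song estimate
#' ("after") and reports the mean absolute percentage error per ratio for
#' both edges, with 90% normal-approximation confidence half-widths.
#'
#' @param trials list from [make_feature_trials()] (or compatible).
#' @param cfg an [edge_config()].
#' @param after one of `"oracle"` (chunked oracle ratio mask, the default)
#'   or `"identity"`, or a function `f(trial)` returning a separator.
#' @param plan [chunk_plan()] used when the trial exceeds one window.
#' @return data frame: one row per (ratio, edge) with before/after MAPE
#'   and confidence half-widths and the trial count.
#' @export
feature_error_study <- function(trials, cfg = edge_config(),
                                after = "oracle", plan = chunk_plan()) {
  sep_factory <- if (is.function(after)) after
    else if (identical(after, "identity")) function(trial) separate_identity
    else function(trial) make_oracle_separator(trial$song_stem,
                                               trial$background_stem)
  rows <- lapply(trials, function(tr) {
    truth <- label_band_edges(tr$clean, cfg)
    before <- tryCatch(label_band_edges(tr$mixture, cfg),
                       error = function(e) list(f_min_hz = NA, f_max_hz = NA))
    est <- chunked_separate(tr$mixture, sep_factory(tr), plan)
    aft <- tryCatch(label_band_edges(est$song_est, cfg),
                    error = function(e) list(f_min_hz = NA, f_max_hz = NA))
    data.frame(ratio = tr$ratio,
               truth_min = truth$f_min_hz, truth_max = truth$f_max_hz,
               before_min = before$f_min_hz, before_max = before$f_max_hz,
               after_min = aft$f_min_hz, after_max = aft$f_max_hz)
  })
  per <- do.call(rbind, rows)
  out <- list()
  for (r in sort(unique(per$ratio))) for (edge in c("min", "max")) {
    d <- per[per$ratio == r, ]
    tv <- d[[paste0("truth_", edge)]]
    ape <- function(col) 100 * abs(d[[col]] - tv) / tv
    ba <- ape(paste0("before_", edge)); aa <- ape(paste0("after_", edge))
    out[[length(out) + 1L]] <- data.frame(
      ratio = r, edge = edge, n = nrow(d),
      before_mape = mean(ba, na.rm = TRUE), before_ci90 = ci90_halfwidth(ba),
      after_mape = mean(aa, na.rm = TRUE), after_ci90 = ci90_halfwidth(aa))
  }
  do.call(rbind, out)
}
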