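# The separator contract and chunked inference. A separator is any
# function `f(mixture_waveform, t0 = 0)` returning a `separation_estimate`
# (song_est + background_est at the mixture's length and rate); `t0` is
# the chunk's offset in the full signal, which lets oracle separators look
# up the matching span of the ground-truth stems. No trained network ships
# with the package — the oracle time-frequency ratio mask is the
# upper-bound stand-in, and the identity separator is the no-separation
# baseline for before/after comparisons.

separation_estimate <- function(song_est, background_est) {
  structure(list(song_est = song_est, background_est = background_est),
            class = "separation_estimate")
}

#' Identity (no-op) separator
#'
#' Returns the mixture unchanged as the song estimate and silence as the
#' background estimate: the "before separation" baseline.
#'
#' @param mixture a [waveform()].
#' @param t0 chunk offset in seconds (ignored).
#' @return a `separation_estimate`.
#' @export
separate_identity <- function(mixture, t0 = 0) {
  separation_estimate(mixture,
                      waveform(numeric(length(mixture$samples)),
                               mixture$rate))
}

#' Oracle time-frequency ratio-mask separation
#'
#' Builds the ideal ratio mask `|S| / (|S| + |B| + eps)` from the
#' ground-truth stems on an STFT grid and applies it (and its complement)
#' to the mixture. The two estimates sum back to the mixture within STFT
#' reconstruction tolerance. This is the performance ceiling a trained
#' mask-based separator could reach.
#'
#' @param mixture a [waveform()].
#' @param true_song,true_background ground-truth stems, same length as the
#'   mixture.
#' @param nfft,hop STFT parameters (defaults 1024 / 256).
#' @return a `separation_estimate`.
#' @export
separate_oracle_ratio_mask <- function(mixture, true_song, true_background,
                                       nfft = 1024, hop = 256) {
  n <- length(mixture$samples)
  if (length(true_song$samples) != n || length(true_background$samples) != n)
    stop("stems and mixture must have equal length")
  sx <- stft(mixture, nfft, hop)
  ss <- Mod(stft(true_song, nfft, hop)$S)
  sb <- Mod(stft(true_background, nfft, hop)$S)
  mask <- ss / (ss + sb + 1e-12)
  st_song <- sx; st_song$S <- sx$S * mask
  st_bg <- sx; st_bg$S <- sx$S * (1 - mask)
  separation_estimate(waveform(istft(st_song), mixture$rate),
                      waveform(istft(st_bg), mixture$rate))
}

#' Make a plug-in oracle separator for chunked inference
#'
#' Closes over full-length ground-truth stems; when [chunked_separate()]
#' hands it a chunk at offset `t0`, it slices the matching span of the
#' stems and applies the oracle ratio mask.
#'
#' @param true_song,true_background full-length ground-truth stems.
#' @param nfft,hop STFT parameters.
#' @return a separator function `f(mixture, t0 = 0)`.
#' @export
make_oracle_separator <- function(true_song, true_background,
                                  nfft = 1024, hop = 256) {
  force(true_song); force(true_background)
  function(mixture, t0 = 0) {
    iv <- list(start_s = t0, end_s = t0 + duration(mixture))
    separate_oracle_ratio_mask(
      mixture,
      slice_wave(true_song, iv, pad = TRUE),
      slice_wave(true_background, iv, pad = TRUE),
      nfft, hop)
  }
}

#' Chunk plan for long-input inference
#'
#' @param window_s chunk length in seconds (default 3, the model input
#'   size).
#' @param overlap_s overlap between consecutive chunks (default 1).
#' @param crossfade_s crossfade used to merge adjacent chunk outputs,
#'   centered within the overlap (default 0.5).
#' @return a `chunk_plan` list.
#' @export
chunk_plan <- function(window_s = 3, overlap_s = 1, crossfade_s = 0.5) {
  if (!(crossfade_s > 0 && crossfade_s <= overlap_s && overlap_s < window_s))
    stop("need 0 < crossfade_s <= overlap_s < window_s")
  structure(list(window_s = window_s, overlap_s = overlap_s,
                 crossfade_s = crossfade_s), class = "chunk_plan")
}

# chunk start samples: every (window - overlap), plus a right-aligned tail
# chunk when the stride grid does not reach the end
chunk_starts <- function(n, wl, hop) {
  if (n <= wl) return(0L)
  starts <- as.integer(seq.int(0L, n - wl, by = hop))
  if (utils::tail(starts, 1) + wl < n)
    starts <- c(starts, as.integer(n - wl))
  starts
}

#' Separate a long input in overlapping chunks with crossfade merging
#'
#' Splits the mixture into `window_s` chunks advanced by
#' `window_s - overlap_s`, runs the separator on each, and merges adjacent
#' outputs with a linear crossfade of `crossfade_s` centered within each
#' overlap; the outer margins of the overlap are taken wholly from the
#' earlier/later chunk. The merge weights form a partition of unity, so an
#' identity separator reproduces the input exactly — the property behind
#' the timing-preservation guarantee. Inputs no longer than one window are
#' passed through in a single call.
#'
#' @param mixture a [waveform()].
#' @param separator a separator function `f(waveform, t0)`.
#' @param plan a [chunk_plan()].
#' @return a `separation_estimate` with full-length estimates.
#' @export
chunked_separate <- function(mixture, separator, plan = chunk_plan()) {
  stopifnot_waveform(mixture)
  rate <- mixture$rate
  n <- length(mixture$samples)
  wl <- round(plan$window_s * rate)
  hop <- wl - round(plan$overlap_s * rate)
  if (n <= wl) return(separator(mixture, 0))
  starts <- chunk_starts(n, wl, hop)
  nfade <- round(plan$crossfade_s * rate)
  song <- numeric(n); bg <- numeric(n); wsum <- numeric(n)
  # per-chunk merge weights: 1 inside, crossfade ramps at shared overlaps
  weights <- lapply(seq_along(starts), function(k) rep(1, wl))
  for (k in seq_len(length(starts) - 1L)) {
    ov0 <- starts[k + 1L]            # overlap = [ov0, starts[k] + wl)
    ov_len <- starts[k] + wl - ov0
    c0 <- ov0 + floor((ov_len - nfade) / 2)   # crossfade start (0-based)
    ramp <- (seq_len(nfade) - 0.5) / nfade
    # earlier chunk: 1 up to c0, ramp down, 0 after
    i_early <- (c0 - starts[k]) + seq_len(nfade)
    weights[[k]][i_early] <- 1 - ramp
    if (max(i_early) < wl) weights[[k]][(max(i_early) + 1L):wl] <- 0
    # later chunk: 0 before c0, ramp up
    i_late <- (c0 - starts[k + 1L]) + seq_len(nfade)
    if (min(i_late) > 1) weights[[k + 1L]][seq_len(min(i_late) - 1L)] <- 0
    weights[[k + 1L]][i_late] <- ramp
  }
  for (k in seq_along(starts)) {
    idx <- starts[k] + seq_len(wl)
    chunk <- waveform(mixture$samples[idx], rate)
    est <- separator(chunk, starts[k] / rate)
    wk <- weights[[k]]
    song[idx] <- song[idx] + est$song_est$samples * wk
    bg[idx] <- bg[idx] + est$background_est$samples * wk
    wsum[idx] <- wsum[idx] + wk
  }
  if (max(abs(wsum - 1)) > 1e-9)
    stop("internal error: merge weights do not form a partition of unity")
  separation_estimate(waveform(song, rate), waveform(bg, rate))
}
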