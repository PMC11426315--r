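# The birdsong cleaning chain applied to every extracted candidate clip:
# zero-phase Butterworth high-pass (drops road rumble and wind below the
# song band), peak normalization to a common level, and stationary spectral
# gating noise reduction. A birdsong-background-ratio screen then discards
# clips whose song is buried under the residual background.

#' Cleaning-chain configuration
#'
#' @param hp_cutoff_hz high-pass cutoff in Hz (default 2000, below the
#'   warbler song band which sits roughly at 3-8 kHz).
#' @param hp_order Butterworth order (default 5).
#' @param target_peak_db normalization target in dBFS (default -1).
#' @param gate_nfft,gate_hop STFT frame and hop in samples for the gate.
#' @param gate_threshold_db gate opens this many dB above the noise floor
#'   (default 6).
#' @param gate_reduction_db attenuation applied to gated bins (default 30).
#' @param noise_quantile fraction of quietest frames used to estimate the
#'   stationary per-frequency noise floor when no explicit noise sample is
#'   given (default 0.10).
#' @return a `cleaning_config` list.
#' @export
cleaning_config <- function(hp_cutoff_hz = 2000, hp_order = 5,
                            target_peak_db = -1,
                            gate_nfft = 1024, gate_hop = 256,
                            gate_threshold_db = 6, gate_reduction_db = 30,
                            noise_quantile = 0.10) {
  if (hp_cutoff_hz <= 0) stop("hp_cutoff_hz must be > 0")
  if (hp_order < 1) stop("hp_order must be >= 1")
  if (gate_threshold_db <= 0) stop("gate_threshold_db must be > 0")
  if (bitwAnd(gate_nfft, gate_nfft - 1L) != 0)
    stop("gate_nfft must be a power of two")
  structure(list(hp_cutoff_hz = hp_cutoff_hz, hp_order = hp_order,
                 target_peak_db = target_peak_db,
                 gate_nfft = gate_nfft, gate_hop = gate_hop,
                 gate_threshold_db = gate_threshold_db,
                 gate_reduction_db = gate_reduction_db,
                 noise_quantile = noise_quantile),
            class = "cleaning_config")
}

#' Zero-phase Butterworth high-pass filter
#'
#' Applies the Butterworth high-pass forward and backward (`filtfilt`), so
#' phase is preserved and the magnitude response is squared: a tone exactly
#' at the cutoff is attenuated 6 dB rather than the single-pass 3 dB.
#'
#' @param w a [waveform()].
#' @param cfg a [cleaning_config()].
#' @return filtered [waveform()] of the same length.
#' @export
highpass <- function(w, cfg = cleaning_config()) {
  stopifnot_waveform(w)
  nyq <- w$rate / 2
  if (cfg$hp_cutoff_hz >= nyq) stop("cutoff must be below Nyquist")
  bf <- signal::butter(cfg$hp_order, cfg$hp_cutoff_hz / nyq, type = "high")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  x <- w$samples
  n <- length(x)
  pad <- min(n - 1L, max(32L, round(3 * w$rate / cfg$hp_cutoff_hz *
                                      cfg$hp_order)))
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
  waveform(y[(pad + 1L):(pad + n)], w$rate)
}

#' Normalize peak amplitude to a target level
#'
#' Pure gain: scales so that [peak_dbfs()] equals `target_peak_db`
#' (default -1 dBFS, leaving 1 dB of headroom before clipping).
#'
#' @param w a [waveform()].
#' @param target_peak_db target peak in dBFS.
#' @return scaled [waveform()].
#' @export
normalize_peak <- function(w, target_peak_db = -1) {
  stopifnot_waveform(w)
  p <- max(abs(w$samples))
  if (p == 0) stop("cannot normalize silent audio")
  waveform(w$samples * db_to_amp(target_peak_db) / p, w$rate)
}

#' Stationary spectral gating noise reduction
#'
#' Estimates a per-frequency stationary noise floor — from `noise_sample`
#' if supplied, otherwise from the quietest fraction of the input's own
#' frames — and attenuates time-frequency bins that do not exceed the floor
#' by `gate_threshold_db`. The binary gate is softened by a 3 x 3
#' frame-by-bin smoothing of the mask before resynthesis, which avoids
#' musical-noise artifacts at gate edges.
#'
#' @param w a [waveform()] longer than one STFT frame.
#' @param cfg a [cleaning_config()].
#' @param noise_sample optional [waveform()] of background-only audio from
#'   which to estimate the floor.
#' @return gated [waveform()], same length as the input.
#' @export
spectral_gate <- function(w, cfg = cleaning_config(), noise_sample = NULL) {
  stopifnot_waveform(w)
  if (length(w$samples) < cfg$gate_nfft)
    stop("input shorter than one gate frame")
  if (all(w$samples == 0)) return(w)
  st <- stft(w, cfg$gate_nfft, cfg$gate_hop)
  mag <- Mod(st$S)
  if (!is.null(noise_sample)) {
    stn <- stft(noise_sample, cfg$gate_nfft, cfg$gate_hop)
    floor_mag <- rowMeans(Mod(stn$S))
  } else {
    # restrict the floor estimate to frames fully inside the signal (the
    # transform pads both ends with silence)
    starts <- (seq_len(ncol(mag)) - 1L) * st$hop
    inside <- which(starts >= st$pad & starts + st$nfft <= st$pad + st$n)
    if (!length(inside)) inside <- seq_len(ncol(mag))
    frame_pow <- colMeans(mag[, inside, drop = FALSE]^2)
    nq <- max(1L, ceiling(cfg$noise_quantile * length(inside)))
    quiet <- inside[order(frame_pow)[seq_len(nq)]]
    floor_mag <- rowMeans(mag[, quiet, drop = FALSE])
  }
  thresh <- floor_mag * db_to_amp(cfg$gate_threshold_db)
  gate <- (mag > thresh) * 1
  gate <- smooth_mask_3x3(gate)
  gain_floor <- db_to_amp(-cfg$gate_reduction_db)
  mask <- gain_floor + (1 - gain_floor) * gate
  st$S <- st$S * mask
  waveform(istft(st), w$rate)
}

# 3x3 box smoothing of a time-frequency mask (bins x frames)
smooth_mask_3x3 <- function(m) {
  pad <- function(x) cbind(x[, 1], x, x[, ncol(x)])
  padr <- function(x) rbind(x[1, ], x, x[nrow(x), ])
  mp <- padr(pad(m))
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + mp[dr + seq_len(nr), dc + seq_len(nc)]
  acc / 9
}

#' Birdsong-background ratio of a clip
#'
#' Compares mean in-band power during the song interval against mean
#' in-band power over the rest of the clip. Clips whose song is more than
#' 10 dB quieter than the background (`ratio_db < -10`) are flagged for
#' removal from the training bank.
#'
#' @param w a [waveform()].
#' @param song_interval a [time_interval()] covering the song.
#' @param song_band numeric `c(lo_hz, hi_hz)` band of the song.
#' @param removal_db screening threshold in dB (default -10).
#' @return list with `song_db`, `background_db`, `ratio_db`, `remove`.
#' @export
estimate_bbr <- function(w, song_interval, song_band, removal_db = -10) {
  stopifnot_waveform(w)
  nyq <- w$rate / 2
  if (song_band[1] >= song_band[2] || song_band[2] >= nyq)
    stop("need song_band lo < hi < Nyquist")
  xb <- bandpass_fft(w$samples, w$rate, song_band[1], song_band[2])
  n <- length(xb)
  i0 <- max(0L, round(song_interval$start_s * w$rate))
  i1 <- min(n, round(song_interval$end_s * w$rate))
  if (i1 <= i0) stop("song interval outside the clip")
  inside <- logical(n); inside[(i0 + 1L):i1] <- TRUE
  if (!any(!inside)) stop("no background complement: song interval covers clip")
  song_db <- 10 * log10(mean(xb[inside]^2) + 1e-300)
  bg_db <- 10 * log10(mean(xb[!inside]^2) + 1e-300)
  ratio <- song_db - bg_db
  list(song_db = song_db, background_db = bg_db, ratio_db = ratio,
       remove = ratio < removal_db)
}

# ideal (brick-wall) bandpass via FFT bin masking; fine for power
# measurement where phase/ringing do not matter
bandpass_fft <- function(x, rate, lo, hi) {
  n <- length(x)
  f <- abs(seq(0, n - 1) * rate / n)
  f <- pmin(f, rate - f)            # fold to 0..Nyquist
  X <- stats::fft(x)
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Full cleaning chain for one candidate clip
#'
#' High-pass filter, then peak normalization, then stationary spectral
#' gating, in that order.
#'
#' @param w a [waveform()].
#' @param cfg a [cleaning_config()].
#' @param noise_sample optional background-only [waveform()] for the gate.
#' @return cleaned [waveform()].
#' @export
clean_segment <- function(w, cfg = cleaning_config(), noise_sample = NULL) {
  w |> highpass(cfg) |>
    normalize_peak(cfg$target_peak_db) |>
    spectral_gate(cfg, noise_sample)
}
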