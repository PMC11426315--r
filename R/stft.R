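# Short-time Fourier transform with exact overlap-add inversion. The STFT
# here is the workhorse behind spectral gating, oracle ratio masks, the
# phase vocoder, and spectrogram edge labeling.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Short-time Fourier transform
#'
#' Frames the signal with a periodic Hann window (no centering padding;
#' the tail is zero-padded to complete the last frame) and returns the
#' one-sided spectrum.
#'
#' @param x numeric vector or [waveform()].
#' @param nfft frame length in samples (power of two recommended).
#' @param hop hop between frame starts in samples.
#' @return list with `S` (complex matrix, `nfft/2 + 1` frequency rows by
#'   frame columns), `nfft`, `hop`, `n` (original length), `rate` (if the
#'   input was a waveform, else `NA`).
#' @export
stft <- function(x, nfft = 1024, hop = 256) {
  rate <- NA_real_
  if (is_waveform(x)) { rate <- x$rate; x <- x$samples }
  n <- length(x)
  if (n < 1) stop("empty input")
  if (hop < 1 || hop > nfft) stop("need 1 <= hop <= nfft")
  # pad both ends by one frame so every original sample sits under a full
  # window-square sum and the inverse transform is exact everywhere
  pad <- nfft
  x <- c(numeric(pad), x, numeric(pad))
  nx <- length(x)
  nframes <- max(1L, as.integer(ceiling((nx - nfft) / hop)) + 1L)
  ntot <- (nframes - 1L) * hop + nfft
  if (ntot > nx) x <- c(x, numeric(ntot - nx))
  idx <- outer(seq_len(nfft), (seq_len(nframes) - 1L) * hop, `+`)
  frames <- matrix(x[idx], nrow = nfft) * hann_window(nfft)
  Sfull <- stats::mvfft(frames)
  list(S = Sfull[1:(nfft / 2 + 1), , drop = FALSE],
       nfft = nfft, hop = hop, n = n, pad = pad, rate = rate)
}

#' Inverse short-time Fourier transform
#'
#' Windowed overlap-add with window-square normalization; `stft()` then
#' `istft()` reconstructs the signal to float precision for `hop <= nfft/2`.
#'
#' @param st an object from [stft()] (possibly with a modified `S`).
#' @param n_out output length; defaults to the analysis length.
#' @return numeric vector of `n_out` samples.
#' @export
istft <- function(st, n_out = st$n) {
  nfft <- st$nfft; hop <- st$hop
  pad <- if (is.null(st$pad)) 0L else st$pad
  S <- st$S
  nframes <- ncol(S)
  # rebuild the full spectrum by conjugate symmetry
  Sfull <- rbind(S, Conj(S[(nfft / 2):2, , drop = FALSE]))
  frames <- Re(stats::mvfft(Sfull, inverse = TRUE)) / nfft
  w <- hann_window(nfft)
  npad <- (nframes - 1L) * hop + nfft
  y <- numeric(npad); wsum <- numeric(npad)
  for (k in seq_len(nframes)) {
    i <- ((k - 1L) * hop + 1L):((k - 1L) * hop + nfft)
    y[i] <- y[i] + frames[, k] * w
    wsum[i] <- wsum[i] + w^2
  }
  # normalize where the window-square sum has real support; samples with
  # negligible coverage (unpadded frame edges) are zeroed, not amplified
  good <- wsum > 0.05 * max(wsum)
  y[good] <- y[good] / wsum[good]
  y[!good] <- 0
  if (pad > 0) y <- y[-seq_len(pad)]
  if (n_out > length(y)) y <- c(y, numeric(n_out - length(y)))
  y[seq_len(n_out)]
}

# frequency (Hz) of each one-sided STFT row
stft_freqs <- function(nfft, rate) (0:(nfft / 2)) * rate / nfft

# power spectrum (periodogram) helper used by synthesis checks and BBR
periodogram_db <- function(x, rate) {
  n <- length(x)
  X <- stats::fft(x)
  p <- Mod(X[1:(n %/% 2 + 1)])^2 / n
  data.frame(freq = (0:(n %/% 2)) * rate / n, power_db = 10 * log10(p + 1e-300))
}
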