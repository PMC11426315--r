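# Song augmentation: pitch-preserving time stretch (phase vocoder),
# duration-preserving pitch shift (stretch + band-limited resample), and
# gain. These diversify the song bank before mixing.

#' Pitch-preserving time stretch
#'
#' Classic phase vocoder: frames are read at a fractional analysis hop
#' `synthesis_hop / factor`, per-bin instantaneous frequencies are
#' estimated from phase increments, and synthesis phases are accumulated
#' at the fixed synthesis hop. At `factor = 1` the analysis and synthesis
#' hops coincide and the transform reduces to an exact STFT round trip.
#'
#' @param w a [waveform()].
#' @param factor output/input duration ratio (> 0); 1.2 makes the song 20%
#'   longer at the same pitch.
#' @param nfft,hop frame length and synthesis hop in samples.
#' @return a [waveform()] of `round(n * factor)` samples.
#' @export
time_stretch <- function(w, factor, nfft = 1024, hop = 256) {
  stopifnot_waveform(w)
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0")
  x <- w$samples
  n <- length(x)
  n_out <- round(n * factor)
  if (factor == 1 || n < nfft * 2) return(waveform(
    c(x, numeric(max(0, n_out - n)))[seq_len(n_out)], w$rate))
  ha <- hop / factor
  K <- max(2L, as.integer(floor((n - nfft) / ha)) + 1L)
  pos <- round((seq_len(K) - 1) * ha)
  xp <- c(x, numeric(nfft))
  win <- hann_window(nfft)
  frames <- vapply(pos, function(p) xp[(p + 1):(p + nfft)] * win,
                   numeric(nfft))
  Sf <- stats::mvfft(frames)
  nb <- nfft / 2 + 1
  S <- Sf[1:nb, , drop = FALSE]
  mag <- Mod(S); ph <- Arg(S)
  omega <- 2 * pi * (0:(nb - 1)) / nfft
  psi <- matrix(0, nb, K)
  psi[, 1] <- ph[, 1]
  for (k in 2:K) {
    delta <- pos[k] - pos[k - 1]
    dev <- ph[, k] - ph[, k - 1] - omega * delta
    dev <- dev - 2 * pi * round(dev / (2 * pi))      # principal value
    psi[, k] <- psi[, k - 1] + hop * (omega + dev / delta)
  }
  st <- list(S = mag * exp(1i * psi), nfft = nfft, hop = hop,
             n = (K - 1L) * hop + nfft)
  y <- istft(st, n_out = n_out)
  waveform(y, w$rate)
}

#' Duration-preserving pitch shift
#'
#' Time-stretches by the frequency factor `2^(semitones/12)` with the
#' phase vocoder, then resamples back to the original length, which scales
#' all frequencies by that factor while keeping the duration.
#'
#' @param w a [waveform()].
#' @param semitones shift in semitones (positive = up).
#' @param nfft,hop phase-vocoder parameters.
#' @return a [waveform()] of the original length.
#' @export
pitch_shift <- function(w, semitones, nfft = 1024, hop = 256) {
  stopifnot_waveform(w)
  if (semitones == 0) return(w)
  alpha <- 2^(semitones / 12)
  y <- time_stretch(w, alpha, nfft, hop)
  waveform(fft_resample(y$samples, length(w$samples)), w$rate)
}

#' Augmentation ranges for the mixture generator
#'
#' Defaults follow the dataset-generation recipe: time stretch drawn
#' uniformly in -20%..+20%, gain ("amplified by -85% to +20%") uniform in
#' 0.15..1.20, pitch shift uniform within +/-1 semitone, and a background
#' attenuation schedule that cuts the background to 10% of its level with
#' probability 0.05 and to 5% with probability 0.05, so the model also
#' sees near-quiet backgrounds.
#'
#' @param time_stretch length-2 stretch-factor interval.
#' @param gain length-2 gain-factor interval.
#' @param pitch_shift_semitones length-2 semitone interval.
#' @param bg_attenuation_schedule list of `c(gain_factor, probability)`;
#'   probabilities must sum to at most 1.
#' @return an `augmentation_ranges` list.
#' @export
augmentation_ranges <- function(time_stretch = c(0.8, 1.2),
                                gain = c(0.15, 1.2),
                                pitch_shift_semitones = c(-1, 1),
                                bg_attenuation_schedule =
                                  list(c(0.1, 0.05), c(0.05, 0.05))) {
  chk <- function(v) length(v) == 2 && v[1] <= v[2]
  if (!chk(time_stretch) || !chk(gain) || !chk(pitch_shift_semitones))
    stop("ranges must be ordered length-2 intervals")
  ps <- sum(vapply(bg_attenuation_schedule, `[`, numeric(1), 2))
  if (ps > 1) stop("attenuation schedule probabilities must sum to <= 1")
  structure(list(time_stretch = time_stretch, gain = gain,
                 pitch_shift_semitones = pitch_shift_semitones,
                 bg_attenuation_schedule = bg_attenuation_schedule),
            class = "augmentation_ranges")
}

#' Randomly augment one song
#'
#' Draws a stretch factor, pitch shift, and gain uniformly from the
#' configured ranges and applies stretch, then pitch shift, then gain.
#' Draws at the interval endpoints collapse to identity operations.
#'
#' @param song a [waveform()].
#' @param ranges an [augmentation_ranges()].
#' @param seed integer RNG seed.
#' @return list with `wave` (the augmented [waveform()]) and `params`
#'   (`stretch`, `semitones`, `gain` actually applied).
#' @export
augment_song <- function(song, ranges = augmentation_ranges(), seed = NULL) {
  stopifnot_waveform(song)
  with_seed(seed, {
    stretch <- stats::runif(1, ranges$time_stretch[1], ranges$time_stretch[2])
    semis <- stats::runif(1, ranges$pitch_shift_semitones[1],
                          ranges$pitch_shift_semitones[2])
    gain <- stats::runif(1, ranges$gain[1], ranges$gain[2])
    y <- song
    if (stretch != 1) y <- time_stretch(y, stretch)
    if (semis != 0) y <- pitch_shift(y, semis)
    y <- waveform(y$samples * gain, y$rate)
    list(wave = y, params = list(stretch = stretch, semitones = semis,
                                 gain = gain))
  })
}
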