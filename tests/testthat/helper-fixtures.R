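# Fixtures built in code: tones, chirps, and small helpers shared by the
# unit tests. No audio files ship with the package.

RATE <- 22050

tone_wave <- function(freq, dur_s, rate = RATE, amp = 0.5, phase = 0) {
  t <- (seq_len(round(dur_s * rate)) - 1) / rate
  waveform(amp * sin(2 * pi * freq * t + phase), rate)
}

chirp_wave <- function(f0, f1, dur_s, rate = RATE, amp = 0.5) {
  n <- round(dur_s * rate)
  t <- (seq_len(n) - 0.5) / rate
  f <- f0 + (f1 - f0) * t / dur_s
  waveform(amp * sin(2 * pi * cumsum(f) / rate), rate)
}

noise_wave <- function(dur_s, rate = RATE, sd = 0.1, seed = NULL) {
  n <- round(dur_s * rate)
  x <- if (is.null(seed)) stats::rnorm(n, 0, sd) else {
    set.seed(seed); stats::rnorm(n, 0, sd)
  }
  waveform(x, rate)
}

# dominant spectral frequency via a long periodogram
dominant_freq <- function(w, nfft = 8192) {
  st <- stft(w, nfft, nfft / 4)
  (which.max(rowSums(Mod(st$S)^2)) - 1) * w$rate / nfft
}

# interior amplitude of a (filtered) sinusoid, avoiding filter edge ringing
interior_amplitude <- function(x, trim_frac = 0.1) {
  n <- length(x)
  i <- seq.int(floor(n * trim_frac), ceiling(n * (1 - trim_frac)))
  sqrt(2) * sqrt(mean(x[i]^2))
}

# band energy in dB over [lo, hi] Hz
band_energy_db <- function(w, lo, hi) {
  xb <- songsep:::bandpass_fft(w$samples, w$rate, lo, hi)
  10 * log10(sum(xb^2) + 1e-300)
}

# independent brute-force BSS-eval oracle: explicit normal-equations
# projections, no shared code with the package implementation
bss_oracle <- function(e, refs, target_index = 1) {
  e <- if (inherits(e, "waveform")) e$samples else e
  refs <- lapply(refs, function(r) if (inherits(r, "waveform")) r$samples else r)
  tgt <- refs[[target_index]]
  s_target <- (sum(e * tgt) / sum(tgt * tgt)) * tgt
  R <- do.call(cbind, refs)
  G <- t(R) %*% R
  coef <- solve(G, t(R) %*% e)
  p_all <- as.numeric(R %*% coef)
  e_interf <- p_all - s_target
  e_artif <- e - p_all
  list(sdr_db = 10 * log10(sum(s_target^2) / sum((e_interf + e_artif)^2)),
       sir_db = 10 * log10(sum(s_target^2) / sum(e_interf^2)),
       sar_db = 10 * log10(sum((s_target + e_interf)^2) / sum(e_artif^2)))
}
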