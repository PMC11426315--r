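#' Mono waveform container
#'
#' A `waveform` is the package's single audio container: a numeric vector of
#' amplitude samples (nominal range -1..1, dimensionless) plus a sampling
#' rate in Hz. All pipeline stages operate on mono waveforms; multichannel
#' audio is represented as a list of waveforms (one per microphone).
#'
#' @param samples numeric vector of finite amplitudes.
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class `waveform` with elements `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, length.out = 22050)), 22050)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (length(samples) && !is.finite(sum(samples)))
    stop("all samples must be finite")
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), peak %.4f>\n",
              length(x$samples), x$rate, duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

is_waveform <- function(x) inherits(x, "waveform")

stopifnot_waveform <- function(w) {
  if (!is_waveform(w)) stop("expected a `waveform` object")
  invisible(w)
}

#' Duration of a waveform in seconds
#' @param w a [waveform()].
#' @return duration in seconds.
#' @export
duration <- function(w) {
  stopifnot_waveform(w)
  length(w$samples) / w$rate
}

#' Half-open time interval
#'
#' Intervals are half-open `[start_s, end_s)` in seconds; sample indices are
#' 0-based internally, so sample `i` covers time `[i/rate, (i+1)/rate)`.
#'
#' @param start_s start in seconds (>= 0 for audio addressing; negative
#'   starts are allowed when slicing with padding).
#' @param end_s end in seconds, strictly greater than `start_s`.
#' @return a `time_interval` object.
#' @export
time_interval <- function(start_s, end_s) {
  if (!is.finite(start_s) || !is.finite(end_s) || end_s <= start_s)
    stop("need finite end_s > start_s")
  structure(list(start_s = start_s, end_s = end_s), class = "time_interval")
}

#' Extract a time span from a waveform
#'
#' Returns the half-open span `[start_s, end_s)`. With `pad = TRUE`,
#' out-of-range regions are zero-filled so the output has exactly
#' `round((end_s - start_s) * rate)` samples — this is how candidate songs
#' get their buffer when a detection sits at the edge of a recording.
#'
#' @param w a [waveform()].
#' @param interval a [time_interval()] (or list with `start_s`, `end_s`).
#' @param pad if `TRUE`, zero-fill outside the recording.
#' @return a [waveform()].
#' @export
slice_wave <- function(w, interval, pad = FALSE) {
  stopifnot_waveform(w)
  n <- length(w$samples)
  i0 <- round(interval$start_s * w$rate)
  i1 <- round(interval$end_s * w$rate)   # exclusive
  if (i1 <= i0) stop("empty interval after rounding")
  if (!pad) {
    if (i1 <= 0 || i0 >= n)
      stop("interval lies fully outside the recording (use pad = TRUE)")
    j0 <- max(i0, 0L); j1 <- min(i1, n)
    return(waveform(w$samples[(j0 + 1L):j1], w$rate))
  }
  out <- numeric(i1 - i0)
  j0 <- max(i0, 0L); j1 <- min(i1, n)
  if (j1 > j0)
    out[(j0 - i0 + 1L):(j1 - i0)] <- w$samples[(j0 + 1L):j1]
  waveform(out, w$rate)
}

#' Peak level in dBFS
#'
#' `20 * log10(max(abs(samples)))`; full scale (peak amplitude 1) is 0 dBFS.
#' All-zero input returns `-Inf` as the distinguished silent value.
#'
#' @param w a [waveform()].
#' @return peak level in dBFS (possibly `-Inf`).
#' @export
peak_dbfs <- function(w) {
  stopifnot_waveform(w)
  if (!length(w$samples)) stop("empty waveform")
  p <- max(abs(w$samples))
  if (p == 0) -Inf else 20 * log10(p)
}

#' Root-mean-square amplitude
#' @param w a [waveform()] or numeric vector.
#' @return RMS amplitude (linear, not dB).
#' @export
rms <- function(w) {
  x <- if (is_waveform(w)) w$samples else as.numeric(w)
  if (!length(x)) stop("empty input")
  sqrt(mean(x^2))
}

#' Resample a waveform
#'
#' Band-limited resampling. Integer-ratio conversions go through the
#' polyphase resampler in the `signal` package; the output is trimmed or
#' zero-padded to exactly `round(n * new_rate / rate)` samples so duration
#' is preserved within one sample period. A same-rate call is the identity.
#'
#' @param w a [waveform()].
#' @param new_rate target rate in Hz.
#' @return a [waveform()] at `new_rate`.
#' @export
resample_wave <- function(w, new_rate) {
  stopifnot_waveform(w)
  if (!is.finite(new_rate) || new_rate <= 0) stop("new_rate must be > 0")
  if (new_rate == w$rate) return(w)
  n_out <- round(length(w$samples) * new_rate / w$rate)
  g <- gcd_int(round(new_rate), round(w$rate))
  p <- round(new_rate) / g; q <- round(w$rate) / g
  if (p * q <= 1e6) {
    y <- as.numeric(signal::resample(w$samples, p, q))
  } else {
    y <- fft_resample(w$samples, n_out)
  }
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  waveform(y, new_rate)
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  max(a, 1)
}

# Fourier-domain resampling of x to m samples (band-limited, periodic
# extension assumption; used for non-rational rate factors e.g. pitch shift).
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  k <- min(n, m)
  h <- floor(k / 2)
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h > 0) Y[(m - h + 1):m] <- X[(n - h + 1):n]
  if (k %% 2 == 0 && h > 0) {
    # split shared Nyquist bin to keep the result real
    Y[h + 1] <- Y[h + 1] / 2
    Y[m - h + 1] <- Y[m - h + 1] + Conj(Y[h + 1])
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

db_to_amp <- function(db) 10^(db / 20)
amp_to_db <- function(a) 20 * log10(a)
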