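# Deterministic synthetic fixtures. The song generator produces schematic
# Golden-cheeked-warbler-like vocalizations — repeated frequency-modulated
# elements, buzzes, an optional trailing hook (A songs) or flourish (B
# songs) — with known band edges and timing, so downstream labeling and
# localization tests have exact ground truth. The background generator
# produces site-like audio: colored noise, tonal interferers, transients,
# and low-frequency rumble. Everything is seed-deterministic.

#' Specification of a synthetic warbler-like song
#'
#' A songs are a train of `n_repeats` FM elements followed by the main
#' buzz and an optional hook sweep; B songs are an initial buzz, a short
#' connecting note, the main buzz, and an optional flourish. Frequencies
#' scale with `peak_freq_hz`, where the main buzz carries the dominant
#' spectral energy.
#'
#' @param song_type `"A"` or `"B"`.
#' @param n_repeats number of repeat elements (A songs; default 4).
#' @param element_dur_s duration of each repeat element (default 0.12 s).
#' @param buzz_dur_s main buzz duration (default 0.4 s).
#' @param peak_freq_hz song peak frequency in Hz (default 5000).
#' @param has_hook trailing hook sweep (A songs; default `TRUE`).
#' @param has_flourish trailing flourish (B songs; default `TRUE`).
#' @param initial_buzz_dur_s initial buzz duration (B songs; default 0.3 s).
#' @param amplitude peak amplitude, 0..1 (default 0.8).
#' @param gap_s silent gap between successive components (default 0.02 s).
#' @param seed integer RNG seed for the small frequency/timing jitter.
#' @return a `song_spec` list.
#' @export
song_spec <- function(song_type = c("A", "B"), n_repeats = 4,
                      element_dur_s = 0.12, buzz_dur_s = 0.4,
                      peak_freq_hz = 5000, has_hook = TRUE,
                      has_flourish = TRUE, initial_buzz_dur_s = 0.3,
                      amplitude = 0.8, gap_s = 0.02, seed = 1) {
  song_type <- match.arg(song_type)
  if (n_repeats < 0 || element_dur_s < 0 || buzz_dur_s < 0 ||
      initial_buzz_dur_s < 0 || gap_s < 0)
    stop("durations and counts must be >= 0")
  if (peak_freq_hz <= 0) stop("peak_freq_hz must be > 0")
  structure(as.list(environment()), class = "song_spec")
}

# one FM component: instantaneous frequency trajectory -> enveloped tone.
# The trajectory argument is warped so its endpoint frequencies are held
# for the first/last tenth of the component: the band extremes are then
# sounded at full amplitude, not inside the onset/offset fades.
fm_component <- function(f_of_t, dur_s, rate, amp = 1, am_hz = 0,
                         am_depth = 0) {
  n <- max(1L, round(dur_s * rate))
  t <- (seq_len(n) - 0.5) / rate
  u <- pmin(pmax((t / dur_s - 0.1) / 0.8, 0), 1)
  f <- f_of_t(u)
  ph <- 2 * pi * cumsum(f) / rate
  x <- sin(ph)
  if (am_hz > 0) x <- x * (1 - am_depth + am_depth * 0.5 *
                             (1 + sin(2 * pi * am_hz * t)))
  # raised-cosine edges (10 ms or a fifth of the component)
  ne <- min(round(0.01 * rate), n %/% 5)
  if (ne > 0) {
    env <- 0.5 * (1 - cos(pi * (seq_len(ne) - 0.5) / ne))
    x[seq_len(ne)] <- x[seq_len(ne)] * env
    x[(n - ne + 1):n] <- x[(n - ne + 1):n] * rev(env)
  }
  list(x = x * amp, f_range = range(f))
}

#' Synthesize a warbler-like song
#'
#' @param spec a [song_spec()].
#' @param rate sampling rate in Hz (default 22050).
#' @return a [waveform()] with attribute `"features"`: the ground-truth
#'   song type, repeat count, buzz durations, peak frequency, and band
#'   edges `f_lo_hz`/`f_hi_hz` (the min/max instantaneous frequency over
#'   all components), used as truth by the labeling tests.
#' @export
synth_song <- function(spec, rate = 22050) {
  if (!inherits(spec, "song_spec")) stop("expected a song_spec")
  if (spec$peak_freq_hz >= rate / 2) stop("peak frequency above Nyquist")
  fp <- spec$peak_freq_hz
  with_seed(spec$seed, {
    comps <- list()
    if (spec$song_type == "A") {
      for (k in seq_len(spec$n_repeats)) {
        j <- stats::runif(1, -0.02, 0.02)       # per-element pitch jitter
        f0 <- fp * (0.80 + j); f1 <- fp * (0.98 + j)
        comps[[length(comps) + 1L]] <- fm_component(
          function(u) f0 + (f1 - f0) * u, spec$element_dur_s, rate, amp = 0.6)
      }
      if (spec$buzz_dur_s > 0)
        comps[[length(comps) + 1L]] <- fm_component(
          function(u) rep(fp, length(u)), spec$buzz_dur_s, rate,
          amp = 1, am_hz = 80, am_depth = 0.5)
      if (spec$has_hook)
        comps[[length(comps) + 1L]] <- fm_component(
          function(u) fp * (1.20 - 0.50 * u), 0.10, rate, amp = 0.7)
    } else {
      if (spec$initial_buzz_dur_s > 0)
        comps[[length(comps) + 1L]] <- fm_component(
          function(u) rep(0.90 * fp, length(u)), spec$initial_buzz_dur_s,
          rate, amp = 0.7, am_hz = 60, am_depth = 0.5)
      comps[[length(comps) + 1L]] <- fm_component(
        function(u) fp * (0.90 + 0.10 * u), 0.08, rate, amp = 0.5)
      if (spec$buzz_dur_s > 0)
        comps[[length(comps) + 1L]] <- fm_component(
          function(u) rep(fp, length(u)), spec$buzz_dur_s, rate,
          amp = 1, am_hz = 90, am_depth = 0.5)
      if (spec$has_flourish)
        comps[[length(comps) + 1L]] <- fm_component(
          function(u) fp * (1.0 + 0.25 * sin(pi * u)), 0.12, rate, amp = 0.7)
    }
    if (!length(comps)) stop("song has zero total duration")
    gap <- numeric(round(spec$gap_s * rate))
    xs <- lapply(comps, `[[`, "x")
    pieces <- xs[1]
    for (k in seq_along(xs)[-1]) pieces <- c(pieces, list(gap), xs[k])
    x <- unlist(pieces)
    x <- x / max(abs(x)) * spec$amplitude
    fr <- range(vapply(comps, `[[`, numeric(2), "f_range"))
    w <- waveform(x, rate)
    attr(w, "features") <- list(
      song_type = spec$song_type, n_repeats = spec$n_repeats,
      buzz_dur_s = spec$buzz_dur_s,
      initial_buzz_dur_s = if (spec$song_type == "B")
        spec$initial_buzz_dur_s else 0,
      peak_freq_hz = fp, f_lo_hz = fr[1], f_hi_hz = fr[2],
      duration_s = length(x) / rate)
    w
  })
}

#' Specification of a synthetic site background
#'
#' @param duration_s duration in seconds (default 60).
#' @param noise_color_exponent spectral slope alpha of the broadband bed
#'   (power proportional to `1/f^alpha`; 0 = white, 1 = pink; default 1).
#' @param tonal_components list of `c(freq_hz, level_db)` steady tones
#'   (level in dB relative to the noise-bed RMS); default none.
#' @param transient_rate_per_min expected transient events (clicks, snaps)
#'   per minute; counts are Poisson (default 2).
#' @param low_freq_rumble_level_db level of a <150 Hz rumble component in
#'   dB relative to the noise-bed RMS; `-Inf` disables (default 0).
#' @param max_freq_hz optional brick-wall upper band limit; used to build
#'   band-disjoint fixtures where the background must stay clear of the
#'   song band (default `NULL`, full band).
#' @param seed integer RNG seed.
#' @return a `background_spec` list.
#' @export
background_spec <- function(duration_s = 60, noise_color_exponent = 1,
                            tonal_components = list(),
                            transient_rate_per_min = 2,
                            low_freq_rumble_level_db = 0,
                            max_freq_hz = NULL, seed = 1) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  structure(as.list(environment()), class = "background_spec")
}

#' Synthesize a site-like background
#'
#' @param spec a [background_spec()].
#' @param rate sampling rate in Hz (default 22050).
#' @return a [waveform()], peak-normalized to 0.5, with attribute
#'   `"n_transients"` (the realized Poisson transient count).
#' @export
synth_background <- function(spec, rate = 22050) {
  if (!inherits(spec, "background_spec")) stop("expected a background_spec")
  n <- round(spec$duration_s * rate)
  with_seed(spec$seed, {
    x <- colored_noise(n, rate, spec$noise_color_exponent)
    base_rms <- rms(x)
    for (tc in spec$tonal_components) {
      a <- base_rms * db_to_amp(tc[2]) * sqrt(2)
      x <- x + a * sin(2 * pi * tc[1] * (seq_len(n) - 0.5) / rate +
                         stats::runif(1, 0, 2 * pi))
    }
    n_tr <- stats::rpois(1, spec$transient_rate_per_min *
                            spec$duration_s / 60)
    if (n_tr > 0) {
      for (k in seq_len(n_tr)) {
        dur <- round(stats::runif(1, 0.005, 0.03) * rate)
        at <- sample.int(max(1L, n - dur), 1)
        burst <- stats::rnorm(dur) *
          sin(pi * (seq_len(dur) - 0.5) / dur)^2 * 4 * base_rms
        x[at:(at + dur - 1L)] <- x[at:(at + dur - 1L)] + burst
      }
    }
    if (is.finite(spec$low_freq_rumble_level_db)) {
      r <- colored_noise(n, rate, 3)
      r <- bandpass_fft(r, rate, 0, 150)
      x <- x + r / rms(r) * base_rms * db_to_amp(spec$low_freq_rumble_level_db)
    }
    if (!is.null(spec$max_freq_hz))
      x <- bandpass_fft(x, rate, 0, spec$max_freq_hz)
    x <- x / max(abs(x)) * 0.5
    w <- waveform(x, rate)
    attr(w, "n_transients") <- n_tr
    w
  })
}

# Gaussian noise with power spectral density proportional to 1/f^alpha,
# shaped in the Fourier domain; DC removed.
colored_noise <- function(n, rate, alpha) {
  X <- stats::fft(stats::rnorm(n))
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f)
  g <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(stats::fft(X * g, inverse = TRUE)) / n
  x / stats::sd(x) * 0.1
}

#' Synthesize a detector score table
#'
#' Emulates a sliding-window classifier's output over a recording with
#' known event truth: windows of `window_len_s` advanced by `stride_s`;
#' the target-class probability is `high` for windows overlapping a target
#' event by at least half a window and `low` otherwise, with optional
#' Gaussian jitter clipped to `[0, 1]`. A single generic other class gets
#' the mirrored treatment for non-target events.
#'
#' @param truth data frame with `start_s`, `end_s`, `is_target` rows
#'   describing events in the recording.
#' @param duration_s recording duration in seconds.
#' @param noise_sd jitter standard deviation on the probability scale
#'   (default 0).
#' @param seed integer RNG seed.
#' @param recording_id id string for the output rows.
#' @param window_len_s,stride_s window geometry (defaults 3 s / 1 s).
#' @param high,low probability levels (defaults 0.95 / 0.02).
#' @return long data frame: `recording_id`, `start_s`, `class`, `prob`.
#' @export
synth_score_table <- function(truth, duration_s, noise_sd = 0, seed = 1,
                              recording_id = "rec1",
                              window_len_s = 3, stride_s = 1,
                              high = 0.95, low = 0.02) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  starts <- seq(0, max(0, duration_s - window_len_s), by = stride_s)
  overlap_at_least_half <- function(ws, rows) {
    if (!nrow(rows)) return(FALSE)
    ov <- pmin(rows$end_s, ws + window_len_s) - pmax(rows$start_s, ws)
    any(ov >= window_len_s / 2)
  }
  tgt_rows <- truth[truth$is_target, , drop = FALSE]
  oth_rows <- truth[!truth$is_target, , drop = FALSE]
  with_seed(seed, {
    mk <- function(cls, rows) {
      p <- vapply(starts, function(ws)
        if (overlap_at_least_half(ws, rows)) high else low, numeric(1))
      if (noise_sd > 0)
        p <- pmin(1, pmax(0, p + stats::rnorm(length(p), 0, noise_sd)))
      data.frame(recording_id = recording_id, start_s = starts,
                 class = cls, prob = p, stringsAsFactors = FALSE)
    }
    rbind(mk("target", tgt_rows), mk("other", oth_rows))
  })
}
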