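# The data generator: stitch background pieces into a continuous bed,
# layer randomly augmented songs on top at random offsets, optionally pin
# the birdsong-background ratio, and emit the mixture together with its
# exact ground-truth stems and an event manifest. The mixture is always
# formed as song_stem + background_stem, so stem additivity is exact by
# construction.

#' Mixture specification
#'
#' @param duration_s example duration in seconds (default 60).
#' @param songs_per_min expected song occurrences per minute; the realized
#'   count is Poisson unless `n_songs` pins it (default 6).
#' @param n_songs optional fixed song count, used for controlled sweeps
#'   such as "20 songs over 60 s" ratio tests (default `NULL`).
#' @param target_ratio optional birdsong-background ratio (RMS of the song
#'   stem over RMS of the background stem); when set, the song stem is
#'   rescaled globally so the realized ratio matches (default `NULL`).
#' @param class_weights named numeric sampling weights over song-bank
#'   classes; uncommon song types can be up-weighted here (default: equal).
#' @param seed integer RNG seed.
#' @return a `mix_spec` list.
#' @export
mix_spec <- function(duration_s = 60, songs_per_min = 6, n_songs = NULL,
                     target_ratio = NULL, class_weights = NULL, seed = 1) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (songs_per_min < 0) stop("songs_per_min must be >= 0")
  if (!is.null(target_ratio) && target_ratio <= 0)
    stop("target_ratio must be > 0")
  structure(as.list(environment()), class = "mix_spec")
}

#' Stitch background pieces into a continuous bed
#'
#' Concatenates randomly chosen bank pieces with 50 ms linear crossfades
#' at the joins until the requested duration is reached; a single piece
#' longer than the request yields a random contiguous excerpt. Backgrounds
#' are never layered on top of each other, which keeps the bed's volume
#' consistent with a single real recording.
#'
#' @param bank nonempty list of [waveform()]s at a common rate.
#' @param duration_s output duration in seconds.
#' @param seed integer RNG seed.
#' @param crossfade_s crossfade at each join (default 0.05 s).
#' @return a [waveform()] of exactly `round(duration_s * rate)` samples.
#' @export
stitch_background <- function(bank, duration_s, seed = NULL,
                              crossfade_s = 0.05) {
  if (!length(bank)) stop("background bank is empty")
  rate <- bank[[1]]$rate
  n_out <- round(duration_s * rate)
  nf <- round(crossfade_s * rate)
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n_out) {
      piece <- bank[[sample.int(length(bank), 1)]]$samples
      if (!length(out) && length(piece) >= n_out) {
        at <- sample.int(length(piece) - n_out + 1L, 1)
        out <- piece[at:(at + n_out - 1L)]
        break
      }
      if (!length(out)) { out <- piece; next }
      k <- min(nf, length(out), length(piece))
      if (k > 0) {
        wfade <- seq_len(k) / (k + 1)
        tail_i <- (length(out) - k + 1L):length(out)
        joined <- out[tail_i] * (1 - wfade) + piece[seq_len(k)] * wfade
        out <- c(out[seq_len(length(out) - k)], joined,
                 piece[(k + 1L):length(piece)])
      } else out <- c(out, piece)
    }
    waveform(out[seq_len(n_out)], rate)
  })
}

#' Birdsong-background ratio of a pair of stems
#'
#' "Total volume" of a stem is its RMS; the ratio is
#' `rms(song) / rms(background)`. Ratios of 0.01-0.02 correspond to songs
#' barely audible under the background.
#'
#' @param song_stem,background_stem [waveform()]s (or numeric vectors) of
#'   equal length.
#' @return dimensionless ratio.
#' @export
realized_ratio <- function(song_stem, background_stem) {
  b <- if (is_waveform(background_stem)) background_stem$samples
       else background_stem
  if (all(b == 0)) stop("background stem is silent; ratio undefined")
  rms(song_stem) / rms(b)
}

#' Generate one mixture example with ground-truth stems
#'
#' Stitches a background bed, draws a song count (Poisson at
#' `songs_per_min`, or fixed via `n_songs`), samples songs by class
#' weight, augments each (stretch/pitch/gain), places them at uniform
#' random offsets (overlaps allowed), optionally rescales the song stem to
#' hit `target_ratio` exactly, applies the background attenuation
#' schedule, and returns mixture = song stem + background stem with a
#' complete event manifest.
#'
#' @param song_bank list of `list(wave = waveform, class = chr)` entries.
#' @param bg_bank list of background [waveform()]s.
#' @param spec a [mix_spec()].
#' @param ranges an [augmentation_ranges()].
#' @return a `mixture_example` list: `mixture`, `song_stem`,
#'   `background_stem` ([waveform()]s), `events` (data frame), and
#'   `realized_ratio`.
#' @export
generate_example <- function(song_bank, bg_bank, spec = mix_spec(),
                             ranges = augmentation_ranges()) {
  if (!length(song_bank)) stop("song bank is empty")
  if (!length(bg_bank)) stop("background bank is empty")
  rate <- bg_bank[[1]]$rate
  n <- round(spec$duration_s * rate)
  classes <- vapply(song_bank, `[[`, character(1), "class")
  wts <- if (is.null(spec$class_weights)) {
    stats::setNames(rep(1, length(unique(classes))), unique(classes))
  } else spec$class_weights
  with_seed(spec$seed, {
    bg <- stitch_background(bg_bank, spec$duration_s,
                            seed = sample.int(2^31 - 2, 1))
    n_songs <- if (!is.null(spec$n_songs)) spec$n_songs
      else stats::rpois(1, spec$songs_per_min * spec$duration_s / 60)
    song_stem <- numeric(n)
    ev <- list()
    for (k in seq_len(n_songs)) {
      cls <- sample(names(wts), 1, prob = wts)
      cand <- which(classes == cls)
      if (!length(cand)) next
      entry <- song_bank[[if (length(cand) == 1) cand
                          else sample(cand, 1)]]
      aug <- augment_song(entry$wave, ranges,
                          seed = sample.int(2^31 - 2, 1))
      m <- length(aug$wave$samples)
      if (m > n) {
        warning("augmented song longer than mixture; skipped")
        next
      }
      at <- sample.int(n - m + 1L, 1)
      song_stem[at:(at + m - 1L)] <- song_stem[at:(at + m - 1L)] +
        aug$wave$samples
      ev[[length(ev) + 1L]] <- data.frame(
        song = k, class = cls, start_s = (at - 1L) / rate,
        end_s = (at - 1L + m) / rate, stretch = aug$params$stretch,
        semitones = aug$params$semitones, gain = aug$params$gain)
    }
    # background attenuation schedule (whole-stem, per example)
    u <- stats::runif(1)
    acc <- 0; bg_gain <- 1
    for (s in ranges$bg_attenuation_schedule) {
      acc <- acc + s[2]
      if (u < acc) { bg_gain <- s[1]; break }
    }
    bg_samples <- bg$samples * bg_gain
    if (!is.null(spec$target_ratio) && any(song_stem != 0)) {
      cur <- rms(song_stem) / rms(bg_samples)
      song_stem <- song_stem * (spec$target_ratio / cur)
    }
    mixture <- song_stem + bg_samples
    structure(list(
      mixture = waveform(mixture, rate),
      song_stem = waveform(song_stem, rate),
      background_stem = waveform(bg_samples, rate),
      events = if (length(ev)) do.call(rbind, ev) else data.frame(),
      bg_gain = bg_gain,
      realized_ratio = if (any(song_stem != 0))
        rms(song_stem) / rms(bg_samples) else 0),
      class = "mixture_example")
  })
}
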