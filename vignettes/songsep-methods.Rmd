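---
title: "songsep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{songsep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`songsep` builds supervised source-separation training data from passive
acoustic monitoring recordings of songbirds and evaluates separation
quality on the tasks bioacousticians actually care about: automated
frequency measurements, timing, and localization. This vignette records
the models, the tunable parameters, and the design decisions behind each
stage, including the choices that were genuinely open.

## The dataset-building model

A supervised separator learns to split a mixture into a *song stem* and a
*background stem*. Training pairs are synthesized: clean songs mined from
the site's own recordings are layered onto background beds mined from
the same recordings, so the model sees the exact interference regime it
will face. The pipeline therefore has two mining stages and one
generation stage.

**Selection.** An external sliding-window classifier (3-s window, 1-s
stride) supplies per-window class probabilities; the package never runs
such a model itself. Windows are ranked by the joint probability that the
window contains the target species and nothing else,
\(p_t \prod_j (1 - p_j)\), treating classes as independent — the simplest
model consistent with "contains the target and no other category". Ties
break toward earlier windows, then lexicographic recording id. Because a
single song straddles several overlapping windows, selection applies
greedy non-maximum suppression with a 3-s minimum start-to-start gap (one
window length); the de-duplication rule is ours, since ranking alone
would extract the same song repeatedly. Selected windows are extracted
with a 1.5-s buffer on each side, zero-padded at recording edges, giving
fixed 6-s clips.

**Cleaning.** Each clip passes through, in order: a zero-phase
Butterworth high-pass (order 5, cutoff 2 kHz — below the warbler song
band at roughly 3–8 kHz; the order and cutoff are our defaults, applied
forward–backward so a tone at the cutoff loses 6 dB rather than 3);
peak normalization to −1 dBFS (read as peak-amplitude normalization,
standard audio practice, leaving 1 dB headroom); and stationary spectral
gating. The gate estimates a per-frequency noise floor — from a supplied
noise sample, otherwise from the quietest 10% of the clip's own STFT
frames (nfft 1024, hop 256) — opens 6 dB above it, attenuates closed
bins by 30 dB, and smooths the binary gate over 3 frames × 3 bins to
avoid musical noise. All gate parameters are package defaults; the
technique itself assumes the noise is stationary, which is why songs
(transient) survive while hiss and hum do not. A self-estimated floor
treats any *continuous* tone as noise; callers cleaning tonal signals
should pass an explicit noise sample. Finally, the
birdsong-background-ratio screen compares mean in-band power inside the
song span against the rest of the clip and flags clips more than 10 dB
below the background for removal. The song span and band come from the
caller (synthesis metadata or detection), since the package has no
manual-vetting step.

**Background mining.** Detector-positive spans are cut out (overlaps
merged), and each hour is condensed to its loudest five minutes: a
centered one-second rolling summation of \(|x|\) smooths the waveform, a
centered one-second rolling maximum spreads each loud event over its
neighborhood, and samples are kept greedily from the top of that metric
until 300 s are covered — merging adjacent samples, discarding fragments
under 2 s, and refilling. Window alignment (centered, truncated at
edges), the earliest-time tie-break, and the greedy select-merge-refill
algorithm are our choices; the metric and the 2-s fragment bound are the
workflow's. The metric is computed exactly (O(n) prefix sums and a
van Herk block cummax), and ties are compared after rounding to 10
significant digits so cumulative-sum float noise cannot reorder equal
values.

**Mixture generation.** Background pieces are stitched with 50-ms
crossfades — linear (equal-amplitude) ones, because constant/correlated
content must stay within the convex hull of the joined pieces; an
equal-power fade can overshoot by up to √2 on correlated material.
Backgrounds are never layered. Songs are augmented per song (stretch
factor uniform in 0.8–1.2 via a phase vocoder; gain uniform in
0.15–1.2; pitch shift uniform in ±1 semitone — the stretch and gain
ranges are the workflow's, the pitch range is our default since only
"reflect the peak-frequency variance" is specified), placed at uniform
offsets with overlaps allowed, and counted either by a Poisson draw at
`songs_per_min` or a fixed count for controlled sweeps. "Total volume"
is implemented as RMS, so the birdsong-background ratio equals an
amplitude scale and the 0.01–0.02 end of the grid is indeed barely
audible. When a target ratio is requested the song stem is rescaled
globally, making the realized ratio exact to float precision. The
background attenuation schedule (×0.1 with probability 0.05, ×0.05 with
probability 0.05) applies per example to the whole background stem. The
mixture is *formed* as `song_stem + background_stem`, which is why stem
additivity is exact rather than approximate.

## Separation and chunked inference

A separator is any function `f(mixture, t0)` returning song and
background estimates; `t0` lets oracle separators slice the matching
span of ground truth. Two ship with the package: the identity separator
(the "before separation" baseline) and the oracle ratio mask
\(|S|/(|S|+|B|+\varepsilon)\) on an STFT grid (nfft 1024, hop 256),
applied with its complement so the estimates sum back to the mixture.
The STFT pads one frame of silence at each end so inverse overlap-add
is exact everywhere; samples with negligible window coverage are zeroed
rather than divided by a vanishing normalizer.

Long inputs are split into 3-s chunks advanced by 2 s (1-s overlap) with
the final chunk right-aligned — re-processing a little audio instead of
zero-padding, to avoid padding artifacts at the signal end. Adjacent
outputs merge with a 0.5-s linear crossfade centered in the overlap;
the outer overlap margins come wholly from the earlier/later chunk
(which also discards each chunk's STFT edge region). The placement of
the crossfade inside the overlap is our decision; only the three
durations are given. The merge weights form an exact partition of unity
(asserted at run time), so chunked inference with the identity separator
reproduces the input to 1e-6 — the basis of the timing guarantee.

## Evaluation battery

**BSS metrics.** SDR/SIR/SAR use gain-only (time-invariant scalar)
projections: target component = projection of the estimate on the target
reference; interference = projection on the span of all references minus
the target; artifact = residual. The classical 512-tap filter-allowed
variant is deliberately out of scope, so absolute values are internally
comparable only. Perfect components give a distinguished `Inf`, capped
at 300 dB for serialization. SI-SDR uses the same projection and is the
quantity whose negative is the usual training loss. A brute-force
normal-equations oracle in the test suite pins the implementation to
1e-6 dB on random cases.

**Frequency labeling.** Clips are cropped to 3 s around the argmax of a
0.5-s moving average of squared samples (zero-padded 'same' alignment;
ties resolve toward the clip middle). A "six-second sliding window over
a six-second clip" is degenerate, so the 0.5-s window is our documented
default, configurable. The log-magnitude spectrogram (nfft 1024, hop
256) is floored at −25 dB below its peak, normalized to [0, 1], and run
through Canny edge detection (Gaussian blur σ = 1 px, relative
hysteresis thresholds 0.1/0.3, non-maximum suppression, weak-edge
linking via connected components); the band edges are the lowest and
highest frequency rows containing an edge pixel at or above 500 Hz (a
rumble guard, configurable to 0). The shallow −25 dB floor keeps the
measurement on the sounded part of the song and *below the Hann
window's spectral-leakage skirt*, which on clean synthetic tones would
otherwise masquerade as signal; with these defaults, tones and chirps
label within ±2 frequency bins and synthetic songs within 3 bins of
their ground-truth band edges.

**Timing.** The timing study synthesizes seeded 6-s mixtures (long
enough to force chunking with a right-aligned tail), separates with the
chunked oracle mask, and reports the full cross-correlation lag between
clean song stem and estimate at integer-sample resolution — one sample
period, ≈45.4 µs at 22,050 Hz, no sub-sample interpolation, matching
the quantization floor of the recording rate.

**Trilateration.** The forest impulse response is a documented
single-scatter model: a direct tap at delay d/c with amplitude
1/max(d, 1), plus up to 512 sampled trees contributing taps at
(d₁+d₂)/c with amplitude scatter_loss/(d₁d₂), scaled by the square root
of the stand density beyond the sample cap. It replaces an external
virtual-forest generator; its purpose is timing realism (echoes always
arrive after the direct path), not acoustic realism. Scenes use three
microphones at (0,0), (0,10), (10,0), 1.5 m up; the bird and the
solution are constrained to the microphone plane, since three in-plane
microphones cannot resolve height, and the speed of sound is fixed at
343 m/s. The background is added identically (not convolved) to every
channel. TDOAs come from integer-sample cross-correlation against
channel 1, and the position solver minimizes the squared TDOA residual
by a coarse ±50-m grid, a fine 0.1-m search restricted to within 10.5 m
of the microphones, and Levenberg–Marquardt refinement of both starts.
With three microphones two TDOA hyperbolas can intersect *twice*, so
some positions outside (and a thin sliver near the corner inside) the
array admit an exact second solution; the solver prefers the candidate
satisfying the survey prior — the bird is within 10 m of some
microphone — whenever it explains the TDOAs comparably well, and the
trial harness reports residual ambiguity as part of the error
distribution, exactly as a deployment would experience it. The
exact-TDOA inversion guarantee (0.05 m) therefore applies to the
unambiguous array neighborhood, verified on a 6-m disc around the
centroid; the zero-TDOA case returns the equidistant point (5, 5).

**Threshold study.** The before/after classification test sweeps every
achievable decision threshold and reports the maximum accuracy. External
classifier scores are inputs; the built-in battery uses a self-contained
proxy detector (in-band energy fraction) so it can run without any
external model.

## Synthetic fixtures

The song generator is schematic, not a vocal-tract model: A songs are a
train of FM repeat elements (sweeping 0.80–0.98 of the peak frequency),
a main buzz (amplitude-modulated tone at the peak), and an optional hook
sweep (1.20 down to 0.70 of peak); B songs are an initial buzz, a short
connecting note, the main buzz, and an optional flourish. Component FM
trajectories hold their endpoint frequencies for the first and last
tenth of each component so the band extremes are sounded at full
amplitude — a labeling ground truth reached only inside an onset fade
would be invisible to any detector. Band edges (min/max instantaneous
frequency), durations, and repeat counts are emitted as metadata, which
is what makes the labeling and timing tests exact. Backgrounds are
colored noise (power ∝ 1/f^α, default α = 1) plus optional tones,
Poisson transients, and a <150 Hz rumble bed, optionally brick-walled at
`max_freq_hz` to build band-disjoint fixtures. Everything is
deterministic given a seed, and stage seeds fan out from one master seed
through a 31-bit string hash, so reruns are byte-identical.

What the fixtures do *not* emulate: real warbler formant structure,
reverberant site acoustics, recorder frequency response, or clock drift
between microphones. Passing tests show the pipeline's bookkeeping,
numerics, and separation-quality ordering are right under controlled
conditions; they do not certify performance on field recordings.

## Problem sizes

The test suite and acceptance script choose sizes that exercise every
code path while staying deterministic: 1,000 trials × 6-s mixtures for
the timing study, 100 trials per arm for the labeling and trilateration
comparisons, a 60-s input for the reconstruction identity, and 100
random cases for the BSS oracle equivalence. The evaluation battery
defaults are intentionally small (a few examples per sweep cell) and
scale up by argument.

## Known limitations

- The phase vocoder smears sharp transients, as phase vocoders do; the
  identity-parameter path bypasses resynthesis entirely.
- The spectral gate's self-estimated floor absorbs continuous tones
  (see above).
- Gain-only BSS-eval understates metrics relative to filter-allowed
  implementations.
- Three-microphone TDOA localization is fundamentally ambiguous for
  part of the sampling region; a fourth microphone, not a better
  solver, is the fix.
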