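# Evaluation mathematics. BSS-eval here is the gain-only (time-invariant
# scalar projection) variant: the estimate is decomposed into a target
# component (projection onto the target reference), an interference
# component (projection onto the span of all references, minus the
# target), and an artifact residual. The classical 512-tap filter-allowed
# variant is out of scope.

METRIC_CAP_DB <- 300  # serialization cap for the distinguished +Inf

#' BSS-eval SDR / SIR / SAR (gain-only projections)
#'
#' Decomposes `estimate = s_target + e_interf + e_artif` with
#' `s_target` the orthogonal projection of the estimate onto the target
#' reference, `e_interf` the projection onto the span of all references
#' minus `s_target`, and `e_artif` the residual, then reports
#' `SDR = 10 log10(|s_target|^2 / |e_interf + e_artif|^2)`,
#' `SIR = 10 log10(|s_target|^2 / |e_interf|^2)`,
#' `SAR = 10 log10(|s_target + e_interf|^2 / |e_artif|^2)`.
#' Perfect components yield the distinguished value `Inf`.
#'
#' @param estimate estimated source ([waveform()] or numeric).
#' @param references list of ground-truth source signals (equal lengths).
#' @param target_index which reference is the target (default 1).
#' @return list with `sdr_db`, `sir_db`, `sar_db`.
#' @export
bss_eval <- function(estimate, references, target_index = 1) {
  e <- as_samples(estimate)
  R <- vapply(references, as_samples, numeric(length(e)))
  tgt <- R[, target_index]
  if (sum(tgt^2) == 0) stop("zero-energy target reference")
  s_target <- sum(e * tgt) / sum(tgt^2) * tgt
  qrR <- qr(R)
  p_all <- qr.fitted(qrR, e)
  e_interf <- p_all - s_target
  e_artif <- e - p_all
  ratio_db <- function(num, den) {
    if (den <= .Machine$double.eps * num) return(Inf)
    10 * log10(num / den)
  }
  num_t <- sum(s_target^2)
  list(sdr_db = ratio_db(num_t, sum((e_interf + e_artif)^2)),
       sir_db = ratio_db(num_t, sum(e_interf^2)),
       sar_db = ratio_db(sum((s_target + e_interf)^2), sum(e_artif^2)))
}

as_samples <- function(x) if (is_waveform(x)) x$samples else as.numeric(x)

#' Scale-invariant SDR
#'
#' Projects the estimate onto the reference and reports
#' `10 log10(|proj|^2 / |estimate - proj|^2)`; invariant to rescaling of
#' the estimate, and the quantity whose negative is the usual training
#' loss of mask-based separators.
#'
#' @param estimate,reference equal-length signals.
#' @return SI-SDR in dB (possibly `Inf`).
#' @export
si_sdr <- function(estimate, reference) {
  e <- as_samples(estimate); r <- as_samples(reference)
  if (length(e) != length(r)) stop("length mismatch")
  if (sum(r^2) == 0) stop("zero reference")
  proj <- sum(e * r) / sum(r^2) * r
  err <- e - proj
  if (sum(err^2) <= .Machine$double.eps * sum(proj^2)) return(Inf)
  10 * log10(sum(proj^2) / sum(err^2))
}

#' Mean absolute percentage error
#'
#' @param estimates,truths equal-length numeric vectors; truths nonzero.
#' @return MAPE in percent.
#' @export
mape <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  if (any(truths == 0)) stop("truths must be nonzero")
  mean(100 * abs(estimates - truths) / abs(truths))
}

#' Cross-correlation lag between two signals
#'
#' Lag (integer samples, reported in seconds) maximizing the full
#' cross-correlation; positive lag means `b` is delayed relative to `a`.
#' Resolution is one sample period — 1/22050 s (about 45.4 microseconds)
#' at the pipeline's canonical rate; no sub-sample interpolation is done.
#'
#' @param a,b [waveform()]s at equal rates, or numeric vectors (then
#'   `rate` applies).
#' @param rate sampling rate used to convert samples to seconds when the
#'   inputs are bare vectors.
#' @return lag in seconds.
#' @export
xcorr_lag <- function(a, b, rate = NULL) {
  if (is_waveform(a) && is_waveform(b)) {
    if (a$rate != b$rate) stop("rates differ")
    rate <- a$rate
  }
  if (is.null(rate)) stop("rate needed for bare numeric inputs")
  x <- as_samples(a); y <- as_samples(b)
  if (all(x == 0) || all(y == 0)) stop("all-zero input; lag undefined")
  # c[l] = sum_t x[t] * y[t + l]; evaluate all l in -(ny-1)..(nx-1) via FFT
  nx <- length(x); ny <- length(y)
  nfft <- stats::nextn(nx + ny - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - nx)))
  Y <- stats::fft(c(y, numeric(nfft - ny)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  lags <- c(0:(nfft %/% 2), -((nfft - nfft %/% 2 - 1):1))
  valid <- lags >= -(nx - 1L) & lags <= (ny - 1L)
  i <- which(valid)[which.max(cc[valid])]
  lags[i] / rate
}

#' Ideal-threshold classification accuracy
#'
#' Sweeps every achievable decision threshold (midpoints between adjacent
#' sorted unique scores, plus the extremes) for the rule "score >=
#' threshold is positive" and returns the threshold maximizing overall
#' accuracy `(TP + TN) / (P + N)`; ties resolve to the lowest threshold.
#' This is the "best possible" detector accuracy before/after separation.
#'
#' @param pos_scores scores of positive examples.
#' @param neg_scores scores of negative examples.
#' @return list with `threshold` and `accuracy`.
#' @export
best_threshold_accuracy <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores)) stop("need both classes")
  s <- sort(unique(c(pos_scores, neg_scores)))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  acc <- vapply(cand, function(th)
    (sum(pos_scores >= th) + sum(neg_scores < th)) /
      (length(pos_scores) + length(neg_scores)), numeric(1))
  best <- which.max(acc)          # which.max takes the first (lowest) tie
  list(threshold = cand[best], accuracy = acc[best])
}

#' Serialize possibly-infinite dB metrics
#'
#' Caps `Inf` at 300 dB so metric tables serialize to plain numbers.
#' @param x numeric vector of dB values.
#' @return capped numeric vector.
#' @export
cap_db <- function(x) pmin(x, METRIC_CAP_DB)

#' Batch BSS metrics with summary confidence intervals
#'
#' @param pairs list of `list(estimate =, references =, target_index =)`.
#' @return list with `per_example` data frame and `summary` (mean and 90%
#'   normal-approximation confidence half-width per metric).
#' @export
bss_eval_batch <- function(pairs) {
  rows <- lapply(pairs, function(p) {
    m <- bss_eval(p$estimate, p$references,
                  if (is.null(p$target_index)) 1 else p$target_index)
    data.frame(sdr_db = cap_db(m$sdr_db), sir_db = cap_db(m$sir_db),
               sar_db = cap_db(m$sar_db))
  })
  per <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("sdr_db", "sir_db", "sar_db"),
    mean = vapply(per, mean, numeric(1)),
    ci90 = vapply(per, ci90_halfwidth, numeric(1)))
  list(per_example = per, summary = summ)
}
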