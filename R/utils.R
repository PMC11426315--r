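# Shared internals: seeded evaluation, deterministic seed fan-out, fast
# rolling statistics, and FFT convolution.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

#' Deterministic per-stage seed fan-out
#'
#' Derives a child seed from a master seed, a stage label, and an item
#' index, so parallel or re-ordered stages draw independent, reproducible
#' random streams. Uses a 31-bit multiplicative string hash; the result is
#' always a valid R integer seed.
#'
#' @param master_seed integer master seed.
#' @param stage character stage label.
#' @param index item index within the stage (default 0).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
fanout_seed <- function(master_seed, stage, index = 0) {
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(as.character(stage)))
    h <- (h * 131 + b) %% m
  h <- (h * 131 + as.numeric(index) + 1) %% m
  as.integer(h %% (m - 1) + 1)
}

# centered rolling sum with truncated (partial) edge windows, O(n)
rolling_sum <- function(x, width) {
  n <- length(x)
  half_l <- (width - 1L) %/% 2L
  half_r <- width - 1L - half_l
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  cs[hi + 1L] - cs[lo]
}

# centered rolling maximum with truncated edges (van Herk / Gil-Werman:
# block-wise prefix and suffix cummax), O(n)
rolling_max <- function(x, width) {
  n <- length(x)
  if (width <= 1L) return(x)
  half_l <- (width - 1L) %/% 2L
  half_r <- width - 1L - half_l
  xp <- c(rep(-Inf, half_l), x, rep(-Inf, half_r))
  np <- length(xp)
  k <- as.integer(ceiling(np / width))
  pad <- k * width - np
  xp2 <- c(xp, rep(-Inf, pad))
  m <- matrix(xp2, nrow = width)
  pref <- apply(m, 2, cummax)
  suff <- apply(m[width:1, , drop = FALSE], 2, cummax)[width:1, , drop = FALSE]
  pref <- as.vector(pref); suff <- as.vector(suff)
  i <- seq_len(n)            # window over xp: [i, i + width - 1]
  out <- pmax(suff[i], pref[i + width - 1L])
  out
}

# linear convolution via FFT, length la + lb - 1
fft_convolve <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- stats::nextn(la + lb - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(a, numeric(n - la))) *
                     stats::fft(c(b, numeric(n - lb))), inverse = TRUE)) / n
  y[seq_len(la + lb - 1L)]
}

# 90% normal-approximation confidence half-width of a mean
ci90_halfwidth <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::qnorm(0.95) * stats::sd(x) / sqrt(length(x))
}
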