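# Independent oracles used to validate the implementation.

# Exhaustive O(n^2) dynamic program for penalized mean-shift segmentation
# under the same cost convention as the package detector: segment cost
# RSS/sigma^2 + log(len/n), per-change-point penalty 3*log(n). No pruning.
dp_segment_oracle <- function(x, min_seglen = 10, noise_sd = NULL,
                              penalty = NULL) {
  n <- length(x)
  sigma <- noise_sd
  if (is.null(sigma)) {
    d <- diff(x)
    sigma <- stats::mad(d) / sqrt(2)
    if (!is.finite(sigma) || sigma == 0) sigma <- stats::sd(d) / sqrt(2)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    return(list(cps = integer(0), cost = 0))
  }
  beta <- if (is.null(penalty)) 3 * log(n) else penalty
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  seg_cost <- function(i, j) {
    l <- j - i
    (s2[j + 1] - s2[i + 1] - (s1[j + 1] - s1[i + 1])^2 / l) / sigma^2 +
      log(l / n)
  }
  f <- rep(Inf, n + 1)
  f[1] <- -beta
  back <- rep(NA_integer_, n + 1)
  for (t in seq_len(n)) {
    if (t < min_seglen) next
    for (s in c(0, seq_len(t - min_seglen))) {
      if (s > 0 && (s < min_seglen || !is.finite(f[s + 1]))) next
      v <- f[s + 1] + seg_cost(s, t) + beta
      if (v < f[t + 1]) {
        f[t + 1] <- v
        back[t + 1] <- s
      }
    }
  }
  cps <- integer(0)
  t <- n
  while (!is.na(back[t + 1]) && back[t + 1] > 0) {
    t <- back[t + 1]
    cps <- c(t, cps)
  }
  list(cps = cps, cost = f[n + 1])
}

# Smoothed-periodogram estimate of the fraction of total power inside a band.
band_power_fraction <- function(x, fs, f_lo, f_hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(11, 11),
                          taper = 0.1, detrend = TRUE, plot = FALSE)
  sum(sp$spec[sp$freq >= f_lo & sp$freq <= f_hi]) / sum(sp$spec)
}

# Frequency of the raw periodogram maximum.
periodogram_peak_hz <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  sp$freq[which.max(sp$spec)]
}
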