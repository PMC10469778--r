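#' Notch out mains line noise and its harmonics
#'
#' Removes 60 Hz line noise and its 120/180 Hz harmonics with narrow
#' second-order IIR notch filters (quality factor `q`), each applied
#' forward-backward so the cascade is zero-phase. Each biquad places a true
#' spectral zero at its notch frequency, so attenuation at the notch is
#' essentially complete while gain a few Hz away is preserved.
#'
#' @param x Numeric vector, one channel of samples.
#' @param fs Sampling rate in Hz; must exceed twice the highest notch
#'   frequency.
#' @param base Fundamental line frequency in Hz (default 60).
#' @param harmonics Harmonic frequencies in Hz to notch as well
#'   (default 120 and 180).
#' @param bandwidth_hz Absolute -3 dB notch width in Hz (default 2, i.e.
#'   quality factor 30 at the 60 Hz fundamental). A constant absolute width
#'   keeps the passband within 5% at frequencies 5 Hz or more away from
#'   every notch, including the 180 Hz harmonic.
#' @return Numeric vector of filtered samples, same length as `x`.
#' @examples
#' fs <- 1000
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 25 * t) + sin(2 * pi * 60 * t)
#' y <- notch_line_noise(x, fs)
#' @export
notch_line_noise <- function(x, fs, base = 60, harmonics = c(120, 180),
                             bandwidth_hz = 2) {
  freqs <- c(base, harmonics)
  assert_scalar_num(fs, "fs", lower = 0, strict = TRUE)
  if (fs <= 2 * max(freqs)) {
    stop("fs must exceed twice the highest notch frequency (",
         max(freqs), " Hz)", call. = FALSE)
  }
  y <- as.numeric(x)
  for (f0 in freqs) {
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) / (2 * f0 / bandwidth_hz)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    y <- signal::filtfilt(signal::Arma(b = b / a[1], a = a / a[1]), y)
  }
  y
}

#' Zero-phase Butterworth sub-band band-pass
#'
#' Band-passes one channel into a canonical sub-band with a 3rd-order digital
#' Butterworth filter applied forward-backward (`signal::filtfilt`), giving a
#' zero-phase 6th-order magnitude response.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz; the upper band edge must lie below Nyquist.
#' @param band Sub-band name (see [subbands()]) or a list/row with `f_lo` and
#'   `f_hi` in Hz.
#' @param order Butterworth prototype order (default 3).
#' @return Filtered samples, same length as `x`.
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 16 * seq(0, 2, by = 1 / fs))
#' y <- bandpass_subband(x, fs, "beta_l")
#' @export
bandpass_subband <- function(x, fs, band, order = 3) {
  if (is.character(band)) band <- band_row(band)
  f_lo <- band$f_lo
  f_hi <- band$f_hi
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_lo >= f_hi) {
    stop("band must define 0 < f_lo < f_hi", call. = FALSE)
  }
  if (f_hi >= fs / 2) {
    stop("band edge ", f_hi, " Hz at or above Nyquist (fs = ", fs, " Hz)",
         call. = FALSE)
  }
  bt <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  signal::filtfilt(bt, as.numeric(x))
}

#' Analytic signal via the Hilbert transform
#'
#' Computes the analytic extension `x + i * H[x]` of a real signal by the
#' standard FFT construction (doubling positive frequencies, zeroing negative
#' ones). The modulus of the result is the instantaneous amplitude and its
#' argument the instantaneous phase.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("signal too short for an analytic extension", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous bandpower from the analytic amplitude
#'
#' Squared modulus of the analytic signal: `P(t) = |x(t) + i H[x](t)|^2`.
#' For a pure sinusoid of amplitude A the interior of `P` equals `A^2`;
#' convolution edge effects distort roughly the first and last 100 ms, which
#' is why trial epochs carry pads that are discarded downstream.
#'
#' @param x Band-limited (already band-passed) real samples.
#' @param fs Sampling rate in Hz (carried as an attribute).
#' @param min_len Minimum accepted length in samples (default 16).
#' @return Numeric vector of nonnegative instantaneous power values with
#'   attributes `fs` and `edge_margin_s` (the declared unreliable margin).
#' @examples
#' fs <- 500
#' p <- analytic_power(2 * cos(2 * pi * 20 * seq(0, 1, by = 1 / fs)), fs)
#' mean(p[100:400]) # ~ 4
#' @export
analytic_power <- function(x, fs, min_len = 16) {
  x <- as.numeric(x)
  if (length(x) < min_len) {
    stop("signal shorter than the minimum window (", min_len, " samples)",
         call. = FALSE)
  }
  p <- Mod(analytic_signal(x))^2
  attr(p, "fs") <- fs
  attr(p, "edge_margin_s") <- 0.1
  p
}

#' Average instantaneous bandpower over channels
#'
#' Sums per-channel instantaneous power series and divides by the number of
#' valid channels.
#'
#' @param per_channel A list of equal-length numeric power series, or a
#'   channels-by-samples matrix.
#' @param n_channels Optional channel count to divide by; defaults to the
#'   number of series supplied.
#' @return Numeric vector: the per-sample channel-average power.
#' @export
average_channel_power <- function(per_channel, n_channels = NULL) {
  if (is.matrix(per_channel)) {
    per_channel <- lapply(seq_len(nrow(per_channel)),
                          function(i) per_channel[i, ])
  }
  lens <- lengths(per_channel)
  if (length(unique(lens)) != 1L) {
    stop("power series have mismatched lengths", call. = FALSE)
  }
  if (is.null(n_channels)) n_channels <- length(per_channel)
  if (n_channels != length(per_channel)) {
    stop("n_channels (", n_channels, ") does not match the number of series (",
         length(per_channel), ")", call. = FALSE)
  }
  Reduce(`+`, per_channel) / n_channels
}

#' Merge a low/high sub-band pair into its parent band
#'
#' Element-wise mean of the low and high sub-band power series, producing the
#' merged beta (12-35 Hz), gamma (35-70 Hz) or Gamma (70-140 Hz) bandpower.
#'
#' @param p_lo,p_hi Equal-length numeric power series for the low and high
#'   member of one pair.
#' @param band Optional merged-band name (`"beta"`, `"gamma"` or `"Gamma"`)
#'   used to tag the output.
#' @return Numeric vector with attributes `band`, `f_lo`, `f_hi` when `band`
#'   is given.
#' @export
merge_band <- function(p_lo, p_hi, band = NULL) {
  if (length(p_lo) != length(p_hi)) {
    stop("sub-band series have mismatched lengths", call. = FALSE)
  }
  out <- (as.numeric(p_lo) + as.numeric(p_hi)) / 2
  if (!is.null(band)) {
    mb <- merged_bands()
    i <- match(band, mb$band)
    if (is.na(i)) stop("unknown merged band: ", band, call. = FALSE)
    attr(out, "band") <- band
    attr(out, "f_lo") <- mb$f_lo[i]
    attr(out, "f_hi") <- mb$f_hi[i]
  }
  out
}
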