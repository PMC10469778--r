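#' Canonical trial grid
#'
#' Sample counts and boundaries of the fixed-length normalized trial:
#' 500 ms ISP1, consonant normalized to the average consonant length
#' (107 ms), vowel normalized to the average vowel length (388 ms), and
#' 500 ms ISP2. Segment lengths are `round(duration * fs)` (ties to even),
#' giving e.g. 1526 + 327 + 1184 + 1526 = 4563 samples at 3052 Hz.
#'
#' @param fs Sampling rate in Hz.
#' @param isp_s,consonant_s,vowel_s Segment durations in seconds.
#' @return List with `lengths` (named: isp1, consonant, vowel, isp2),
#'   `boundaries` (cumulative indices: ISP1 end, CV transition, vowel end)
#'   and `total`.
#' @export
canonical_grid <- function(fs, isp_s = 0.5, consonant_s = 0.107,
                           vowel_s = 0.388) {
  lens <- c(isp1 = round(isp_s * fs), consonant = round(consonant_s * fs),
            vowel = round(vowel_s * fs), isp2 = round(isp_s * fs))
  list(lengths = lens, boundaries = unname(cumsum(lens)[1:3]),
       total = sum(lens))
}

#' Derive inter-speech (ISP) intervals from speech annotations
#'
#' The i-th inter-speech interval runs from the end of utterance i to the
#' start of utterance i+1.
#'
#' @param annotations Data.frame with `start_s` and `end_s` columns, ordered
#'   and non-overlapping.
#' @return Data.frame with `start_s`, `end_s`; `n_utterances - 1` rows.
#' @examples
#' ann <- data.frame(start_s = c(0.2, 1.8, 3.0), end_s = c(1.0, 2.5, 3.6))
#' derive_isp_intervals(ann)
#' @export
derive_isp_intervals <- function(annotations) {
  n <- nrow(annotations)
  if (n < 2) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  s <- annotations$start_s
  e <- annotations$end_s
  if (any(e[-n] > s[-1])) {
    stop("annotations overlap: an utterance ends after the next one starts",
         call. = FALSE)
  }
  data.frame(start_s = e[-n], end_s = s[-1])
}

#' Build ISP1-CV-ISP2 trials with inclusion rules
#'
#' Applies, in order, the trial filters: (1) boundary exclusion of the first
#' and last utterance (their flanking ISP is undefined); (2) exclusion of
#' trials whose analyzed intervals intersect an annotated invalid interval;
#' (3) the vowel filter (final vowel of the syllable label must match
#' `vowel_filter`); (4) the minimum-ISP rule (both flanking gaps at least
#' `min_isp_ms`). Surviving trials keep only the 500 ms of each ISP nearest
#' the CV interval, plus `pad_ms` of extra signal on each side used solely to
#' absorb filter/Hilbert edge effects. A trial failing several rules is
#' tallied under the first failing rule in the stated order.
#'
#' @param session An `"ecog_session"`.
#' @param min_isp_ms Minimum flanking ISP duration (ms), also the kept ISP
#'   length.
#' @param vowel_filter Final-vowel label to keep (default `"i"`).
#' @param pad_ms Edge pad attached to each side (ms).
#' @return An object of class `"ecog_trial_set"`: a list with `trials`
#'   (data.frame, one row per candidate utterance, with timing, label,
#'   `included` flag and exclusion `reason`), `tally` (named exclusion
#'   counts), `epochs` (list of sample-index layouts for included trials)
#'   and the epoch parameters.
#' @export
build_trials <- function(session, min_isp_ms = 500, vowel_filter = "i",
                         pad_ms = 500) {
  ann <- session$annotations
  fs <- session$sample_rate_hz
  n <- nrow(ann)
  if (n < 3) stop("need at least 3 utterances to form one interior trial",
                  call. = FALSE)
  min_isp <- min_isp_ms / 1000
  pad <- pad_ms / 1000
  n_samples <- ncol(session$csep)

  isp1_len <- c(NA, ann$start_s[-1] - ann$end_s[-n])
  isp2_len <- c(isp1_len[-1], NA)
  final_vowel <- substr(ann$label, nchar(ann$label), nchar(ann$label))

  reason <- rep(NA_character_, n)
  reason[c(1, n)] <- "boundary"
  inv <- session$invalid_intervals
  for (j in seq_len(n)) {
    if (!is.na(reason[j])) next
    # analyzed extent: clipped ISPs (bounded by the neighbouring utterances)
    a0 <- max(ann$end_s[j - 1], ann$start_s[j] - min_isp)
    a1 <- min(ann$start_s[j + 1], ann$end_s[j] + min_isp)
    if (nrow(inv) && intervals_overlap(a0, a1, inv$start_s, inv$end_s)) {
      reason[j] <- "invalid_overlap"
    }
  }
  sel <- is.na(reason) & final_vowel != vowel_filter
  reason[sel] <- "vowel"
  sel <- is.na(reason) & (isp1_len < min_isp | isp2_len < min_isp)
  reason[sel] <- "short_isp"

  isp_n <- round(min_isp * fs)
  pad_n <- round(pad * fs)
  epochs <- list()
  for (j in which(is.na(reason))) {
    start_i <- round(ann$start_s[j] * fs) # 0-based sample of speech start
    c_n <- round((ann$cv_s[j] - ann$start_s[j]) * fs)
    v_n <- round((ann$end_s[j] - ann$cv_s[j]) * fs)
    first <- start_i - isp_n - pad_n
    last <- start_i + c_n + v_n + isp_n + pad_n # exclusive
    if (first < 0 || last > n_samples) {
      reason[j] <- "boundary"
      next
    }
    epochs[[length(epochs) + 1]] <- list(
      utterance = j, first = first, last = last,
      seg_lengths = c(pad = pad_n, isp1 = isp_n, consonant = c_n,
                      vowel = v_n, isp2 = isp_n),
      label = ann$label[j]
    )
  }

  trials <- data.frame(
    utterance = seq_len(n),
    start_s = ann$start_s, cv_s = ann$cv_s, end_s = ann$end_s,
    label = ann$label, isp1_s = isp1_len, isp2_s = isp2_len,
    included = is.na(reason), reason = reason,
    stringsAsFactors = FALSE
  )
  tally <- c(boundary = sum(reason == "boundary", na.rm = TRUE),
             invalid_overlap = sum(reason == "invalid_overlap", na.rm = TRUE),
             vowel = sum(reason == "vowel", na.rm = TRUE),
             short_isp = sum(reason == "short_isp", na.rm = TRUE))
  structure(list(trials = trials, tally = tally, epochs = epochs,
                 fs = fs, min_isp_ms = min_isp_ms, pad_ms = pad_ms,
                 vowel_filter = vowel_filter),
            class = "ecog_trial_set")
}

#' @export
print.ecog_trial_set <- function(x, ...) {
  cat("<ecog_trial_set>", sum(x$trials$included), "included /",
      nrow(x$trials), "candidate trials\n")
  cat("  excluded:", paste(names(x$tally), x$tally, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Band-limited (periodic sinc) resampling of an interval
#'
#' Resamples a series to an exact target length through the frequency
#' domain: the FFT is truncated or zero-padded to the target length with the
#' usual Nyquist-bin bookkeeping, which is equivalent to periodic sinc
#' interpolation. Constant inputs are preserved exactly; an identity target
#' length returns the input unchanged.
#'
#' @param x Numeric vector, length >= 2.
#' @param target_len Desired output length (>= 2).
#' @return Numeric vector of length `target_len`.
#' @examples
#' resample_interval(rep(1, 13), 327)[1:5]
#' @export
resample_interval <- function(x, target_len) {
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(target_len)
  if (n < 2 || m < 2) {
    stop("resampling needs input and target lengths >= 2", call. = FALSE)
  }
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  nkeep <- min(n, m)
  npos <- (nkeep + 1) %/% 2          # positive-frequency bins incl. DC
  nneg <- (nkeep - 1) %/% 2          # strictly negative-frequency bins
  Y[seq_len(npos)] <- X[seq_len(npos)]
  if (nneg > 0) {
    Y[(m - nneg + 1):m] <- X[(n - nneg + 1):n]
  }
  if (nkeep %% 2 == 0) {
    k <- nkeep %/% 2 + 1             # Nyquist bin of the shorter grid
    if (m < n) {
      Y[k] <- X[k] + X[n - nkeep %/% 2 + 1]
    } else {
      Y[k] <- X[k] / 2
      Y[m - nkeep %/% 2 + 1] <- Y[k]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) * (1 / n)
}

#' Assemble one trial's fixed-length bandpower time course
#'
#' Truncates the edge pads from a padded trial power series, resamples the
#' consonant and vowel segments to the canonical average lengths (periodic
#' sinc), keeps the two 500 ms ISP segments as-is, and concatenates the
#' result into the canonical fixed-length trial series.
#'
#' @param p Numeric power series covering pad+ISP1+C+V+ISP2+pad.
#' @param seg_lengths Named integer vector with `pad`, `isp1`, `consonant`,
#'   `vowel`, `isp2` sample counts (as produced by [build_trials()]).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `canonical_grid(fs)$total` with
#'   attribute `boundaries`.
#' @export
assemble_timecourse <- function(p, seg_lengths, fs) {
  need <- c("pad", "isp1", "consonant", "vowel", "isp2")
  if (!all(need %in% names(seg_lengths))) {
    stop("seg_lengths must name ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sl <- seg_lengths
  tot <- 2 * sl[["pad"]] + sl[["isp1"]] + sl[["consonant"]] + sl[["vowel"]] +
    sl[["isp2"]]
  if (length(p) != tot) {
    stop("power series length ", length(p), " does not match segment layout (",
         tot, ")", call. = FALSE)
  }
  grid <- canonical_grid(fs)
  o <- sl[["pad"]]
  take <- function(k) {
    seg <- p[(o + 1):(o + k)]
    o <<- o + k
    seg
  }
  isp1 <- take(sl[["isp1"]])
  cons <- take(sl[["consonant"]])
  vow <- take(sl[["vowel"]])
  isp2 <- take(sl[["isp2"]])
  out <- c(isp1,
           resample_interval(cons, grid$lengths[["consonant"]]),
           resample_interval(vow, grid$lengths[["vowel"]]),
           isp2)
  stopifnot(length(out) == grid$total)
  attr(out, "boundaries") <- grid$boundaries
  out
}

#' Z-score a session's trial time courses
#'
#' Standardizes all canonical trial series of one session and band against
#' the pooled mean and standard deviation over every sample of every
#' included trial, so the concatenated session samples have mean 0 and
#' standard deviation 1.
#'
#' @param trials Trials-by-time numeric matrix (one band, one session).
#' @return Matrix of the same shape, z-scored; attributes `mu` and `sigma`
#'   record the session moments.
#' @export
zscore_session <- function(trials) {
  if (!is.matrix(trials) || nrow(trials) < 2) {
    stop("session z-scoring needs >= 2 trials", call. = FALSE)
  }
  mu <- mean(trials)
  sigma <- stats::sd(as.vector(trials))
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate session: zero variance in trial bandpower",
         call. = FALSE)
  }
  z <- (trials - mu) / sigma
  attr(z, "mu") <- mu
  attr(z, "sigma") <- sigma
  z
}

#' Grand-average time course across sessions
#'
#' Pointwise mean of per-session mean time courses with a per-sample
#' dispersion estimate: the across-session standard deviation divided by
#' `sqrt(N)` (standard error) or, optionally, by `N`.
#'
#' @param session_means Sessions-by-time numeric matrix.
#' @param se_divisor `"sqrt_n"` (default) or `"n"`.
#' @return List with `mean`, `se`, `n` and any `boundaries` attribute carried
#'   from the inputs.
#' @export
grand_average <- function(session_means, se_divisor = c("sqrt_n", "n")) {
  se_divisor <- match.arg(se_divisor)
  if (!is.matrix(session_means)) session_means <- rbind(session_means)
  ns <- nrow(session_means)
  m <- colMeans(session_means)
  sdv <- apply(session_means, 2, stats::sd)
  if (ns == 1) sdv <- rep(0, ncol(session_means))
  div <- if (se_divisor == "sqrt_n") sqrt(ns) else ns
  list(mean = m, se = sdv / div, n = ns,
       boundaries = attr(session_means, "boundaries"))
}
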