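#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of comparisons (>= 1). Fifteen for the 6-band correlation
#'   grids: `choose(6, 2)`.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 15) # ~0.003
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  assert_scalar_num(m, "m", lower = 1)
  alpha / m
}

interval_slice <- function(boundaries, total, interval) {
  b <- c(0, boundaries, total)
  k <- match(interval, c("ISP1", "consonant", "vowel", "ISP2"))
  if (is.na(k)) stop("unknown interval: ", interval, call. = FALSE)
  (b[k] + 1):(b[k + 1])
}

cor_grid <- function(mat, alpha = 0.05) {
  k <- nrow(mat)
  nvar <- apply(mat, 1, stats::var)
  if (any(!is.finite(nvar)) || any(nvar == 0)) {
    stop("undefined correlation: a band has zero variance over the interval",
         call. = FALSE)
  }
  n <- ncol(mat)
  if (n < 3) stop("interval has fewer than 3 samples", call. = FALSE)
  r <- stats::cor(t(mat))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  m <- choose(k, 2)
  a_crit <- bonferroni_threshold(alpha, m)
  mask <- p < a_crit
  diag(mask) <- FALSE
  list(r = r, p = p, alpha = alpha, m = m, alpha_critical = a_crit,
       mask = mask, n = n)
}

#' Pairwise sub-band correlations within one trial interval
#'
#' Pearson product-moment correlations (with two-tailed p-values) between all
#' pairs of z-scored sub-band time courses over the samples of one canonical
#' trial interval, compared against the Bonferroni-corrected level
#' `alpha / choose(k, 2)` (15 unique pairs for 6 bands).
#'
#' @param timecourses Named list of equal-length numeric series (one per
#'   sub-band), or a bands-by-time matrix with row names.
#' @param boundaries Canonical segment boundaries (ISP1 end, CV transition,
#'   vowel end) in samples.
#' @param interval One of `"ISP1"`, `"consonant"`, `"vowel"`, `"ISP2"`.
#' @param alpha Family-wise level (default 0.05).
#' @return Object of class `"ecog_cor_grid"`: symmetric `r` and `p`
#'   matrices, `alpha`, `m`, `alpha_critical`, a significance `mask` and the
#'   interval sample count `n`.
#' @export
interval_correlations <- function(timecourses, boundaries,
                                  interval = c("ISP1", "consonant", "vowel",
                                               "ISP2"),
                                  alpha = 0.05) {
  interval <- match.arg(interval)
  mat <- if (is.matrix(timecourses)) timecourses else
    do.call(rbind, timecourses)
  idx <- interval_slice(boundaries, ncol(mat), interval)
  g <- cor_grid(mat[, idx, drop = FALSE], alpha)
  g$interval <- interval
  class(g) <- "ecog_cor_grid"
  g
}

#' @export
print.ecog_cor_grid <- function(x, ...) {
  cat("<ecog_cor_grid>", x$interval %||% "", "n =", x$n,
      " alpha_critical =", signif(x$alpha_critical, 3), "\n")
  print(round(x$r, 2))
  invisible(x)
}

#' Correlations over a window centred on the CV transition
#'
#' Pairwise sub-band Pearson correlations over
#' `[cv - width/2, cv + width/2)`, the consonant-movement-length window
#' centred at the consonant-vowel transition used to probe local
#' high-gamma/beta coupling at the transition.
#'
#' @inheritParams interval_correlations
#' @param width Window width in samples (default: one canonical consonant
#'   length is a natural choice).
#' @return An `"ecog_cor_grid"` whose `window` field holds the sample bounds.
#' @export
cv_centered_correlations <- function(timecourses, boundaries, width,
                                     alpha = 0.05) {
  mat <- if (is.matrix(timecourses)) timecourses else
    do.call(rbind, timecourses)
  width <- as.integer(width)
  if (width < 3) stop("window width must be >= 3 samples", call. = FALSE)
  cv <- boundaries[2]
  first <- cv - width %/% 2 # 0-based start of half-open window
  last <- first + width
  if (first < 0 || last > ncol(mat)) {
    stop("CV-centred window [", first, ", ", last,
         ") falls outside the series", call. = FALSE)
  }
  g <- cor_grid(mat[, (first + 1):last, drop = FALSE], alpha)
  g$interval <- "cv_centered"
  g$window <- c(first = first, last = last)
  class(g) <- "ecog_cor_grid"
  g
}

#' Local extrema within each trial interval
#'
#' Strict interior local maxima and minima of a series inside each canonical
#' interval (endpoints excluded).
#'
#' @param series Numeric vector (one band's canonical time course).
#' @param boundaries Canonical segment boundaries in samples.
#' @return Data.frame with `interval`, `type` (`"max"`/`"min"`), `index`
#'   (1-based position in the full series) and `value`.
#' @export
local_extrema <- function(series, boundaries) {
  out <- list()
  for (iv in c("ISP1", "consonant", "vowel", "ISP2")) {
    idx <- interval_slice(boundaries, length(series), iv)
    if (length(idx) < 3) next
    x <- series[idx]
    i <- 2:(length(x) - 1)
    is_max <- x[i] > x[i - 1] & x[i] > x[i + 1]
    is_min <- x[i] < x[i - 1] & x[i] < x[i + 1]
    if (any(is_max)) {
      out[[length(out) + 1]] <- data.frame(
        interval = iv, type = "max", index = idx[i[is_max]],
        value = x[i[is_max]], stringsAsFactors = FALSE)
    }
    if (any(is_min)) {
      out[[length(out) + 1]] <- data.frame(
        interval = iv, type = "min", index = idx[i[is_min]],
        value = x[i[is_min]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(interval = character(0), type = character(0),
                      index = integer(0), value = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$index), , drop = FALSE]
}

#' Gaussian-wavelet correlation map
#'
#' Correlates zero-mean, unit-energy Gaussian templates of widths
#' `sigma` (standard deviation, in samples; support truncated at +/- 4
#' sigma) with a series at every time point. Positive coefficients mark
#' peak-like features at that scale, negative coefficients troughs; a
#' constant input maps to (numerically) zero everywhere because the
#' templates are zero-mean.
#'
#' @param series Numeric vector, longer than the largest template support.
#' @param sigma Vector of template widths in samples (default `1:42`).
#' @return Object of class `"ecog_wavelet_map"`: `sigma` and a
#'   `length(sigma)` x `length(series)` coefficient matrix (`NA` where the
#'   template support overruns the edges).
#' @export
gaussian_wavelet_map <- function(series, sigma = 1:42) {
  x <- as.numeric(series)
  max_support <- 2 * ceiling(4 * max(sigma)) + 1
  if (length(x) <= max_support) {
    stop("series (", length(x), " samples) not longer than the largest ",
         "wavelet support (", max_support, ")", call. = FALSE)
  }
  coef <- matrix(NA_real_, nrow = length(sigma), ncol = length(x))
  for (i in seq_along(sigma)) {
    h <- ceiling(4 * sigma[i])
    u <- (-h):h
    g <- exp(-u^2 / (2 * sigma[i]^2))
    g <- g - mean(g)
    g <- g / sqrt(sum(g^2))
    coef[i, ] <- as.numeric(stats::filter(x, g, method = "convolution",
                                          sides = 2))
  }
  structure(list(sigma = sigma, coef = coef), class = "ecog_wavelet_map")
}

# ---- change-point detection -------------------------------------------------

# Segment cost on (i, j]: RSS / sigma^2 plus the modified-BIC segment-length
# term log(len / n). Computed from cumulative sums.
mbic_cost_fn <- function(x, sigma2) {
  n <- length(x)
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  function(i, j) {
    l <- j - i
    rss <- s2[j + 1] - s2[i + 1] - (s1[j + 1] - s1[i + 1])^2 / l
    rss / sigma2 + log(l / n)
  }
}

estimate_noise_sd <- function(x) {
  d <- diff(x)
  s <- stats::mad(d) / sqrt(2)
  if (!is.finite(s) || s == 0) s <- stats::sd(d) / sqrt(2)
  s
}

#' PELT change-point detection with a modified BIC penalty
#'
#' Exact penalized segmentation of a series under a normal mean-shift cost,
#' solved with the Pruned Exact Linear Time (PELT) dynamic program. The
#' penalty follows the modified Bayesian Information Criterion for
#' mean-shift models on the -2 log-likelihood scale: each segment
#' contributes `RSS / sigma^2 + log(len / n)` and each additional change
#' point costs `3 log(n)`. Pruning uses the constant `K = log(n)`, which
#' bounds the subadditivity defect of the segment-length term, so the
#' segmentation equals the exhaustive optimum.
#'
#' @param x Numeric series.
#' @param min_seglen Minimum segment length in samples (default 10).
#' @param noise_sd Noise scale used to normalize the cost. Default `NULL`
#'   estimates it from the median absolute successive difference
#'   (appropriate for approximately white noise); pass an externally known
#'   scale (e.g. a grand-average standard error) when the noise is
#'   temporally correlated.
#' @param penalty Per-change-point penalty; default `3 * log(n)`.
#' @return Integer vector of strictly increasing interior change points,
#'   each the index of the last sample of a segment (empty when the series
#'   is best described by a single segment). Attribute `cost` holds the
#'   total penalized cost.
#' @examples
#' detect_change_points(c(rep(0, 40), rep(1, 40)))
#' @export
detect_change_points <- function(x, min_seglen = 10, noise_sd = NULL,
                                 penalty = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (min_seglen < 1) stop("min_seglen must be >= 1", call. = FALSE)
  if (n < 2 * min_seglen) {
    out <- integer(0)
    attr(out, "cost") <- NA_real_
    return(out)
  }
  sigma <- if (is.null(noise_sd)) estimate_noise_sd(x) else noise_sd
  if (!is.finite(sigma) || sigma <= 0) {
    # constant series: one segment, no change points
    out <- integer(0)
    attr(out, "cost") <- 0
    return(out)
  }
  beta <- if (is.null(penalty)) 3 * log(n) else penalty
  cost <- mbic_cost_fn(x, sigma^2)
  K <- log(n)

  f <- rep(Inf, n + 1) # f[t+1] = optimal cost of x[1..t]
  f[1] <- -beta
  prev <- rep(NA_integer_, n + 1)
  cands <- 0L
  for (t in seq_len(n)) {
    valid <- cands[t - cands >= min_seglen]
    if (!length(valid)) next
    base <- f[valid + 1] + vapply(valid, function(s) cost(s, t), 0)
    b <- which.min(base)
    f[t + 1] <- base[b] + beta
    prev[t + 1] <- valid[b]
    keep <- base + K <= f[t + 1]
    cands <- c(valid[keep], cands[t - cands < min_seglen])
    if (is.finite(f[t + 1])) cands <- c(cands, t)
  }
  cps <- integer(0)
  t <- n
  while (!is.na(prev[t + 1]) && prev[t + 1] > 0) {
    t <- prev[t + 1]
    cps <- c(t, cps)
  }
  out <- as.integer(cps)
  attr(out, "cost") <- f[n + 1]
  out
}

#' Interval means between change points
#'
#' @param x Numeric series.
#' @param cps Interior change points as returned by
#'   [detect_change_points()].
#' @return Data.frame with `interval` (I1..IK), `first`, `last` (1-based,
#'   inclusive) and `mean`.
#' @export
changepoint_interval_means <- function(x, cps) {
  edges <- c(0, cps, length(x))
  k <- length(edges) - 1
  data.frame(
    interval = paste0("I", seq_len(k)),
    first = edges[-length(edges)] + 1L,
    last = edges[-1],
    mean = vapply(seq_len(k),
                  function(i) mean(x[(edges[i] + 1):edges[i + 1]]), 0),
    stringsAsFactors = FALSE
  )
}

#' Pre-movement ERD onset from a change-point segmentation
#'
#' Estimates when a beta-band series starts to decline from its pre-movement
#' maximum: among the change-point intervals ending at or before consonant
#' movement onset, the one with the largest mean is the pre-movement
#' maximum, and its right edge is where the event-related
#' desynchronization begins.
#'
#' @param series Canonical-grid numeric series (typically a grand-average
#'   beta sub-band time course).
#' @param cps Interior change points from [detect_change_points()].
#' @param onset_idx Sample index of consonant movement onset (the ISP1/
#'   consonant boundary).
#' @return The ERD onset as a sample index (the last sample of the maximal
#'   pre-onset interval), or `NA` if no interval ends before onset.
#' @export
erd_onset <- function(series, cps, onset_idx) {
  ivm <- changepoint_interval_means(series, cps)
  pre <- ivm[ivm$last <= onset_idx, , drop = FALSE]
  if (!nrow(pre)) return(NA_integer_)
  pre$last[which.max(pre$mean)]
}

# ---- mixed-effects interval inference --------------------------------------

#' Linear mixed-effects model over change-point intervals with LRT
#'
#' Fits, by maximum likelihood, a linear mixed-effects model of average
#' bandpower per change-point interval with a fixed effect of interval and a
#' random intercept per session, and compares it with a chi-squared
#' likelihood-ratio test against the null model omitting the interval
#' predictor. One observation per session per interval.
#'
#' @param data Data.frame with columns `session`, `interval` and `power`.
#' @return Object of class `"ecog_interval_lme"`: the fitted `model` and
#'   `null_model`, `chisq`, `df` (= K - 1), `p`, per-interval estimated
#'   means, the number of sessions, and a `singular` flag (a singular random
#'   effect fit is flagged, not dropped).
#' @export
interval_lme_lrt <- function(data) {
  need <- c("session", "interval", "power")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data$session <- factor(data$session)
  data$interval <- factor(data$interval, levels = unique(data$interval))
  k <- nlevels(data$interval)
  if (k < 2) stop("need >= 2 intervals", call. = FALSE)
  if (nlevels(data$session) < 2) stop("need >= 2 sessions", call. = FALSE)
  full <- suppressMessages(
    lme4::lmer(power ~ interval + (1 | session), data = data, REML = FALSE))
  null <- suppressMessages(
    lme4::lmer(power ~ 1 + (1 | session), data = data, REML = FALSE))
  chisq <- as.numeric(2 * (stats::logLik(full) - stats::logLik(null)))
  df <- k - 1
  p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
  fe <- lme4::fixef(full)
  means <- fe[1] + c(0, fe[-1])
  names(means) <- levels(data$interval)
  structure(list(model = full, null_model = null, chisq = chisq, df = df,
                 p = p, interval_means = means,
                 n_sessions = nlevels(data$session), k = k,
                 singular = lme4::isSingular(full)),
            class = "ecog_interval_lme")
}

#' @export
print.ecog_interval_lme <- function(x, ...) {
  cat(sprintf("<ecog_interval_lme> chi^2(%d) = %.4g, p = %.3g (%d sessions, %d intervals)%s\n",
              x$df, x$chisq, x$p, x$n_sessions, x$k,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Tukey post hoc pairwise interval comparisons
#'
#' All `choose(K, 2)` pairwise comparisons of interval means from a fitted
#' interval model, with Tukey HSD family-wise adjustment; an optional
#' second-stage Bonferroni factor across band-wise families is reported as a
#' separate column (both stages are kept visible rather than collapsed).
#'
#' @param fit An `"ecog_interval_lme"` (or a fitted `lmerMod` with an
#'   `interval` fixed effect).
#' @param df_method Degrees-of-freedom method for the contrasts:
#'   `"satterthwaite"` (needs lmerTest; accurate for small interval counts)
#'   or `"asymptotic"` (z statistics; used for large interval counts).
#' @param bonferroni_families Number of band families tested in parallel
#'   (multiplies the Tukey-adjusted p in `p_bonferroni`; default 1).
#' @return Data.frame with `contrast`, `estimate`, `se`, `df`, `stat`,
#'   `p_tukey` and `p_bonferroni`.
#' @export
tukey_pairwise <- function(fit, df_method = c("satterthwaite", "asymptotic"),
                           bonferroni_families = 1) {
  df_method <- match.arg(df_method)
  model <- if (inherits(fit, "ecog_interval_lme")) fit$model else fit
  k <- if (inherits(fit, "ecog_interval_lme")) fit$k else
    length(unique(stats::model.frame(model)$interval))
  if (k < 2) stop("pairwise comparisons need >= 2 intervals", call. = FALSE)
  if (df_method == "satterthwaite" &&
      !requireNamespace("lmerTest", quietly = TRUE)) {
    df_method <- "asymptotic"
  }
  emm <- emmeans::emmeans(model, ~interval, lmer.df = df_method)
  pr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  out <- data.frame(
    contrast = as.character(pr$contrast),
    estimate = pr$estimate,
    se = pr$SE,
    df = pr$df,
    stat = if (!is.null(pr$t.ratio)) pr$t.ratio else pr$z.ratio,
    p_tukey = pr$p.value,
    stringsAsFactors = FALSE
  )
  out$p_bonferroni <- pmin(1, out$p_tukey * bonferroni_families)
  out
}
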