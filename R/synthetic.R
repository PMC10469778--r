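#' Default per-sub-band envelope event templates
#'
#' Piecewise-linear amplitude-envelope templates encoding the qualitative
#' event structure of sensorimotor bandpower around a consonant-vowel (CV)
#' syllable flanked by inter-utterance speech posture (ISP) intervals:
#'
#' * beta sub-bands hold a high ISP plateau, start to decline `lead_s`
#'   (default 0.4 s) before consonant movement onset, reach their trial
#'   minimum early in the vowel, rise to a local peak before vowel
#'   termination, dip briefly at termination, then rebound to the ISP
#'   plateau (ERD at movement, ERS/rebound at rest).
#' * gamma/high-gamma sub-bands mirror this: a low ISP plateau, a rise
#'   starting `lead_s` (default 0.3 s) before onset, a peak near the CV
#'   transition (mid-vowel for low gamma), and a decline back to the ISP
#'   minimum after vowel termination.
#'
#' Node times are anchored to the trial annotations: `ref` is one of
#' `"isp1_start"`, `"onset"`, `"consonant"`, `"cv"`, `"vowel"`, `"end"`,
#' `"isp2_end"`; `offset_s` shifts anchors in seconds (used for the
#' pre-onset lead and post-termination events) and `frac` places a node at a
#' fraction of the consonant or vowel interval.
#'
#' @return Named list (one element per sub-band) of lists with `lead_s` and a
#'   `nodes` data.frame (`ref`, `offset_s`, `frac`, `level`).
#' @export
default_envelope_params <- function() {
  node <- function(ref, offset_s = 0, frac = NA_real_, level) {
    data.frame(ref = ref, offset_s = offset_s, frac = frac, level = level,
               stringsAsFactors = FALSE)
  }
  beta_nodes <- function(lead, onset_lev, bump, cv_lev, peak_lev, end_lev,
                         dip_lev) {
    rbind(
      node("isp1_start", level = 1.0),
      node("onset", offset_s = -lead, level = 1.0),
      if (is.null(bump)) NULL else node("consonant", frac = 0.5, level = bump),
      node("onset", level = onset_lev),
      node("cv", level = cv_lev),
      node("vowel", frac = 0.15, level = 0.20),
      node("vowel", frac = 0.85, level = peak_lev),
      node("end", level = end_lev),
      node("end", offset_s = 0.06, level = dip_lev),
      node("end", offset_s = 0.25, level = 1.0),
      node("isp2_end", level = 1.0)
    )
  }
  # order within a trial must be monotone in time; the beta_h consonant bump
  # node sits between onset and cv so the frame is reordered below
  order_nodes <- function(nd) {
    rank <- c(isp1_start = 1, onset = 2, consonant = 3, cv = 4, vowel = 5,
              end = 6, isp2_end = 7)
    key <- rank[nd$ref] + ifelse(is.na(nd$frac), 0, nd$frac / 10) +
      nd$offset_s / 100
    nd[order(key), , drop = FALSE]
  }
  gamma_hi <- rbind(
    node("isp1_start", level = 0.25),
    node("onset", offset_s = -0.3, level = 0.25),
    node("onset", level = 0.60),
    node("cv", level = 1.0),
    node("vowel", frac = 0.20, level = 0.80),
    node("end", level = 0.35),
    node("end", offset_s = 0.06, level = 0.30),
    node("end", offset_s = 0.25, level = 0.22),
    node("isp2_end", level = 0.20)
  )
  list(
    beta_l = list(lead_s = 0.4, nodes = order_nodes(
      beta_nodes(0.4, 0.72, NULL, 0.55, 0.78, 0.70, 0.55))),
    beta_h = list(lead_s = 0.4, nodes = order_nodes(
      beta_nodes(0.4, 0.70, 0.74, 0.62, 0.82, 0.72, 0.52))),
    gamma_l = list(lead_s = 0.3, nodes = rbind(
      node("isp1_start", level = 0.30),
      node("onset", offset_s = -0.3, level = 0.22),
      node("onset", level = 0.45),
      node("cv", level = 0.70),
      node("vowel", frac = 0.35, level = 1.0),
      node("end", level = 0.45),
      node("end", offset_s = 0.06, level = 0.60),
      node("end", offset_s = 0.25, level = 0.30),
      node("isp2_end", level = 0.25)
    )),
    gamma_h = list(lead_s = 0.3, nodes = gamma_hi),
    Gamma_l = list(lead_s = 0.3, nodes = gamma_hi),
    Gamma_h = list(lead_s = 0.3, nodes = gamma_hi)
  )
}

resolve_node_times <- function(nodes, timing) {
  cons_len <- timing$cv - timing$onset
  vow_len <- timing$end - timing$cv
  t <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    t[i] <- switch(nodes$ref[i],
      isp1_start = timing$isp1_start,
      onset      = timing$onset + nodes$offset_s[i],
      consonant  = timing$onset + nodes$frac[i] * cons_len,
      cv         = timing$cv + nodes$offset_s[i],
      vowel      = timing$cv + nodes$frac[i] * vow_len,
      end        = timing$end + nodes$offset_s[i],
      isp2_end   = timing$isp2_end,
      stop("unknown node anchor: ", nodes$ref[i], call. = FALSE)
    )
  }
  t
}

#' Sampled envelope template for one trial
#'
#' Resolves a sub-band's event-node template against one trial's annotation
#' timing and samples the piecewise-linear envelope on a regular grid over
#' `[isp1_start, isp2_end)`.
#'
#' @param band Sub-band name (see [subbands()]).
#' @param timing List with `isp1_start`, `onset`, `cv`, `end`, `isp2_end`
#'   times in seconds; must be strictly increasing.
#' @param params Envelope parameter list as from
#'   [default_envelope_params()].
#' @param fs Sampling rate in Hz.
#' @return List with `t` (sample times), `env` (nonnegative envelope values),
#'   and `nodes` (data.frame of resolved node times and levels).
#' @examples
#' tm <- list(isp1_start = 0.5, onset = 1, cv = 1.1, end = 1.5, isp2_end = 2)
#' e <- make_envelope_template("beta_h", tm, fs = 1000)
#' e$nodes$t[2] # decline node 400 ms before onset
#' @export
make_envelope_template <- function(band, timing,
                                   params = default_envelope_params(),
                                   fs = 1000) {
  need <- c("isp1_start", "onset", "cv", "end", "isp2_end")
  if (!all(need %in% names(timing))) {
    stop("timing must supply ", paste(need, collapse = ", "), call. = FALSE)
  }
  tv <- unlist(timing[need])
  if (any(diff(tv) <= 0)) {
    stop("trial timing must be strictly increasing", call. = FALSE)
  }
  p <- params[[band]]
  if (is.null(p)) stop("no envelope params for band ", band, call. = FALSE)
  if (any(p$nodes$level < 0)) {
    stop("envelope node levels must be nonnegative", call. = FALSE)
  }
  nt <- resolve_node_times(p$nodes, timing)
  if (any(diff(nt) <= 0)) {
    stop("resolved node times are not strictly increasing; ",
         "trial too short for the configured leads/offsets", call. = FALSE)
  }
  tt <- seq(timing$isp1_start, timing$isp2_end - 1 / fs, by = 1 / fs)
  env <- stats::approx(nt, p$nodes$level, xout = tt, rule = 2)$y
  list(t = tt, env = env,
       nodes = data.frame(t = nt, level = p$nodes$level, ref = p$nodes$ref,
                          stringsAsFactors = FALSE))
}

#' Simulation configuration for a synthetic ECoG session
#'
#' Bundles and validates every knob of the synthetic session generator.
#' Defaults emulate the shape of a consonant-vowel syllable reading session:
#' utterance gaps with median ~825 ms, consonant/vowel durations with means
#' ~110/~390 ms, one third of syllables ending in /i/, 60/120/180 Hz line
#' noise, 1/f broadband noise and a fraction of artifact-dominated bad
#' channels.
#'
#' @param n_channels Number of recorded channels.
#' @param sample_rate_hz Sampling rate; must exceed 280 Hz (twice the 140 Hz
#'   upper sub-band edge). 1000 Hz by default; configurable up to 3052 Hz.
#' @param n_utterances Number of uttered syllables in the session.
#' @param syllables Character pool of syllable labels sampled uniformly.
#' @param consonant_ms,vowel_ms,isp_ms Length-2 ranges (ms) for uniform draws
#'   of consonant, vowel and inter-utterance gap durations.
#' @param envelope_params Per-band envelope templates
#'   ([default_envelope_params()]).
#' @param carrier_amp Carrier RMS amplitude (a.u.) multiplying each band
#'   envelope.
#' @param line_noise_amp Amplitude (a.u.) of the 60 Hz line component; the
#'   120/180 Hz harmonics carry 0.4x and 0.25x that amplitude, with a random
#'   per-channel gain so common-average referencing cannot cancel it exactly.
#' @param broadband_noise_sd RMS (a.u.) of the 1/f broadband noise floor.
#' @param broadband_noise_exponent Spectral slope of the broadband noise
#'   (power ~ 1/f^exponent).
#' @param bad_channel_fraction Fraction in `[0, 1)` of channels replaced by
#'   large low-frequency artifact.
#' @param n_invalid_intervals Number of annotated invalid (artifact) time
#'   intervals per session.
#' @param invalid_interval_s Duration (s) of each invalid interval.
#' @param seed Integer seed; the generated session is fully determined by the
#'   configuration including the seed.
#' @return A validated list of class `"ecog_sim_config"`.
#' @export
sim_config <- function(n_channels = 8,
                       sample_rate_hz = 1000,
                       n_utterances = 155,
                       syllables = c("ba", "bi", "bu", "da", "di", "du",
                                     "ga", "gi", "gu"),
                       consonant_ms = c(60, 160),
                       vowel_ms = c(250, 530),
                       isp_ms = c(500, 1150),
                       envelope_params = default_envelope_params(),
                       carrier_amp = 1,
                       line_noise_amp = 0.5,
                       broadband_noise_sd = 0.25,
                       broadband_noise_exponent = 1,
                       bad_channel_fraction = 0.125,
                       n_invalid_intervals = 1,
                       invalid_interval_s = 1.5,
                       seed = 1L) {
  assert_scalar_num(n_channels, "n_channels", lower = 2)
  assert_scalar_num(sample_rate_hz, "sample_rate_hz", lower = 2 * 140,
                    strict = TRUE)
  assert_scalar_num(n_utterances, "n_utterances", lower = 1)
  for (nm in c("consonant_ms", "vowel_ms", "isp_ms")) {
    r <- get(nm)
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      stop(nm, " must be a positive, ordered length-2 range", call. = FALSE)
    }
  }
  assert_scalar_num(bad_channel_fraction, "bad_channel_fraction",
                    lower = 0, upper = 1 - 1e-9)
  assert_scalar_num(line_noise_amp, "line_noise_amp", lower = 0)
  assert_scalar_num(broadband_noise_sd, "broadband_noise_sd", lower = 0)
  cfg <- list(
    n_channels = as.integer(n_channels),
    sample_rate_hz = sample_rate_hz,
    n_utterances = as.integer(n_utterances),
    syllables = syllables,
    consonant_ms = consonant_ms, vowel_ms = vowel_ms, isp_ms = isp_ms,
    envelope_params = envelope_params,
    carrier_amp = carrier_amp,
    line_noise_amp = line_noise_amp,
    broadband_noise_sd = broadband_noise_sd,
    broadband_noise_exponent = broadband_noise_exponent,
    bad_channel_fraction = bad_channel_fraction,
    n_invalid_intervals = as.integer(n_invalid_intervals),
    invalid_interval_s = invalid_interval_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "ecog_sim_config"
  cfg
}

pink_noise <- function(n, exponent, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index, DC guarded
  shape <- 1 / f^(exponent / 2)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x * sd_target / stats::sd(x)
}

#' Generate a synthetic ECoG session with known ground truth
#'
#' Builds a multi-channel cortical-surface-potential matrix in which each
#' good channel is a sum over the six sub-bands of envelope-modulated
#' band-limited Gaussian-noise carriers, plus 1/f broadband noise and
#' 60/120/180 Hz line noise; bad channels are replaced by high-amplitude
#' low-frequency artifact. Per-utterance annotations (speech start, CV
#' transition, speech end, syllable label) and invalid intervals are emitted
#' alongside the exact envelope node ground truth.
#'
#' @param config An [sim_config()] object.
#' @param subject_id,session_id Metadata labels.
#' @return List with elements `session` (class `"ecog_session"`) and `truth`
#'   (class `"ecog_ground_truth"`).
#' @export
generate_session <- function(config = sim_config(), subject_id = "S1",
                             session_id = "ses-01") {
  stopifnot(inherits(config, "ecog_sim_config"))
  fs <- config$sample_rate_hz
  set.seed(config$seed)

  nu <- config$n_utterances
  margin <- 1.2
  cons <- stats::runif(nu, config$consonant_ms[1], config$consonant_ms[2]) / 1000
  vow <- stats::runif(nu, config$vowel_ms[1], config$vowel_ms[2]) / 1000
  gaps <- stats::runif(nu - 1, config$isp_ms[1], config$isp_ms[2]) / 1000
  starts <- numeric(nu)
  starts[1] <- margin
  if (nu > 1) {
    for (k in 2:nu) starts[k] <- starts[k - 1] + cons[k - 1] + vow[k - 1] + gaps[k - 1]
  }
  cvs <- starts + cons
  ends <- cvs + vow
  labels <- sample(config$syllables, nu, replace = TRUE)
  duration <- ends[nu] + margin
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs

  bands <- subbands()$band
  # ground-truth global envelope per band: baseline plateaus joined through
  # the per-utterance event nodes
  band_nodes <- list()
  envs <- matrix(0, nrow = length(bands), ncol = n,
                 dimnames = list(bands, NULL))
  for (b in bands) {
    p <- config$envelope_params[[b]]
    base_first <- p$nodes$level[p$nodes$ref == "isp1_start"][1]
    base_last <- p$nodes$level[p$nodes$ref == "isp2_end"][1]
    inner <- p$nodes[!(p$nodes$ref %in% c("isp1_start", "isp2_end")), ,
                     drop = FALSE]
    nt <- c(0)
    nl <- c(base_first)
    for (k in seq_len(nu)) {
      timing <- list(isp1_start = NA, onset = starts[k], cv = cvs[k],
                     end = ends[k], isp2_end = NA)
      t_k <- resolve_node_times(inner, timing)
      # the pre-onset lead node is the anchored event; when the previous
      # utterance's post-termination nodes would overrun it (short gaps),
      # compress the earlier rebound rather than delaying the lead node
      keep <- nt < t_k[1] - 1 / fs
      nt <- c(nt[keep], t_k)
      nl <- c(nl[keep], inner$level)
    }
    nt <- c(nt, duration)
    nl <- c(nl, base_last)
    for (i in 2:length(nt)) if (nt[i] <= nt[i - 1]) nt[i] <- nt[i - 1] + 1 / fs
    envs[b, ] <- stats::approx(nt, nl, xout = tt, rule = 2)$y
    band_nodes[[b]] <- data.frame(t = nt, level = nl)
  }

  n_bad <- floor(config$bad_channel_fraction * config$n_channels)
  bad_idx <- if (n_bad > 0) sort(sample(config$n_channels, n_bad)) else integer(0)

  line_phase <- stats::runif(3, 0, 2 * pi)
  csep <- matrix(0, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    if (ch %in% bad_idx) {
      # low-frequency high-amplitude artifact: removable only by exclusion
      csep[ch, ] <- 25 * sin(2 * pi * 0.6 * tt + stats::runif(1, 0, 2 * pi)) +
        5 + pink_noise(n, 2, 3)
      next
    }
    x <- numeric(n)
    for (b in bands) {
      carrier <- bandpass_subband(stats::rnorm(n), fs, b)
      carrier <- carrier / stats::sd(carrier)
      x <- x + config$carrier_amp * envs[b, ] * carrier
    }
    x <- x + pink_noise(n, config$broadband_noise_exponent,
                        config$broadband_noise_sd)
    gain <- stats::runif(1, 0.7, 1.3)
    x <- x + config$line_noise_amp * gain *
      (sin(2 * pi * 60 * tt + line_phase[1]) +
         0.4 * sin(2 * pi * 120 * tt + line_phase[2]) +
         0.25 * sin(2 * pi * 180 * tt + line_phase[3]))
    csep[ch, ] <- x
  }

  invalid <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (config$n_invalid_intervals > 0) {
    s0 <- sort(stats::runif(config$n_invalid_intervals, margin,
                            duration - margin - config$invalid_interval_s))
    invalid <- data.frame(start_s = s0, end_s = s0 + config$invalid_interval_s)
  }

  annotations <- data.frame(start_s = starts, cv_s = cvs, end_s = ends,
                            label = labels, stringsAsFactors = FALSE)
  session <- structure(list(
    subject_id = subject_id, session_id = session_id,
    sample_rate_hz = fs, csep = csep,
    annotations = annotations, invalid_intervals = invalid,
    smc_indices = seq_len(config$n_channels), bad_indices = bad_idx
  ), class = "ecog_session")
  truth <- structure(list(
    band_nodes = band_nodes,
    leads_s = vapply(config$envelope_params, `[[`, numeric(1), "lead_s"),
    bad_indices = bad_idx,
    annotations = annotations,
    seed = config$seed
  ), class = "ecog_ground_truth")
  list(session = session, truth = truth)
}

#' @export
print.ecog_session <- function(x, ...) {
  cat("<ecog_session> subject", x$subject_id, "session", x$session_id, "\n")
  cat("  ", nrow(x$csep), "channels x", ncol(x$csep), "samples @",
      x$sample_rate_hz, "Hz\n")
  cat("  ", nrow(x$annotations), "annotated utterances,",
      length(x$bad_indices), "bad channel(s)\n")
  invisible(x)
}

#' Ground-truth envelope on the canonical trial grid
#'
#' Samples a sub-band's envelope template over the canonical
#' ISP1 / consonant / vowel / ISP2 trial layout (0.5 / 0.107 / 0.388 / 0.5 s)
#' used by [assemble_timecourse()], so that recovered z-scored bandpower time
#' courses can be compared against known truth. Power follows the squared
#' envelope, so the squared template is returned alongside.
#'
#' @param band Sub-band name.
#' @param fs Sampling rate of the canonical grid (Hz).
#' @param params Envelope parameter list.
#' @return List with `env`, `power` (= env^2), `boundaries` (ISP1 end, CV,
#'   vowel end, in canonical samples) and `erd_onset_s` (time of the
#'   pre-movement decline/rise node on the canonical grid).
#' @export
canonical_template <- function(band, fs = 1000,
                               params = default_envelope_params()) {
  seg <- canonical_grid(fs)
  timing <- list(isp1_start = 0, onset = 0.5, cv = 0.607, end = 0.995,
                 isp2_end = 1.495)
  tot <- sum(seg$lengths)
  tt <- (seq_len(tot) - 1) / fs
  p <- params[[band]]
  nt <- resolve_node_times(p$nodes, timing)
  env <- stats::approx(nt, p$nodes$level, xout = tt, rule = 2)$y
  list(env = env, power = env^2, boundaries = seg$boundaries,
       erd_onset_s = 0.5 - p$lead_s)
}

#' Write a session plus ground truth as a plain-text fixture
#'
#' Persists a session in the package's self-describing fixture layout: a
#' directory holding `meta.json` (metadata, channel sets, invalid intervals,
#' ground truth), `annotations.csv` (one row per utterance: `start_s`,
#' `cv_s`, `end_s`, `label`) and `csep.csv` (samples in rows, channels in
#' columns `ch1..chN`).
#'
#' @param session An `"ecog_session"`.
#' @param truth Optional `"ecog_ground_truth"` to embed.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session_fixture <- function(session, truth = NULL, path) {
  stopifnot(inherits(session, "ecog_session"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok || !dir.exists(path)) {
    stop("cannot create fixture directory: ", path, call. = FALSE)
  }
  meta <- list(
    schema = "ecogposture-fixture",
    schema_version = 1L,
    subject_id = session$subject_id,
    session_id = session$session_id,
    sample_rate_hz = session$sample_rate_hz,
    n_channels = nrow(session$csep),
    n_samples = ncol(session$csep),
    smc_indices = as.integer(session$smc_indices),
    bad_indices = as.integer(session$bad_indices),
    invalid_intervals = session$invalid_intervals
  )
  if (!is.null(truth)) {
    meta$ground_truth <- list(
      band_nodes = truth$band_nodes,
      leads_s = as.list(truth$leads_s),
      bad_indices = as.integer(truth$bad_indices),
      seed = truth$seed
    )
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  data.table::fwrite(session$annotations, file.path(path, "annotations.csv"))
  m <- data.table::as.data.table(t(session$csep))
  data.table::setnames(m, paste0("ch", seq_len(nrow(session$csep))))
  data.table::fwrite(m, file.path(path, "csep.csv"))
  invisible(path)
}
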