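# In-code fixtures shared across test files.

# A minimal hand-built session around explicit annotations; flat zero signal
# is enough for the epoching logic, which never looks at the samples.
fake_session <- function(annotations, fs = 1000, n_channels = 2,
                         invalid = NULL, tail_s = 2) {
  dur <- max(annotations$end_s) + tail_s
  if (is.null(invalid)) {
    invalid <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  structure(list(
    subject_id = "T0", session_id = "test", sample_rate_hz = fs,
    csep = matrix(0, nrow = n_channels, ncol = round(dur * fs)),
    annotations = annotations, invalid_intervals = invalid,
    smc_indices = seq_len(n_channels), bad_indices = integer(0)
  ), class = "ecog_session")
}

# Annotations with given inter-utterance gaps (s); utterance k spans
# [start, start + cons + vow] with the CV transition after the consonant.
gap_annotations <- function(gaps, cons = 0.15, vow = 0.35, label = "di",
                            first_start = 1.5) {
  n <- length(gaps) + 1
  starts <- numeric(n)
  starts[1] <- first_start
  for (k in seq_along(gaps)) {
    starts[k + 1] <- starts[k] + cons + vow + gaps[k]
  }
  data.frame(start_s = starts, cv_s = starts + cons,
             end_s = starts + cons + vow,
             label = rep_len(label, n), stringsAsFactors = FALSE)
}

# Small synthetic collection for pipeline-level tests (kept light; the
# full-size default collection is exercised by the acceptance tests).
small_pipeline_config <- function(seed = 11, n_sessions = 3) {
  pipeline_config(
    n_sessions = n_sessions,
    sim = sim_config(n_channels = 4, n_utterances = 40, seed = 1),
    seed = seed
  )
}

run_small_pipeline_cached <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$report)) {
      cache$report <- suppressMessages(run_pipeline(small_pipeline_config()))
    }
    cache$report
  }
})
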