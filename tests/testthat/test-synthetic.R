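test_that("envelope templates place the pre-movement event nodes at the configured leads", {
  timing <- list(isp1_start = 0.4, onset = 1.000, cv = 1.107, end = 1.495,
                 isp2_end = 2.0)
  for (b in c("beta_l", "beta_h")) {
    e <- make_envelope_template(b, timing, fs = 1000)
    # the beta decline starts from the plateau node 400 ms before onset
    decline <- e$nodes[e$nodes$ref == "onset", ]
    expect_equal(decline$t[1], 0.600)
    expect_equal(decline$level[1], max(e$nodes$level))
  }
  for (b in c("gamma_h", "Gamma_l", "Gamma_h")) {
    e <- make_envelope_template(b, timing, fs = 1000)
    rise <- e$nodes[e$nodes$ref == "onset", ]
    expect_equal(rise$t[1], 0.700) # 300 ms gamma rise lead
  }
})

test_that("envelopes are piecewise linear, nonnegative and bounded by their node levels", {
  timing <- list(isp1_start = 0, onset = 1, cv = 1.12, end = 1.5,
                 isp2_end = 2.1)
  for (b in subbands()$band) {
    e <- make_envelope_template(b, timing, fs = 500)
    expect_true(all(e$env >= 0))
    expect_gte(min(e$env), min(e$nodes$level) - 1e-12)
    expect_lte(max(e$env), max(e$nodes$level) + 1e-12)
  }
  # all node levels equal -> constant envelope
  flat <- default_envelope_params()
  flat$beta_l$nodes$level <- 0.7
  e <- make_envelope_template("beta_l", timing, params = flat, fs = 500)
  expect_equal(e$env, rep(0.7, length(e$env)))
})

test_that("unordered trial timing is rejected", {
  bad <- list(isp1_start = 0, onset = 1, cv = 0.9, end = 1.5, isp2_end = 2)
  expect_error(make_envelope_template("beta_l", bad, fs = 500),
               "strictly increasing")
  cramped <- list(isp1_start = 0.9, onset = 1, cv = 1.1, end = 1.5,
                  isp2_end = 1.55)
  expect_error(make_envelope_template("beta_l", cramped, fs = 500))
})

test_that("session generation is fully determined by the seed", {
  cfg <- sim_config(n_channels = 3, n_utterances = 8, seed = 99)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$session$csep, b$session$csep)
  expect_identical(a$session$annotations, b$session$annotations)
  expect_identical(a$truth$band_nodes, b$truth$band_nodes)
  c <- generate_session(sim_config(n_channels = 3, n_utterances = 8,
                                   seed = 100))
  expect_false(identical(a$session$csep, c$session$csep))
})

test_that("dominant line noise shows up as a 60 Hz periodogram peak on good channels", {
  cfg <- sim_config(n_channels = 3, n_utterances = 6, carrier_amp = 0.05,
                    line_noise_amp = 10, broadband_noise_sd = 0.05,
                    bad_channel_fraction = 0, seed = 5)
  g <- generate_session(cfg)
  peak <- periodogram_peak_hz(g$session$csep[1, ], cfg$sample_rate_hz)
  expect_lt(abs(peak - 60), 0.5)
})

test_that("a lone sub-band carrier concentrates its power inside the band", {
  # silence every band but one and strip the noise terms, then check the
  # emitted channel against a periodogram band-power oracle
  for (target in c("beta_l", "Gamma_h")) {
    pars <- default_envelope_params()
    for (b in names(pars)) {
      pars[[b]]$nodes$level <- if (b == target) 1 else 0
    }
    cfg <- sim_config(n_channels = 2, n_utterances = 6,
                      envelope_params = pars, line_noise_amp = 0,
                      broadband_noise_sd = 0, bad_channel_fraction = 0,
                      seed = 21)
    g <- generate_session(cfg)
    row <- subbands()[subbands()$band == target, ]
    frac <- band_power_fraction(g$session$csep[1, ], cfg$sample_rate_hz,
                                row$f_lo, row$f_hi)
    expect_gte(frac, 0.9)
  }
})

test_that("bad channels carry large low-frequency artifact and are listed in the ground truth", {
  cfg <- sim_config(n_channels = 8, n_utterances = 6,
                    bad_channel_fraction = 0.25, seed = 3)
  g <- generate_session(cfg)
  expect_length(g$truth$bad_indices, 2)
  expect_identical(g$session$bad_indices, g$truth$bad_indices)
  bad <- g$session$csep[g$truth$bad_indices[1], ]
  good <- g$session$csep[setdiff(1:8, g$truth$bad_indices)[1], ]
  expect_gt(stats::sd(bad), 3 * stats::sd(good))
  expect_lt(periodogram_peak_hz(bad, cfg$sample_rate_hz), 2)
})

test_that("fixtures round-trip through write and read", {
  cfg <- sim_config(n_channels = 3, n_utterances = 6, seed = 14)
  g <- generate_session(cfg)
  path <- file.path(tempdir(), "fixture-roundtrip")
  write_session_fixture(g$session, g$truth, path)
  s2 <- read_session(path)
  expect_equal(s2$csep, g$session$csep, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(s2$annotations$cv_s, g$session$annotations$cv_s)
  expect_identical(s2$bad_indices, as.integer(g$session$bad_indices))
  expect_identical(s2$smc_indices, as.integer(g$session$smc_indices))
  expect_equal(s2$sample_rate_hz, g$session$sample_rate_hz)
  expect_equal(as.data.frame(s2$invalid_intervals),
               g$session$invalid_intervals, ignore_attr = TRUE)
  unlink(path, recursive = TRUE)
})

test_that("fixtures missing mandatory fields are rejected on read", {
  cfg <- sim_config(n_channels = 2, n_utterances = 4, seed = 15)
  g <- generate_session(cfg)
  path <- file.path(tempdir(), "fixture-broken")
  write_session_fixture(g$session, NULL, path)
  ann <- read.csv(file.path(path, "annotations.csv"))
  write.csv(ann[, setdiff(names(ann), "cv_s")],
            file.path(path, "annotations.csv"), row.names = FALSE)
  expect_error(read_session(path), "cv_s")
  file.remove(file.path(path, "meta.json"))
  expect_error(read_session(path), "meta.json")
  expect_error(read_session(file.path(tempdir(), "no-such-dir")), "no such")
  unlink(path, recursive = TRUE)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(sample_rate_hz = 250), "sample_rate_hz")
  expect_error(sim_config(bad_channel_fraction = 1), "bad_channel_fraction")
  expect_error(sim_config(isp_ms = c(500, 400)), "isp_ms")
  expect_error(sim_config(consonant_ms = c(-10, 50)), "consonant_ms")
})
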