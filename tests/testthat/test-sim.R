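test_that("SSVEP epochs have the canonical size and a spectral peak at the stimulus", {
  cfg <- signal_model_config()
  ep <- make_ssvep_epoch(10, cfg, seed = 0)
  expect_s3_class(ep, "eeg_epoch")
  expect_length(ep$samples, 1000L)
  expect_equal(ep$label, "ssvep_10")

  # at very high SNR the raw-epoch DFT peaks at the stimulus bin
  cfg_hi <- signal_model_config(snr_db = 60)
  ep_hi <- make_ssvep_epoch(10, cfg_hi, seed = 4)
  mag <- Mod(stats::fft(ep_hi$samples))[2:500]     # positive bins, DC dropped
  expect_equal(which.max(mag) * cfg$fs / 1000, 10)
})

test_that("in the noise-free limit a single-harmonic epoch is a pure sinusoid", {
  cfg <- signal_model_config(n_harmonics = 1, snr_db = 240)
  ep <- make_ssvep_epoch(12, cfg, seed = 2)
  t <- (0:999) / cfg$fs
  # recover amplitude/phase by least squares and compare pointwise
  X <- cbind(sin(2 * pi * 12 * t), cos(2 * pi * 12 * t))
  fit <- lm.fit(X, ep$samples)
  expect_lt(max(abs(fit$residuals)), 1e-6 * max(abs(ep$samples)))
})

test_that("spectral correctness holds across all six frequencies and seeds", {
  cfg <- signal_model_config(snr_db = 20)
  for (f in cfg$ssvep_freqs) {
    for (s in 1:10) {
      ep <- make_ssvep_epoch(f, cfg, seed = 1000 + s)
      mag <- Mod(stats::fft(ep$samples))[2:500]
      peak_hz <- which.max(mag) * cfg$fs / 1000
      expect_equal(peak_hz, round(f * cfg$duration) * cfg$fs / 1000,
                   tolerance = 1e-9,
                   label = sprintf("peak for %g Hz seed %d", f, s))
    }
  }
})

test_that("unknown stimulus frequency is rejected naming the valid set", {
  cfg <- signal_model_config()
  expect_error(make_ssvep_epoch(9, cfg), "6.6, 7.5, 8.57, 10, 11, 12")
})

test_that("blink epochs contain the right number of threshold-crossing pulses", {
  cfg <- signal_model_config()
  bg_rms <- sqrt(2 * (1 - cfg$shared_noise_frac)) * cfg$noise_rms_uv
  single <- make_blink_epoch("single", cfg, seed = 0)
  expect_equal(single$label, "single_blink")
  expect_equal(count_pulses(single$samples, 4 * bg_rms)$n, 1L)

  double <- make_blink_epoch("double", cfg, seed = 0)
  expect_equal(double$label, "double_blink")
  cp <- count_pulses(double$samples, 4 * bg_rms)
  expect_equal(cp$n, 2L)
  gap_s <- diff(cp$centers) / cfg$fs
  expect_lt(abs(gap_s - cfg$double_blink_gap_s), cfg$blink_width_s / 2)
})

test_that("blink pulse counts are right over many seeds and vanish at zero amplitude", {
  cfg <- signal_model_config()
  bg_rms <- sqrt(2 * (1 - cfg$shared_noise_frac)) * cfg$noise_rms_uv
  for (s in 1:100) {
    expect_equal(count_pulses(make_blink_epoch("single", cfg, seed = s)$samples,
                              4 * bg_rms)$n, 1L,
                 label = paste("single blink seed", s))
    expect_equal(count_pulses(make_blink_epoch("double", cfg, seed = s)$samples,
                              4 * bg_rms)$n, 2L,
                 label = paste("double blink seed", s))
  }
  flat <- signal_model_config(blink_amp_factor = 0)
  expect_equal(count_pulses(make_blink_epoch("single", flat, seed = 0)$samples,
                            4 * bg_rms)$n, 0L)
})

test_that("datasets are balanced, subject-tagged and deterministic", {
  cfg <- signal_model_config()
  ds <- make_dataset(cfg, n_subjects = 1, n_trials_per_task = 1, seed = 5)
  expect_equal(nrow(ds$samples), 8L)
  expect_true(all(table(ds$labels) == 1L))

  ds2 <- make_dataset(cfg, n_subjects = 2, n_trials_per_task = 3, seed = 9)
  expect_equal(nrow(ds2$samples), 48L)
  expect_true(all(table(ds2$labels) == 6L))
  expect_equal(sort(unique(ds2$subject)), 1:2)

  ds3 <- make_dataset(cfg, n_subjects = 2, n_trials_per_task = 3, seed = 9)
  expect_identical(ds2$samples, ds3$samples)
  expect_identical(ds2$labels, ds3$labels)
})

test_that("simulator rejects invalid configurations", {
  expect_error(signal_model_config(fs = 500, duration = 1.0015),
               "integer sample count")
  expect_error(signal_model_config(ssvep_freqs = c(6.6, 7.5, 8.57, 10, 11, 300)),
               "Nyquist")
  expect_error(signal_model_config(ssvep_freqs = c(6.6, 6.6, 8.57, 10, 11, 12)),
               "distinct")
  expect_error(signal_model_config(duration = 0.6, double_blink_gap_s = 0.5),
               "does not fit")
})

test_that("session streams realize the scripted intents with a ground-truth log", {
  cfg <- signal_model_config(snr_db = 40)
  script <- data.frame(onset = c(0, 4), duration = c(2, 2),
                       intent = c("ssvep_12", "single_blink"))
  sess <- make_session_stream(script, cfg, seed = 3)
  expect_s3_class(sess$stream, "eeg_stream")
  expect_setequal(sess$stream$channels, c("O1", "O2"))
  expect_equal(ncol(sess$stream$samples), 3000L)
  expect_equal(nrow(sess$events), 2L)
  expect_equal(sess$events$class, script$intent)

  # the first 2 s of the bipolar trace peaks at 12 Hz
  bip <- make_bipolar(sess$stream)
  ep <- extract_epoch(bip, 0, 2)
  mag <- Mod(stats::fft(ep$samples))[2:500]
  expect_equal(which.max(mag) * cfg$fs / 1000, 12)

  # empty script: background only, no events
  empty <- make_session_stream(NULL, cfg, seed = 3)
  expect_equal(nrow(empty$events), 0L)
  expect_equal(ncol(empty$stream$samples), 1000L)

  # overlapping intents are rejected
  bad <- data.frame(onset = c(0, 1), duration = c(2, 2),
                    intent = c("ssvep_10", "ssvep_11"))
  expect_error(make_session_stream(bad, cfg), "overlap")
})

test_that("identical config and seed give bit-identical epochs", {
  cfg <- signal_model_config()
  a <- make_ssvep_epoch(7.5, cfg, seed = 77)
  b <- make_ssvep_epoch(7.5, cfg, seed = 77)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples,
                         make_ssvep_epoch(7.5, cfg, seed = 78)$samples))
})

test_that("bipolar view equals O1 minus O2 for the same trial seed", {
  cfg <- signal_model_config()
  o1 <- make_ssvep_epoch(11, cfg, seed = 12, channel = "O1")
  o2 <- make_ssvep_epoch(11, cfg, seed = 12, channel = "O2")
  bi <- make_ssvep_epoch(11, cfg, seed = 12, channel = "bipolar")
  expect_equal(bi$samples, o1$samples - o2$samples, tolerance = 1e-12)
})
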