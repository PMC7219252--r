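test_that("edge trimming keeps the interior and tracks provenance", {
  rec <- make_eeg(clean_eeg_spec(360, 2))
  trimmed <- trim_edges(rec, 60)
  expect_equal(n_samples(trimmed), 240L * 256L)
  expect_equal(trimmed$start_trim_applied, 60)
  expect_identical(trimmed$samples,
                   rec$samples[, (60 * 256 + 1):(300 * 256)])
  expect_identical(trim_edges(rec, 0), rec)
  short <- make_eeg(clean_eeg_spec(90, 2))
  expect_error(trim_edges(short, 60), "too short")
})

test_that("high-pass removes DC, passes 10 Hz within 1%, kills 0.1 Hz", {
  fs <- 256
  const <- recording(matrix(100, 1, 60 * fs), fs, "Cz")
  expect_lt(mean(abs(highpass_fir(const)$samples)), 0.1)

  tt <- (0:(60 * fs - 1)) / fs
  h <- musupp:::design_highpass(1, fs)
  for (f0 in c(10, 0.1)) {
    x <- sin(2 * pi * f0 * tt)
    y <- highpass_fir(recording(matrix(x, 1), fs, "Cz"))$samples[1, ]
    core <- (10 * fs):(50 * fs)          # avoid edge-reflection region
    amp <- tone_amplitude(y[core], f0, fs)
    gain <- fir_gain(h, f0, fs)
    expect_equal(amp, gain, tolerance = 0.01)
  }
  expect_gt(fir_gain(h, 10, fs), 0.99)
  expect_lt(fir_gain(h, 10, fs), 1.01)
  expect_lt(20 * log10(fir_gain(h, 0.1, fs)), -20)
  expect_error(highpass_fir(const, cutoff = 200), "Nyquist")
})

test_that("high-pass output is zero-phase against a band-limited input", {
  rec <- make_eeg(eeg_spec(duration = 30,
                           band_amplitudes = c(theta = 0, mu = 10, beta = 0,
                                               gamma = 0),
                           background_scale = 0, seed = 12))
  y <- highpass_fir(rec)$samples[1, ]
  x <- rec$samples[1, ]
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    n <- length(x)
    idx <- (1 + max(0, l)):(n + min(0, l))
    stats::cor(x[idx - l], y[idx])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0L)
})

test_that("epoching counts epochs and drops the remainder", {
  rec <- make_eeg(clean_eeg_spec(240, 3))
  expect_equal(dim(epoch_recording(rec, 2)$epochs)[1], 120L)
  rec241 <- recording(cbind(rec$samples, rec$samples[, 1:256]), 256,
                      rec$channel_labels)
  expect_equal(dim(epoch_recording(rec241, 2)$epochs)[1], 120L)
  one <- recording(matrix(0, 3, 256), 256, rec$channel_labels)
  expect_error(epoch_recording(one, 2), "shorter")
})

test_that("epoch rejection flags amplitude and kurtosis outliers only", {
  fs <- 256
  set.seed(41)
  n_ep <- 20
  len <- 2 * fs
  epochs <- array(stats::rnorm(n_ep * 1 * len, sd = 12.5), c(n_ep, 1, len))
  # epoch 3: gross spike above the 3000 uV ceiling; epoch 5: flat channel
  epochs[3, 1, 100] <- 5000
  epochs[5, 1, ] <- stats::rnorm(len, sd = 1 / 8)
  eset <- structure(list(epochs = epochs, keep_mask = rep(TRUE, n_ep),
                         rejection_reasons = rep(NA_character_, n_ep),
                         sampling_rate = fs, channel_labels = "Cz"),
                    class = "epoch_set")
  out <- reject_epochs(eset, rejection_criteria())
  expect_false(out$keep_mask[3]); expect_equal(out$rejection_reasons[3], "p2p_max")
  expect_false(out$keep_mask[5]); expect_equal(out$rejection_reasons[5], "p2p_min")
  expect_true(all(out$keep_mask[-c(3, 5)]))
  # surviving epochs are untouched
  expect_identical(out$epochs, epochs)

  # kurtosis rule: Gaussian epochs with one replaced by a heavy-tailed draw
  # (a single 12 SD outlier sample); its kurtosis z-score exceeds 5
  set.seed(43)
  n_ep <- 60
  gaus <- array(stats::rnorm(n_ep * 1 * len, sd = 12.5), c(n_ep, 1, len))
  gaus[8, 1, 50] <- 12 * 12.5
  eset2 <- structure(list(epochs = gaus, keep_mask = rep(TRUE, n_ep),
                          rejection_reasons = rep(NA_character_, n_ep),
                          sampling_rate = fs, channel_labels = "Cz"),
                     class = "epoch_set")
  out2 <- reject_epochs(eset2, rejection_criteria())
  expect_false(out2$keep_mask[8])
  expect_equal(out2$rejection_reasons[8], "kurtosis")
  expect_true(all(out2$keep_mask[-8]))

  few <- structure(list(epochs = epochs[1:4, , , drop = FALSE],
                        keep_mask = rep(TRUE, 4),
                        rejection_reasons = rep(NA_character_, 4),
                        sampling_rate = fs, channel_labels = "Cz"),
                   class = "epoch_set")
  expect_error(reject_epochs(few), "8 epochs")

  flat_all <- structure(list(epochs = array(0.01 * stats::rnorm(10 * len),
                                            c(10, 1, len)),
                             keep_mask = rep(TRUE, 10),
                             rejection_reasons = rep(NA_character_, 10),
                             sampling_rate = fs, channel_labels = "Cz"),
                        class = "epoch_set")
  expect_error(reject_epochs(flat_all), "no contamination-free")
})

test_that("the composed clean-data pipeline preserves mu power within 5%", {
  rec <- make_eeg(clean_eeg_spec(140, 19))
  base <- highpass_fir(make_eeg(clean_eeg_spec(60, 20)))
  raw_mu <- direct_band_power(rec$samples[1, ], 256, 8, 14)
  model <- asr_calibrate(base)
  out <- asr_clean(highpass_fir(trim_edges(rec, 10)), model)
  eset <- reject_epochs(epoch_recording(out, 2))
  mu <- band_powers(welch_psd(eset))$absolute["Cz", "mu"]
  expect_equal(mu, raw_mu, tolerance = 0.05)
})
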