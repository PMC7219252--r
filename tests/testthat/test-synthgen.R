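test_that("eeg_spec validation names the offending field", {
  expect_error(eeg_spec(duration = -1), "duration")
  expect_error(eeg_spec(duration = 10, sampling_rate = 80), "sampling_rate")
  expect_error(eeg_spec(duration = 10,
                        band_amplitudes = c(theta = -1, mu = 0, beta = 0,
                                            gamma = 0)),
               "band_amplitudes")
  expect_error(eeg_spec(duration = 10, background_scale = -2),
               "background_scale")
})

test_that("a source-free spec yields an all-zero recording", {
  sp <- eeg_spec(duration = 4,
                 band_amplitudes = c(theta = 0, mu = 0, beta = 0, gamma = 0),
                 background_scale = 0)
  rec <- make_eeg(sp)
  expect_equal(dim(rec$samples), c(3L, 4L * 256L))
  expect_true(all(rec$samples == 0))
})

test_that("generators are pure functions of their seed", {
  sp7 <- eeg_spec(duration = 4, seed = 7)
  sp8 <- eeg_spec(duration = 4, seed = 8)
  expect_identical(make_eeg(sp7)$samples, make_eeg(sp7)$samples)
  expect_false(identical(make_eeg(sp7)$samples, make_eeg(sp8)$samples))
  es <- emg_spec(seed = 7)
  expect_identical(make_emg_trial(es)$emg, make_emg_trial(es)$emg)
  expect_false(identical(make_emg_trial(es)$emg,
                         make_emg_trial(emg_spec(seed = 8))$emg))
})

test_that("single-band specs are band-confined and bands add in power", {
  bands <- list(theta = c(4, 8), mu = c(8, 14), beta = c(14, 31),
                gamma = c(31, 50))
  total <- numeric(0)
  for (b in names(bands)) {
    amps <- c(theta = 0, mu = 0, beta = 0, gamma = 0)
    amps[b] <- 10
    rec <- make_eeg(eeg_spec(duration = 16, band_amplitudes = amps,
                             background_scale = 0, seed = 42))
    x <- rec$samples[1, ]
    in_band <- direct_band_power(x, 256, bands[[b]][1], bands[[b]][2])
    all_band <- direct_band_power(x, 256, 4, 50)
    expect_gte(in_band / all_band, 0.99)
    expect_equal(sqrt(mean(x^2)), 10, tolerance = 1e-12)
    total[b] <- mean(x^2)
  }
  multi <- make_eeg(eeg_spec(duration = 16,
                             band_amplitudes = c(theta = 10, mu = 10,
                                                 beta = 10, gamma = 10),
                             background_scale = 0, seed = 43))
  expect_equal(mean(multi$samples[1, ]^2), sum(total), tolerance = 0.05)
})

test_that("make_eeg_pair plants the requested mu power factor", {
  expect_error(make_eeg_pair(clean_eeg_spec(4, 1), 0), "positive")
  expect_error(make_eeg_pair(clean_eeg_spec(4, 1), -0.5), "positive")
  sp <- eeg_spec(duration = 240,
                 band_amplitudes = c(theta = 3, mu = 8, beta = 2.5, gamma = 1),
                 background_scale = 0, seed = 31)
  pair <- make_eeg_pair(sp, 0.6, seed = 99)
  r <- direct_band_power(pair$after$samples[1, ], 256, 8, 14) /
    direct_band_power(pair$before$samples[1, ], 256, 8, 14)
  expect_equal(r, 0.6, tolerance = 0.05)
  ident <- make_eeg_pair(sp, 1.0, seed = 99)
  r1 <- direct_band_power(ident$after$samples[1, ], 256, 8, 14) /
    direct_band_power(ident$before$samples[1, ], 256, 8, 14)
  expect_equal(r1, 1.0, tolerance = 0.05)
})

test_that("artifact injection adds exactly-masked templates", {
  rec <- make_eeg(clean_eeg_spec(60, 5))
  empty <- inject_artifacts(rec, artifact_schedule(), seed = 1)
  expect_identical(empty$recording$samples, rec$samples)
  expect_false(any(empty$schedule$ground_truth_mask))

  sch <- artifact_schedule(list(
    list(channels = "Cz", start = 10, duration = 0.5, kind = "muscle_burst",
         amplitude = 500)))
  inj <- inject_artifacts(rec, sch, seed = 2)
  mask <- inj$schedule$ground_truth_mask
  expect_equal(sum(mask["Cz", ]), round(0.5 * 256))
  expect_equal(sum(mask[c("C3", "C4"), ]), 0)
  seg <- inj$recording$samples["Cz", mask["Cz", ]]
  expect_gte(max(seg) - min(seg), 500)
  expect_identical(inj$recording$samples["Cz", !mask["Cz", ]],
                   rec$samples["Cz", !mask["Cz", ]])

  two <- inject_artifacts(rec, artifact_schedule(list(
    list(channels = "Cz", start = 5, duration = 1, kind = "blink",
         amplitude = 200),
    list(channels = "Cz", start = 20, duration = 2, kind = "movement",
         amplitude = 300))), seed = 3)
  m <- two$schedule$ground_truth_mask["Cz", ]
  expect_equal(sum(m), round(1 * 256) + round(2 * 256))

  expect_error(
    inject_artifacts(rec, artifact_schedule(list(
      list(channels = "Cz", start = 59.9, duration = 1, kind = "blink",
           amplitude = 100))), seed = 1),
    "outside")
})

test_that("emg trials hit the planted spectral median, RMS and onset", {
  es <- emg_spec(target_mpf = 100, rms_scale = 200, onset_time = 1.0,
                 peak_force = 300, plateau_duration = 6.5, seed = 11)
  tr <- make_emg_trial(es)
  fs <- tr$sampling_rate
  plateau <- seq(round((1.0 + 0.2) * fs) + 1, round((1.0 + 0.2 + 6.5) * fs))
  expect_equal(sqrt(mean(tr$emg[plateau]^2)), 200, tolerance = 1e-9)
  mpf <- median_power_frequency(tr$emg[plateau], fs)
  expect_equal(mpf, 100, tolerance = 3 / 100)
  # pre-onset EMG is near silent
  pre <- seq_len(round(0.9 * fs))
  expect_lt(sqrt(mean(tr$emg[pre]^2)), 0.05 * 200)
  # 10% of peak force is reached inside the 0.2 s ramp after onset
  i10 <- which(tr$force >= 30)[1]
  expect_gte((i10 - 1) / fs, 1.0)
  expect_lte((i10 - 1) / fs, 1.25)
  expect_equal(max(tr$force), 300)
})

test_that("emg_spec validation rejects out-of-range parameters", {
  expect_error(emg_spec(target_mpf = 4), "target_mpf")
  expect_error(emg_spec(target_mpf = 600), "target_mpf")
  expect_error(emg_spec(peak_force = 0), "peak_force")
  expect_error(emg_spec(onset_time = 4, plateau_duration = 5, duration = 8),
               "plateau_duration")
  expect_error(emg_spec(sampling_rate = 800), "sampling_rate")
})
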