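tone_trial <- function(f0, fs = 2000, dur = 8) {
  tt <- (0:(dur * fs - 1)) / fs
  emg_trial(sin(2 * pi * f0 * tt), c(rep(0, fs %/% 2), rep(1, dur * fs - fs %/% 2)),
            fs)
}

test_that("EMG filtering matches its own frequency response contracts", {
  fs <- 2000
  for (f0 in c(60, 100, 2)) {
    tr <- tone_trial(f0)
    out <- filter_emg(tr)
    core <- (2 * fs):(6 * fs)
    gain <- tone_amplitude(out$emg[core], f0, fs)
    # independent oracle: squared cascade response (forward-backward)
    notch <- musupp:::design_notch(60, fs, 30)
    bp <- signal::butter(4, c(5, 500) / (fs / 2), type = "pass")
    g_ref <- (iir_gain(notch$b, notch$a, f0, fs) *
                iir_gain(bp$b, bp$a, f0, fs))^2
    expect_equal(gain, g_ref, tolerance = max(0.02, 0.1 * g_ref))
    if (f0 == 60) expect_lte(gain, 0.05)
    if (f0 == 100) expect_equal(gain, 1, tolerance = 0.02)
    if (f0 == 2) expect_lt(20 * log10(gain), -20)
    expect_identical(out$force, tr$force)   # force untouched
  }
  slow <- emg_trial(stats::rnorm(1000), rep(1, 1000), 800)
  expect_error(filter_emg(slow), "1000 Hz")
})

test_that("passband content is nearly unchanged by repeated filtering", {
  set.seed(55)
  tr <- make_emg_trial(emg_spec(target_mpf = 120, seed = 55))
  once <- filter_emg(tr)
  twice <- filter_emg(once)
  r_once <- rms_amplitude(once$emg)
  r_twice <- rms_amplitude(twice$emg)
  expect_equal(r_twice / r_once, 1, tolerance = 0.04)
})

test_that("onset detection finds the first threshold crossing exactly", {
  fs <- 2000
  ramp <- 300 * (0:(fs - 1)) / fs          # 0 -> 300 over 1 s
  onset <- detect_onset(ramp)
  expect_equal(onset, which(ramp >= 30)[1])
  expect_equal(ramp[onset] >= 30, TRUE)
  expect_equal(detect_onset(ramp * 1e-3), onset)  # unit rescaling
  expect_equal(detect_onset(rep(5, 100)), 1L)
  expect_error(detect_onset(rep(0, 100)), "no onset")
  expect_error(detect_onset(rep(-1, 100)), "no onset")
})

test_that("segment selection takes exactly 6.5 s from onset", {
  fs <- 2000
  tr <- emg_trial(seq_len(8 * fs), rep(1, 8 * fs), fs)
  seg <- select_segment(tr, 200)
  expect_equal(length(seg), 13000L)
  expect_equal(seg[1], 200)
  expect_equal(seg[13000], 13199)
  full <- emg_trial(seq_len(13000), rep(1, 13000), fs)
  expect_equal(select_segment(full, 1), as.numeric(1:13000))
  expect_error(select_segment(tr, 8 * fs - fs), "too short")
})

test_that("median power frequency matches closed-form cases", {
  fs <- 2000
  tt <- (0:(7 * fs - 1)) / fs
  tone <- sin(2 * pi * 100 * tt)
  expect_equal(median_power_frequency(tone, fs), 100, tolerance = 0.5 / 100)
  # white noise through the EMG filters: near-flat over [5, 500], so the MPF
  # sits near the band midpoint, shifted slightly down by the Butterworth
  # roll-off. Oracle: median of the net (forward-backward squared) power
  # response computed independently from the filter coefficients.
  set.seed(77)
  tr <- emg_trial(stats::rnorm(8 * fs), c(rep(0, 100), rep(1, 8 * fs - 100)), fs)
  flat <- filter_emg(tr)
  mpf <- median_power_frequency(flat$emg, fs)
  notch <- musupp:::design_notch(60, fs, 30)
  bp <- signal::butter(4, c(5, 500) / (fs / 2), type = "pass")
  grid <- seq(5, 500, by = 0.25)
  resp <- (iir_gain(notch$b, notch$a, grid, fs) *
             iir_gain(bp$b, bp$a, grid, fs))^4
  cum <- cumsum((resp[-1] + resp[-length(resp)]) / 2 * diff(grid))
  expected <- grid[which(cum >= cum[length(cum)] / 2)[1]]
  expect_equal(mpf, expected, tolerance = 5 / expected)
  expect_gt(mpf, 200); expect_lt(mpf, 300)   # near the 252.5 Hz midpoint
  # scale invariance
  expect_equal(median_power_frequency(17.3 * tone, fs),
               median_power_frequency(tone, fs), tolerance = 1e-12)
  expect_error(median_power_frequency(tone[1:100], fs), "shorter")
  expect_error(median_power_frequency(rep(0, fs * 2), fs), "zero total power")
})

test_that("RMS amplitude has its closed forms and homogeneity", {
  expect_equal(rms_amplitude(rep(-3, 100)), 3)
  fs <- 2000
  tt <- (0:(fs - 1)) / fs
  expect_equal(rms_amplitude(sin(2 * pi * 50 * tt)), 1 / sqrt(2),
               tolerance = 1e-3)
  x <- stats::rnorm(1000)
  expect_equal(rms_amplitude(4 * x), 4 * rms_amplitude(x), tolerance = 1e-12)
  expect_error(rms_amplitude(numeric(0)), "empty")
})

test_that("fatigue ratios aggregate trial means and keep effect signs", {
  mk <- function(mpf, rms) structure(list(mpf = mpf, rms = rms,
                                          onset_sample = 1, peak_force = 300,
                                          trial_id = "t"),
                                     class = "fatigue_indices")
  same <- list(mk(120, 200), mk(118, 210))
  fr <- fatigue_ratio(same, same)
  expect_equal(fr$mpf$ratio, 1); expect_equal(fr$rms$percent_change, 0)
  down <- list(mk(0.9 * 120, 200), mk(0.9 * 118, 210))
  fr2 <- fatigue_ratio(same, down)
  expect_equal(fr2$mpf$percent_change, -10, tolerance = 1e-9)

  # muscle-fatigue signature through the full synthetic pipeline:
  # MPF down and RMS up must be recovered with the correct signs
  before <- lapply(1:3, function(i)
    fatigue_indices(make_emg_trial(emg_spec(target_mpf = 120, rms_scale = 200,
                                            seed = 200 + i))))
  after <- lapply(1:3, function(i)
    fatigue_indices(make_emg_trial(emg_spec(target_mpf = 102, rms_scale = 230,
                                            seed = 300 + i))))
  fr3 <- fatigue_ratio(before, after)
  expect_lt(fr3$mpf$percent_change, 0)
  expect_gt(fr3$rms$percent_change, 0)
})
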