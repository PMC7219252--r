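make_eset <- function(x, fs = 256, epoch_s = 2) {
  epoch_recording(recording(matrix(x, 1), fs, "Cz"), epoch_s)
}

flat_psd <- function(level = 1, fs = 256, len = 512) {
  n_half <- len %/% 2
  structure(list(frequencies = (0:n_half) * fs / len,
                 density = matrix(level, 1, n_half + 1,
                                  dimnames = list("Cz", NULL)),
                 n_epochs_used = 1L, resolution = fs / len,
                 channel_labels = "Cz"),
            class = "psd_result")
}

test_that("Welch density integrates to signal power (Parseval)", {
  fs <- 256
  tt <- (0:(240 * fs - 1)) / fs
  psd <- welch_psd(make_eset(sin(2 * pi * 10 * tt)))
  f <- psd$frequencies
  sel <- f >= 9 & f <= 11
  p_band <- sum((psd$density[1, ][sel][-1] + head(psd$density[1, ][sel], -1)) /
                  2 * diff(f[sel]))
  expect_equal(p_band, 0.5, tolerance = 0.02)

  set.seed(91)
  noise <- stats::rnorm(240 * fs, sd = 3)
  psd_n <- welch_psd(make_eset(noise))
  total <- sum((psd_n$density[1, ][-1] + head(psd_n$density[1, ], -1)) / 2 *
                 diff(psd_n$frequencies))
  expect_equal(total, 9, tolerance = 0.05 * 9)

  psd2 <- welch_psd(make_eset(2 * sin(2 * pi * 10 * tt)))
  expect_equal(psd2$density, 4 * psd$density, tolerance = 1e-9)
})

test_that("welch_psd uses only surviving epochs and refuses none", {
  eset <- make_eset(stats::rnorm(20 * 256))
  eset$keep_mask[] <- FALSE
  expect_error(welch_psd(eset), "no surviving epochs")
  eset$keep_mask[1] <- TRUE
  expect_equal(welch_psd(eset)$n_epochs_used, 1L)
})

test_that("band powers split pure and mixed tones as expected", {
  fs <- 256
  tt <- (0:(60 * fs - 1)) / fs
  mu_only <- band_powers(welch_psd(make_eset(sin(2 * pi * 10 * tt))))
  expect_gte(mu_only$relative["Cz", "mu"], 0.99)

  two <- band_powers(welch_psd(make_eset(sin(2 * pi * 10 * tt) +
                                           sin(2 * pi * 20 * tt))))
  expect_equal(unname(two$relative["Cz", "mu"]), 0.5, tolerance = 0.02)
  expect_equal(unname(two$relative["Cz", "beta"]), 0.5, tolerance = 0.02)

  flat <- band_powers(flat_psd())
  expect_equal(unname(flat$relative["Cz", "mu"]), 6 / 46, tolerance = 0.005)
  expect_equal(unname(flat$relative["Cz", "theta"]), 4 / 46, tolerance = 0.005)
})

test_that("band powers conserve total power and normalize to one", {
  rec <- make_eeg(clean_eeg_spec(60, 33))
  tbl <- band_powers(welch_psd(epoch_recording(rec, 2)))
  expect_equal(unname(rowSums(tbl$absolute)), unname(tbl$total),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(tbl$relative)), rep(1, 3), tolerance = 1e-9)
  # scale invariance / quadratic scaling
  k <- 3.7
  tbl_k <- band_powers(welch_psd(epoch_recording(
    recording(rec$samples * k, 256, rec$channel_labels), 2)))
  expect_equal(tbl_k$relative, tbl$relative, tolerance = 1e-9)
  expect_equal(tbl_k$absolute, tbl$absolute * k^2, tolerance = 1e-9)
})

test_that("band_powers requires a grid covering the scheme", {
  psd <- flat_psd(fs = 64, len = 128)   # grid up to 32 Hz only
  expect_error(band_powers(psd), "does not cover")
})

test_that("session ratios follow the single-band scaling algebra", {
  rec <- make_eeg(clean_eeg_spec(120, 34))
  before <- band_powers(welch_psd(epoch_recording(rec, 2)))
  # scale only the measured mu power: synthesize the after-table directly
  after <- before
  f <- 0.6
  after$absolute[, "mu"] <- before$absolute[, "mu"] * f
  after$total <- rowSums(after$absolute)
  after$relative <- after$absolute / after$total

  abs_sr <- session_ratio(before, after, "absolute_mu", "Cz")
  expect_equal(abs_sr$ratio, f, tolerance = 1e-12)
  expect_equal(abs_sr$percent_change, (f - 1) * 100, tolerance = 1e-9)

  r_mu <- before$relative["Cz", "mu"]
  predicted <- f / (f * r_mu + (1 - r_mu))
  rel_sr <- session_ratio(before, after, "relative_mu", "Cz")
  expect_equal(rel_sr$ratio, unname(predicted), tolerance = 1e-12)

  ident <- session_ratio(before, before, "relative_mu", "Cz")
  expect_equal(ident$ratio, 1)
  expect_equal(ident$percent_change, 0)

  zero <- before
  zero$absolute[, "mu"] <- 0
  expect_error(session_ratio(zero, after, "absolute_mu", "Cz"),
               "not positive")
  expect_error(session_ratio(before, after, "absolute_mu", "Oz"), "Oz")
  expect_error(session_ratio(before, after, "absolute_delta", "Cz"),
               "unknown")
})

test_that("treatment change compares last against first session ratios", {
  first <- musupp:::make_session_ratio("relative_mu", 1, 1.14, "C3")
  last <- musupp:::make_session_ratio("relative_mu", 1, 1.06, "C3")
  expect_equal(treatment_change(first, last), (1.06 / 1.14 - 1) * 100,
               tolerance = 1e-12)
  expect_equal(round(treatment_change(first, last), 2), -7.02)
  expect_equal(treatment_change(first, first), 0)
  ten <- musupp:::make_session_ratio("relative_mu", 1, 0.8, "C3")
  one <- musupp:::make_session_ratio("relative_mu", 1, 1.0, "C3")
  expect_equal(treatment_change(one, ten), -20)
  other <- musupp:::make_session_ratio("absolute_mu", 1, 1.06, "C3")
  expect_error(treatment_change(first, other), "metric mismatch")
  elsewhere <- musupp:::make_session_ratio("relative_mu", 1, 1.06, "C4")
  expect_error(treatment_change(first, elsewhere), "channel")
})

test_that("band_scheme rejects gapped or reversed partitions", {
  expect_error(band_scheme(list(a = c(4, 8), b = c(9, 12))), "contiguous")
  expect_error(band_scheme(list(a = c(8, 4))), "increasing")
  sch <- band_scheme()
  expect_equal(sch$total, c(4, 50))
  expect_equal(names(sch$bands), c("theta", "mu", "beta", "gamma"))
})
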