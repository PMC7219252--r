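#' Onset-detection and segment parameters
#'
#' @param threshold_fraction fraction of peak force defining contraction onset
#'   (default 0.10).
#' @param segment_length seconds of EMG analyzed from onset (default 6.5).
#' @return an object of class `onset_params`.
#' @export
onset_params <- function(threshold_fraction = 0.1, segment_length = 6.5) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (segment_length <= 0) stop("segment_length must be > 0", call. = FALSE)
  structure(list(threshold_fraction = threshold_fraction,
                 segment_length = segment_length),
            class = "onset_params")
}

# RBJ biquad notch at f0 with quality factor q.
design_notch <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Filter an EMG trial
#'
#' A 60 Hz biquad notch (quality factor 30) to remove line noise, followed by
#' a 4th-order Butterworth band-pass (5-500 Hz). Both are applied
#' forward-backward so the net phase is zero and onset-aligned timing is not
#' skewed by group delay. The force channel is left untouched.
#'
#' @param trial an [emg_trial()] sampled above 1 kHz (so the 500 Hz band edge
#'   is below Nyquist).
#' @param notch_hz,notch_q notch centre frequency and quality factor.
#' @param band band-pass corner frequencies in Hz.
#' @return the filtered [emg_trial()].
#' @export
filter_emg <- function(trial, notch_hz = 60, notch_q = 30, band = c(5, 500)) {
  fs <- trial$sampling_rate
  if (fs <= 1000) {
    stop("filter_emg requires a sampling rate above 1000 Hz", call. = FALSE)
  }
  notch <- design_notch(notch_hz, fs, notch_q)
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(notch, trial$emg)
  x <- signal::filtfilt(bp, x)
  out <- trial
  out$emg <- as.numeric(x)
  out
}

#' Force-threshold contraction onset
#'
#' Returns the first sample index (1-based) at which the force reaches
#' `threshold_fraction` of its peak. Invariant to force-unit rescaling.
#'
#' @param force numeric force series with a positive maximum.
#' @param params an [onset_params()].
#' @return the onset sample index.
#' @export
detect_onset <- function(force, params = onset_params()) {
  peak <- max(force)
  if (!is.finite(peak) || peak <= 0) {
    stop("no onset: force has no positive peak", call. = FALSE)
  }
  which(force >= params$threshold_fraction * peak)[1]
}

#' Select the analyzed EMG segment
#'
#' EMG samples from the detected onset spanning `segment_length` seconds
#' (default 6.5 s).
#'
#' @param trial an [emg_trial()].
#' @param onset_sample onset index from [detect_onset()].
#' @param params an [onset_params()].
#' @return numeric vector of EMG samples.
#' @export
select_segment <- function(trial, onset_sample, params = onset_params()) {
  len <- round(params$segment_length * trial$sampling_rate)
  avail <- length(trial$emg) - onset_sample + 1L
  if (avail < len) {
    stop(sprintf("trial too short after onset: %.3g s available, %.3g s needed",
                 avail / trial$sampling_rate, params$segment_length),
         call. = FALSE)
  }
  trial$emg[onset_sample:(onset_sample + len - 1L)]
}

# Welch PSD of a plain vector: Hamming windows of win_s seconds, 50% overlap.
welch_vector <- function(x, fs, win_s = 1, overlap = 0.5) {
  len <- round(win_s * fs)
  if (length(x) < len) {
    stop(sprintf("segment shorter than one %g s analysis window", win_s),
         call. = FALSE)
  }
  hop <- max(1L, round(len * (1 - overlap)))
  starts <- seq(1L, length(x) - len + 1L, by = hop)
  w <- signal::hamming(len)
  u <- sum(w^2)
  n_half <- len %/% 2L
  acc <- numeric(n_half + 1L)
  for (s0 in starts) {
    X <- Mod(stats::fft(x[s0:(s0 + len - 1L)] * w))^2 / (fs * u)
    one <- X[1:(n_half + 1L)]
    dbl <- 2:(n_half + if (len %% 2L == 0L) 0L else 1L)
    one[dbl] <- 2 * one[dbl]
    acc <- acc + one
  }
  list(frequencies = (0:n_half) * fs / len, density = acc / length(starts))
}

#' Median power frequency of an EMG segment
#'
#' Welch spectrum (1 s Hamming windows, 50% overlap); the MPF is the frequency
#' at which the cumulative power over 5-500 Hz reaches half the total over
#' that range, with linear interpolation between grid points. Invariant to
#' amplitude scaling.
#'
#' @param segment numeric EMG samples, at least 1 s long.
#' @param rate sampling rate in Hz.
#' @return MPF in Hz.
#' @export
median_power_frequency <- function(segment, rate) {
  psd <- welch_vector(segment, rate)
  sel <- psd$frequencies >= 5 & psd$frequencies <= min(500, rate / 2)
  cumulative_median(psd$frequencies[sel], psd$density[sel])
}

#' RMS amplitude of an EMG segment
#'
#' @param segment non-empty numeric vector in uV.
#' @return `sqrt(mean(segment^2))`.
#' @export
rms_amplitude <- function(segment) {
  if (!length(segment)) stop("empty segment", call. = FALSE)
  sqrt(mean(segment^2))
}

#' Fatigue indices of one MVC trial
#'
#' Runs the full per-trial chain: zero-phase filtering, force-threshold onset
#' detection, segment selection, MPF and RMS.
#'
#' @param trial an [emg_trial()].
#' @param params an [onset_params()].
#' @param prefilter apply [filter_emg()] first (default `TRUE`).
#' @return an object of class `fatigue_indices`: `mpf` (Hz), `rms` (uV),
#'   `onset_sample`, `peak_force`, `trial_id`.
#' @export
fatigue_indices <- function(trial, params = onset_params(), prefilter = TRUE) {
  if (prefilter) trial <- filter_emg(trial)
  onset <- detect_onset(trial$force, params)
  seg <- select_segment(trial, onset, params)
  structure(list(mpf = median_power_frequency(seg, trial$sampling_rate),
                 rms = rms_amplitude(seg), onset_sample = onset,
                 peak_force = max(trial$force), trial_id = trial$trial_id),
            class = "fatigue_indices")
}

#' After/before muscle-fatigue ratios
#'
#' Aggregates the MVC trials of each measurement by the arithmetic mean of
#' per-trial MPF and RMS, and forms the after/before ratio and percent change
#' for each index. Muscle fatigue shows as a decreased MPF and an increased
#' RMS.
#'
#' @param before,after lists of [fatigue_indices()] (the repeated MVC trials
#'   of the before/after measurement).
#' @return list with `mpf` and `rms` session-ratio objects.
#' @export
fatigue_ratio <- function(before, after) {
  agg <- function(lst, what) mean(vapply(lst, `[[`, numeric(1), what))
  list(mpf = make_session_ratio("mpf", agg(before, "mpf"), agg(after, "mpf")),
       rms = make_session_ratio("rms", agg(before, "rms"), agg(after, "rms")))
}
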