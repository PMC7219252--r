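#' Trim the recording edges
#'
#' Removes the first and last `trim` seconds of a recording, discarding the
#' settling-in and wrap-up periods of a resting acquisition (and, for the mu
#' analysis, reducing attention-driven alpha modulation at the run edges).
#'
#' @param rec a [recording()].
#' @param trim seconds removed from each end (default 60).
#' @return the interior [recording()]; `start_trim_applied` is updated.
#' @export
trim_edges <- function(rec, trim = 60) {
  if (trim < 0) stop("`trim` must be >= 0", call. = FALSE)
  if (trim == 0) return(rec)
  if (duration(rec) <= 2 * trim) {
    stop(sprintf("recording too short to trim: %.3g s with %g s off each end",
                 duration(rec), trim), call. = FALSE)
  }
  k <- round(trim * rec$sampling_rate)
  idx <- (k + 1L):(n_samples(rec) - k)
  recording(rec$samples[, idx, drop = FALSE], rec$sampling_rate,
            rec$channel_labels, rec$start_trim_applied + trim)
}

# Hamming windowed-sinc high-pass design. Transition bandwidth follows the
# common EEG-filtering heuristic min(max(cutoff/4, 2), cutoff) Hz, and the
# (even) order is 3.3 / normalized transition width. Built as delta minus a
# unity-DC low-pass, so the DC gain is exactly zero.
design_highpass <- function(cutoff, fs) {
  tbw <- min(max(cutoff * 0.25, 2), cutoff)
  ord <- ceiling(3.3 * fs / tbw)
  if (ord %% 2 == 1) ord <- ord + 1      # even order -> odd, symmetric taps
  lp <- signal::fir1(ord, cutoff / (fs / 2), type = "low",
                     window = signal::hamming(ord + 1))
  h <- -lp / sum(lp)
  h[ord / 2 + 1] <- h[ord / 2 + 1] + 1
  h
}

#' Zero-phase FIR high-pass filter
#'
#' Applies a linear-phase Hamming windowed-sinc high-pass with full group-delay
#' compensation, so the net phase response is zero and the output has the same
#' length as the input. Edges are handled by signal reflection.
#'
#' @param rec a [recording()].
#' @param cutoff -6 dB cutoff in Hz (default 1); must be below Nyquist.
#' @return the filtered [recording()].
#' @export
highpass_fir <- function(rec, cutoff = 1) {
  fs <- rec$sampling_rate
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, fs / 2),
         call. = FALSE)
  }
  h <- design_highpass(cutoff, fs)
  m <- (length(h) - 1L) %/% 2L
  n <- n_samples(rec)
  if (n <= m + 1L) {
    stop("recording shorter than the filter's half-length", call. = FALSE)
  }
  out <- rec$samples
  for (ci in seq_len(n_channels(rec))) {
    x <- rec$samples[ci, ]
    xp <- c(rev(x[2:(m + 1L)]), x, rev(x[(n - m):(n - 1L)]))
    z <- signal::fftfilt(h, xp)
    out[ci, ] <- z[(2L * m + 1L):(2L * m + n)]
  }
  recording(out, fs, rec$channel_labels, rec$start_trim_applied)
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive, non-overlapping epochs; a trailing remainder shorter than one
#' epoch is dropped. All epochs start with `keep_mask = TRUE`.
#'
#' @param rec a [recording()].
#' @param epoch_length epoch length in seconds (default 2, giving 0.5 Hz
#'   spectral resolution at 256 Hz).
#' @return an object of class `epoch_set`: an `n_epochs x channels x samples`
#'   array plus keep mask and rejection reasons.
#' @export
epoch_recording <- function(rec, epoch_length = 2) {
  len <- round(epoch_length * rec$sampling_rate)
  n_ep <- n_samples(rec) %/% len
  if (n_ep < 1L) {
    stop(sprintf("recording (%.3g s) shorter than one epoch (%g s)",
                 duration(rec), epoch_length), call. = FALSE)
  }
  epochs <- array(0, dim = c(n_ep, n_channels(rec), len))
  for (e in seq_len(n_ep)) {
    epochs[e, , ] <- rec$samples[, ((e - 1L) * len + 1L):(e * len)]
  }
  structure(
    list(epochs = epochs, keep_mask = rep(TRUE, n_ep),
         rejection_reasons = rep(NA_character_, n_ep),
         sampling_rate = rec$sampling_rate,
         channel_labels = rec$channel_labels),
    class = "epoch_set"
  )
}

#' Epoch rejection criteria
#'
#' Amplitude bounds are read as peak-to-peak per epoch per channel: above
#' `p2p_max` marks a gross artifact, below `p2p_min` a flat or disconnected
#' channel. The kurtosis rule is a per-channel across-epoch z-score, one-sided.
#'
#' @param p2p_min,p2p_max peak-to-peak bounds in uV (defaults 30 and 3000).
#' @param kurtosis_z_max one-sided z-score ceiling for epoch sample kurtosis
#'   (default 5).
#' @param epoch_length epoch length in seconds used by the chain (default 2).
#' @return an object of class `rejection_criteria`.
#' @export
rejection_criteria <- function(p2p_min = 30, p2p_max = 3000,
                               kurtosis_z_max = 5, epoch_length = 2) {
  if (p2p_min <= 0 || p2p_min >= p2p_max) {
    stop("require 0 < p2p_min < p2p_max", call. = FALSE)
  }
  if (kurtosis_z_max <= 0) stop("kurtosis_z_max must be > 0", call. = FALSE)
  structure(list(p2p_min = p2p_min, p2p_max = p2p_max,
                 kurtosis_z_max = kurtosis_z_max,
                 epoch_length = epoch_length),
            class = "rejection_criteria")
}

sample_kurtosis <- function(x) {
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) return(0)
  mean(xc^4) / m2^2
}

#' Reject contaminated epochs
#'
#' An epoch is rejected if on any channel its peak-to-peak amplitude exceeds
#' `p2p_max`, falls below `p2p_min`, or its sample kurtosis lies more than
#' `kurtosis_z_max` standard deviations above the across-epoch mean kurtosis
#' for that channel. Surviving epochs are returned unmodified; the keep mask
#' and per-epoch reasons are updated.
#'
#' @param eset an `epoch_set` with at least 8 epochs (kurtosis z-scores are
#'   unstable below that).
#' @param crit a [rejection_criteria()].
#' @return the `epoch_set` with `keep_mask` and `rejection_reasons` filled.
#' @export
reject_epochs <- function(eset, crit = rejection_criteria()) {
  n_ep <- dim(eset$epochs)[1]
  n_ch <- dim(eset$epochs)[2]
  if (n_ep < 8L) {
    stop("need at least 8 epochs for stable kurtosis z-scores", call. = FALSE)
  }
  p2p <- apply(eset$epochs, c(1, 2), function(x) max(x) - min(x))
  kur <- apply(eset$epochs, c(1, 2), sample_kurtosis)
  kz <- scale(kur)  # per-channel (column) z-scores across epochs
  keep <- eset$keep_mask
  reasons <- eset$rejection_reasons
  for (e in seq_len(n_ep)) {
    if (any(p2p[e, ] > crit$p2p_max)) {
      keep[e] <- FALSE; reasons[e] <- "p2p_max"
    } else if (any(p2p[e, ] < crit$p2p_min)) {
      keep[e] <- FALSE; reasons[e] <- "p2p_min"
    } else if (any(kz[e, ] > crit$kurtosis_z_max, na.rm = TRUE)) {
      keep[e] <- FALSE; reasons[e] <- "kurtosis"
    }
  }
  if (!any(keep)) {
    stop("all epochs rejected: no contamination-free signal to analyze",
         call. = FALSE)
  }
  eset$keep_mask <- keep
  eset$rejection_reasons <- reasons
  eset
}
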