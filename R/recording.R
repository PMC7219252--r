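#' Multichannel uniformly sampled recording
#'
#' The common currency of the EEG chain: a channels-by-time matrix of samples
#' in microvolts, with channel labels and a sampling rate. `start_trim_applied`
#' records how many seconds were removed from the start of the original
#' acquisition (provenance for edge trimming).
#'
#' @param samples numeric matrix, channels x time, in uV. A vector is treated
#'   as a single channel.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique labels, one per channel.
#' @param start_trim_applied seconds already trimmed from the recording start.
#' @return an object of class `recording`.
#' @export
recording <- function(samples, sampling_rate, channel_labels,
                      start_trim_applied = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric channels x time matrix", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples)) {
    stop("`channel_labels` length must equal the number of channels",
         call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("`channel_labels` must be unique", call. = FALSE)
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = channel_labels,
         start_trim_applied = start_trim_applied),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) [%s], %.6g s @ %g Hz\n",
              n_channels(x), paste(x$channel_labels, collapse = ", "),
              duration(x), x$sampling_rate))
  if (x$start_trim_applied > 0) {
    cat(sprintf("  start trim applied: %g s\n", x$start_trim_applied))
  }
  invisible(x)
}

#' Recording geometry helpers
#'
#' @param rec a [recording()].
#' @return `duration()` the length in seconds; `n_samples()` samples per
#'   channel; `n_channels()` the channel count.
#' @export
duration <- function(rec) n_samples(rec) / rec$sampling_rate

#' @rdname duration
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname duration
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' Paired EMG and load-cell force trial
#'
#' Holds one maximum-voluntary-contraction trial: the surface EMG channel (uV)
#' and the simultaneously acquired load-cell force channel, sampled at the same
#' rate.
#'
#' @param emg numeric vector, EMG in uV.
#' @param force numeric vector, load-cell units; same length as `emg`.
#' @param sampling_rate Hz.
#' @param trial_id label for the trial.
#' @param session_tag `"before"` or `"after"` (position of the trial relative
#'   to the treatment session), or `NA` when not applicable.
#' @param ground_truth optional generator spec the trial was synthesized from.
#' @return an object of class `emg_trial`.
#' @export
emg_trial <- function(emg, force, sampling_rate, trial_id = "trial",
                      session_tag = NA_character_, ground_truth = NULL) {
  if (length(emg) != length(force)) {
    stop("`emg` and `force` must have the same length", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be positive", call. = FALSE)
  }
  structure(
    list(emg = as.numeric(emg), force = as.numeric(force),
         sampling_rate = sampling_rate, trial_id = trial_id,
         session_tag = session_tag, ground_truth = ground_truth),
    class = "emg_trial"
  )
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("<emg_trial> '%s' (%s): %.6g s @ %g Hz, peak force %.4g\n",
              x$trial_id, x$session_tag %||% NA, length(x$emg) / x$sampling_rate,
              x$sampling_rate, max(x$force)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a fixed RNG state, restoring the caller's state afterwards so
# generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
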