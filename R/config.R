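#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults: the EEG chain
#' (edge trim, high-pass cutoff, ASR window/cutoff, epoching, rejection
#' bounds), the band scheme, the EMG chain (notch, band-pass, onset threshold,
#' segment length) and the statistics policy.
#'
#' @return a nested named list.
#' @export
default_config <- function() {
  list(
    eeg = list(
      trim_s = 60,
      highpass_hz = 1,
      epoch_s = 2,
      asr = list(window_s = 0.25, cutoff_sd = 5, overlap = 0.5),
      reject = list(p2p_min_uV = 30, p2p_max_uV = 3000, kurtosis_z = 5)
    ),
    bands = list(theta = c(4, 8), mu = c(8, 14), beta = c(14, 31),
                 gamma = c(31, 50)),
    emg = list(
      notch_hz = 60, notch_q = 30,
      bandpass_hz = c(5, 500),
      onset_fraction = 0.1,
      segment_s = 6.5
    ),
    stats = list(policy = "paper_fixed", alpha = 0.05)
  )
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file, fills every unspecified key from [default_config()], and
#' rejects unknown keys (with a nearest-match suggestion) and invalid values
#' such as reversed band edges. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return the validated, fully populated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      cfg <- merge_config(cfg, user, prefix = NULL)
    }
  }
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, prefix) {
  if (!is.list(user)) {
    stop(sprintf("config section '%s' must be a mapping",
                 paste(prefix, collapse = ".")), call. = FALSE)
  }
  for (k in names(user)) {
    key_path <- paste(c(prefix, k), collapse = ".")
    if (!k %in% names(base)) {
      sug <- names(base)[which.min(utils::adist(k, names(base)))]
      stop(sprintf("unknown config key '%s'; did you mean '%s'?",
                   key_path, paste(c(prefix, sug), collapse = ".")),
           call. = FALSE)
    }
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], c(prefix, k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  for (b in names(cfg$bands)) {
    edges <- as.numeric(cfg$bands[[b]])
    if (length(edges) != 2L || edges[1] >= edges[2]) {
      stop(sprintf("config key 'bands.%s' must be an increasing [low, high] pair",
                   b), call. = FALSE)
    }
  }
  band_scheme(cfg$bands)  # contiguity check
  pos <- c(eeg.trim_s = cfg$eeg$trim_s >= 0,
           eeg.highpass_hz = cfg$eeg$highpass_hz > 0,
           eeg.epoch_s = cfg$eeg$epoch_s > 0,
           eeg.asr.window_s = cfg$eeg$asr$window_s > 0,
           eeg.asr.cutoff_sd = cfg$eeg$asr$cutoff_sd > 0,
           emg.segment_s = cfg$emg$segment_s > 0)
  if (!all(pos)) {
    stop(sprintf("config key '%s' must be positive", names(pos)[!pos][1]),
         call. = FALSE)
  }
  if (cfg$eeg$asr$overlap < 0 || cfg$eeg$asr$overlap >= 1) {
    stop("config key 'eeg.asr.overlap' must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$eeg$reject$p2p_min_uV <= 0 ||
      cfg$eeg$reject$p2p_min_uV >= cfg$eeg$reject$p2p_max_uV) {
    stop("config keys 'eeg.reject.p2p_min_uV' < 'eeg.reject.p2p_max_uV' required",
         call. = FALSE)
  }
  if (cfg$emg$onset_fraction <= 0 || cfg$emg$onset_fraction >= 1) {
    stop("config key 'emg.onset_fraction' must lie in (0, 1)", call. = FALSE)
  }
  if (!cfg$stats$policy %in% c("paper_fixed", "normality_gated")) {
    stop("config key 'stats.policy' must be 'paper_fixed' or 'normality_gated'",
         call. = FALSE)
  }
  invisible(cfg)
}
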