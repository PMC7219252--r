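#' Synthetic resting-EEG specification
#'
#' Describes a resting-state EEG emulation: a 1/f^alpha stochastic background
#' plus band-limited oscillatory components in the theta, mu, beta and gamma
#' bands with controllable per-band RMS amplitude. Generated recordings have
#' analytically known band powers, which makes every downstream spectral stage
#' testable by parameter recovery.
#'
#' @param duration recording length in seconds (> 0).
#' @param sampling_rate Hz; must exceed twice the highest generated band edge.
#' @param channels character vector of channel labels.
#' @param band_amplitudes either a named numeric vector `c(theta=, mu=, beta=,
#'   gamma=)` of RMS amplitudes in uV applied to every channel, or a named list
#'   of such vectors keyed by channel label. Values must be >= 0.
#' @param background_exponent spectral slope alpha of the 1/f^alpha background.
#' @param background_scale total RMS of the background in uV (0 disables it).
#' @param seed integer seed; the generator is a pure function of the spec
#'   including this seed.
#' @param bands band scheme used to place the oscillatory components, see
#'   [band_scheme()].
#' @return an object of class `eeg_spec`.
#' @export
eeg_spec <- function(duration,
                     sampling_rate = 256,
                     channels = c("Cz", "C3", "C4"),
                     band_amplitudes = c(theta = 4, mu = 6, beta = 3,
                                         gamma = 1.5),
                     background_exponent = 1,
                     background_scale = 5,
                     seed = 1L,
                     bands = band_scheme()) {
  spec <- structure(
    list(duration = duration, sampling_rate = sampling_rate,
         channels = as.character(channels),
         band_amplitudes = band_amplitudes,
         background_exponent = background_exponent,
         background_scale = background_scale,
         seed = as.integer(seed), bands = bands),
    class = "eeg_spec"
  )
  validate_eeg_spec(spec)
  spec
}

validate_eeg_spec <- function(spec) {
  if (!is.numeric(spec$duration) || spec$duration <= 0) {
    stop("invalid eeg_spec: `duration` must be > 0", call. = FALSE)
  }
  top_edge <- max(vapply(spec$bands$bands, max, numeric(1)))
  if (spec$sampling_rate <= 2 * top_edge) {
    stop(sprintf(
      "invalid eeg_spec: `sampling_rate` (%g Hz) must exceed twice the highest band edge (%g Hz)",
      spec$sampling_rate, top_edge), call. = FALSE)
  }
  if (length(spec$channels) < 1L || anyDuplicated(spec$channels)) {
    stop("invalid eeg_spec: `channels` must be non-empty and unique",
         call. = FALSE)
  }
  amps <- resolve_band_amplitudes(spec)
  for (ch in names(amps)) {
    if (any(amps[[ch]] < 0)) {
      stop(sprintf("invalid eeg_spec: `band_amplitudes` for channel %s must be >= 0", ch),
           call. = FALSE)
    }
  }
  if (spec$background_scale < 0) {
    stop("invalid eeg_spec: `background_scale` must be >= 0", call. = FALSE)
  }
  invisible(spec)
}

# Normalize band_amplitudes to a per-channel named list over the band names.
resolve_band_amplitudes <- function(spec) {
  band_names <- names(spec$bands$bands)
  canon <- function(a, where) {
    if (is.null(names(a)) || !all(names(a) %in% band_names)) {
      stop(sprintf("invalid eeg_spec: `band_amplitudes`%s must be named with bands %s",
                   where, paste(band_names, collapse = "/")), call. = FALSE)
    }
    out <- stats::setNames(numeric(length(band_names)), band_names)
    out[names(a)] <- as.numeric(a)
    out
  }
  if (is.list(spec$band_amplitudes)) {
    missing <- setdiff(spec$channels, names(spec$band_amplitudes))
    if (length(missing)) {
      stop(sprintf("invalid eeg_spec: `band_amplitudes` missing channel(s) %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    out <- lapply(spec$channels, function(ch)
      canon(spec$band_amplitudes[[ch]], sprintf("[['%s']]", ch)))
    names(out) <- spec$channels
    out
  } else {
    amps <- canon(spec$band_amplitudes, "")
    out <- rep(list(amps), length(spec$channels))
    names(out) <- spec$channels
    out
  }
}

# Tone frequencies for one band: one tone per ~0.5 Hz of guarded bandwidth,
# kept 1 Hz clear of each band edge so finite-window spectral leakage into
# neighbouring bands stays negligible. The placement controls the pairwise
# spacings, because epoch-averaged spectral estimates only converge when
# every two-tone beat decorrelates across epochs:
#   - every spacing is >= 0.1 Hz, so no beat is slower than ~10 s and band
#     power is stationary over analysis windows of tens of seconds;
#   - spacings near one and two 0.5 Hz analysis bins are excluded: under a
#     full-epoch Hamming window only 1- and 2-bin tone pairs have nonzero
#     cross terms, and a spacing resonant with the epoch grid would repeat
#     the same beat phase in every epoch instead of averaging out.
# Implemented as stratified jitter with alternating sign and a lower bound on
# next-nearest jitter differences.
band_tone_freqs <- function(lo, hi, guard = 1) {
  a <- lo + guard; b <- hi - guard
  if (b <= a) {
    return(stats::runif(1, lo + (hi - lo) / 3, hi - (hi - lo) / 3))
  }
  k <- max(3L, round((b - a) / 0.5))
  step <- (b - a) / k
  v <- stats::runif(k, 0.1, 0.35)
  for (i in seq_len(k)) {               # keep 2-strata spacings off 2 bins
    while (i > 2L && abs(v[i] - v[i - 2L]) < 0.06) {
      v[i] <- stats::runif(1, 0.1, 0.35)
    }
  }
  u <- v * (-1)^seq_len(k)              # adjacent spacings off 1 bin
  a + (seq_len(k) - 0.5 + u) * step
}

#' Generate a synthetic resting-EEG recording
#'
#' Each oscillatory band is synthesized as a bank of equal-amplitude sinusoids
#' with independent uniform random phases and frequencies drawn uniformly
#' inside the band (1 Hz guard from the edges, about one tone per 0.5 Hz of
#' bandwidth); the summed component is rescaled so its time-domain RMS equals
#' the requested band RMS exactly. The background is Gaussian noise spectrally
#' shaped to 1/f^alpha (flat below 1 Hz) and rescaled to the requested total
#' RMS.
#'
#' @param spec an [eeg_spec()].
#' @return a [recording()] of the requested duration, rate and channels.
#' @export
make_eeg <- function(spec) {
  validate_eeg_spec(spec)
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  amps <- resolve_band_amplitudes(spec)
  with_seed(spec$seed, {
    samples <- matrix(0, nrow = length(spec$channels), ncol = n)
    for (ci in seq_along(spec$channels)) {
      ch <- spec$channels[ci]
      x <- numeric(n)
      for (b in names(spec$bands$bands)) {
        rms <- amps[[ch]][[b]]
        if (rms <= 0) next
        edges <- spec$bands$bands[[b]]
        f <- band_tone_freqs(edges[1], edges[2])
        ph <- stats::runif(length(f), 0, 2 * pi)
        comp <- colSums(sin(outer(2 * pi * f, tt) + ph))
        x <- x + comp * (rms / sqrt(mean(comp^2)))  # exact band RMS
      }
      if (spec$background_scale > 0) {
        x <- x + shaped_background(n, fs, spec$background_exponent,
                                   spec$background_scale)
      }
      samples[ci, ] <- x
    }
    recording(samples, fs, spec$channels)
  })
}

# Gaussian noise with amplitude spectrum 1/f^(alpha/2), flattened below 1 Hz,
# DC removed, rescaled to an exact total RMS.
shaped_background <- function(n, fs, alpha, rms) {
  w <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)            # two-sided frequency magnitude
  shape <- 1 / pmax(f, 1)^(alpha / 2)
  shape[1] <- 0                   # no DC
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x * (rms / sqrt(mean(x^2)))
}

#' Generate a matched before/after EEG pair with a planted mu-power change
#'
#' The two recordings share the same specification except that the
#' after-recording's mu-band component power is scaled by `mu_power_factor`
#' (amplitude by its square root); all other bands and the background are
#' unchanged. Noise draws are independent between the two recordings.
#'
#' @param spec_before an [eeg_spec()] describing the before-recording.
#' @param mu_power_factor positive multiplier applied to the mu band power.
#' @param seed integer; the pair is deterministic given this seed.
#' @return list with elements `before` and `after`, both [recording()]s.
#' @export
make_eeg_pair <- function(spec_before, mu_power_factor, seed = spec_before$seed) {
  if (!is.numeric(mu_power_factor) || length(mu_power_factor) != 1L ||
      mu_power_factor <= 0) {
    stop("`mu_power_factor` must be a single positive number", call. = FALSE)
  }
  amps <- resolve_band_amplitudes(spec_before)
  amps_after <- lapply(amps, function(a) {
    a[["mu"]] <- a[["mu"]] * sqrt(mu_power_factor)
    a
  })
  spec_b <- spec_before
  spec_b$seed <- as.integer(seed)
  spec_a <- spec_before
  spec_a$band_amplitudes <- amps_after
  spec_a$seed <- as.integer(seed) + 1237L
  list(before = make_eeg(spec_b), after = make_eeg(spec_a))
}

#' Schedule of high-amplitude artifact events
#'
#' @param events list of events; each event is a list with fields `channels`
#'   (labels the artifact touches), `start` (s), `duration` (s), `kind` (one of
#'   `"blink"`, `"muscle_burst"`, `"movement"`) and `amplitude` (peak uV > 0).
#' @return an object of class `artifact_schedule`.
#' @export
artifact_schedule <- function(events = list()) {
  kinds <- c("blink", "muscle_burst", "movement")
  for (ev in events) {
    need <- c("channels", "start", "duration", "kind", "amplitude")
    if (!all(need %in% names(ev))) {
      stop(sprintf("artifact event must have fields %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    }
    if (!ev$kind %in% kinds) {
      stop(sprintf("unknown artifact kind '%s'", ev$kind), call. = FALSE)
    }
    if (ev$amplitude <= 0) stop("artifact amplitude must be > 0", call. = FALSE)
    if (ev$duration <= 0) stop("artifact duration must be > 0", call. = FALSE)
    if (ev$start < 0) stop("artifact start must be >= 0", call. = FALSE)
  }
  structure(list(events = events, ground_truth_mask = NULL),
            class = "artifact_schedule")
}

#' Inject artifact templates into a recording
#'
#' Adds fixed analytic artifact shapes with stochastic carriers: `blink` is a
#' low-frequency biphasic bump (Gaussian-derivative, ~0.5-4 Hz content),
#' `muscle_burst` a 20-100 Hz band-passed noise burst, `movement` a slow
#' raised-cosine drift. Each template is scaled to its event's peak amplitude.
#' The returned schedule carries the exact per-sample, per-channel mask of
#' injected samples.
#'
#' @param rec a [recording()].
#' @param schedule an [artifact_schedule()] whose events lie inside `rec`.
#' @param seed integer seed for the stochastic carriers.
#' @return list with elements `recording` (contaminated copy) and `schedule`
#'   (with `ground_truth_mask` filled in).
#' @export
inject_artifacts <- function(rec, schedule, seed = 1L) {
  fs <- rec$sampling_rate
  n <- n_samples(rec)
  mask <- matrix(FALSE, nrow = n_channels(rec), ncol = n,
                 dimnames = list(rec$channel_labels, NULL))
  out <- rec$samples
  with_seed(seed, {
    for (ev in schedule$events) {
      i0 <- floor(ev$start * fs) + 1L
      len <- round(ev$duration * fs)
      idx <- i0:(i0 + len - 1L)
      if (i0 < 1L || max(idx) > n) {
        stop(sprintf("artifact event at %g s (+%g s) lies outside the recording",
                     ev$start, ev$duration), call. = FALSE)
      }
      bad <- setdiff(ev$channels, rec$channel_labels)
      if (length(bad)) {
        stop(sprintf("artifact event names unknown channel(s): %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      for (ch in ev$channels) {
        tmpl <- artifact_template(ev$kind, len, fs) * ev$amplitude
        out[ch, idx] <- out[ch, idx] + tmpl
        mask[ch, idx] <- TRUE
      }
    }
  })
  sched <- schedule
  sched$ground_truth_mask <- mask
  list(recording = recording(out, fs, rec$channel_labels,
                             rec$start_trim_applied),
       schedule = sched)
}

# Unit-peak artifact shapes; len samples at rate fs.
artifact_template <- function(kind, len, fs) {
  u <- seq(0, 1, length.out = len)
  switch(
    kind,
    blink = {
      z <- (u - 0.5) * 6              # +-3 sigma across the event
      s <- -z * exp(-z^2 / 2)
      s / max(abs(s))
    },
    muscle_burst = {
      x <- stats::rnorm(len)
      bf <- signal::butter(4, c(20, 100) / (fs / 2), type = "pass")
      s <- signal::filtfilt(bf, x)
      taper <- 0.5 - 0.5 * cos(2 * pi * u)   # Hann, confines the burst
      s <- s * taper
      s / max(abs(s))
    },
    movement = 0.5 - 0.5 * cos(2 * pi * u),  # slow unidirectional drift
    stop(sprintf("unknown artifact kind '%s'", kind), call. = FALSE)
  )
}

#' Synthetic MVC EMG trial specification
#'
#' Describes one maximum-voluntary-contraction trial: band-shaped stochastic
#' EMG with a controllable spectral median frequency and plateau RMS, plus a
#' ramp-and-plateau load-cell force channel.
#'
#' @param duration trial length in seconds.
#' @param sampling_rate Hz (default 2000; must exceed 1000 so the 500 Hz band
#'   edge is below Nyquist).
#' @param target_mpf desired spectral median of the EMG shaping envelope, Hz;
#'   must lie in (5, 500).
#' @param rms_scale RMS of the EMG over the contraction plateau, uV.
#' @param onset_time seconds at which force ramps up from zero.
#' @param peak_force plateau force in load-cell units (> 0).
#' @param plateau_duration seconds the force (and full-amplitude EMG) is held;
#'   the 0.2 s ramp plus the plateau must fit inside the trial.
#' @param seed integer seed.
#' @return an object of class `emg_spec`.
#' @export
emg_spec <- function(duration = 8,
                     sampling_rate = 2000,
                     target_mpf = 120,
                     rms_scale = 200,
                     onset_time = 0.5,
                     peak_force = 300,
                     plateau_duration = 7,
                     seed = 1L) {
  spec <- structure(
    list(duration = duration, sampling_rate = sampling_rate,
         target_mpf = target_mpf, rms_scale = rms_scale,
         onset_time = onset_time, peak_force = peak_force,
         plateau_duration = plateau_duration, seed = as.integer(seed)),
    class = "emg_spec"
  )
  validate_emg_spec(spec)
  spec
}

validate_emg_spec <- function(spec) {
  if (spec$duration <= 0) {
    stop("invalid emg_spec: `duration` must be > 0", call. = FALSE)
  }
  if (spec$sampling_rate <= 1000) {
    stop("invalid emg_spec: `sampling_rate` must exceed 1000 Hz", call. = FALSE)
  }
  if (spec$target_mpf <= 5 || spec$target_mpf >= 500) {
    stop("invalid emg_spec: `target_mpf` must lie in (5, 500) Hz", call. = FALSE)
  }
  if (spec$rms_scale < 0) {
    stop("invalid emg_spec: `rms_scale` must be >= 0", call. = FALSE)
  }
  if (spec$onset_time < 0) {
    stop("invalid emg_spec: `onset_time` must be >= 0", call. = FALSE)
  }
  if (spec$peak_force <= 0) {
    stop("invalid emg_spec: `peak_force` must be > 0", call. = FALSE)
  }
  ramp <- 0.2
  if (spec$onset_time + ramp + spec$plateau_duration > spec$duration) {
    stop("invalid emg_spec: `onset_time` + ramp (0.2 s) + `plateau_duration` must fit inside `duration`",
         call. = FALSE)
  }
  invisible(spec)
}

# Solve the corner placement of a 4th-order Butterworth band-pass (fixed
# half-octave geometry f1 = c/r, f2 = c*r, r = 2) so that the spectral median
# of its white-noise-driven power response over [5, 500] Hz equals target Hz.
solve_emg_shaping <- function(target, fs, r = 2) {
  grid <- seq(0.5, fs / 2 - 0.5, by = 0.5)
  med_of <- function(centre) {
    f2 <- min(centre * r, 0.98 * fs / 2)
    f1 <- max(centre / r, 1)
    bf <- signal::butter(4, c(f1, f2) / (fs / 2), type = "pass")
    p <- Mod(freq_response(bf$b, bf$a, grid, fs))^2
    sel <- grid >= 5 & grid <= 500
    cumulative_median(grid[sel], p[sel])
  }
  lo <- max(7, target / 3)
  hi <- min(480, target * 3)
  centre <- stats::uniroot(function(c) med_of(c) - target, c(lo, hi),
                           tol = 1e-3)$root
  f2 <- min(centre * r, 0.98 * fs / 2)
  f1 <- max(centre / r, 1)
  signal::butter(4, c(f1, f2) / (fs / 2), type = "pass")
}

# Complex frequency response of a rational digital filter at frequencies f
# (Hz) for sampling rate fs.
freq_response <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- outer(z, seq_along(b) - 1, `^`) %*% b
  den <- outer(z, seq_along(a) - 1, `^`) %*% a
  as.vector(num / den)
}

# Median of a sampled non-negative density by linear interpolation of the
# cumulative trapezoid.
cumulative_median <- function(f, p) {
  seg <- (p[-1] + p[-length(p)]) / 2 * diff(f)
  cum <- c(0, cumsum(seg))
  half <- cum[length(cum)] / 2
  if (half <= 0) stop("zero total power", call. = FALSE)
  i <- which(cum >= half)[1]
  if (i == 1L) return(f[1])
  f[i - 1] + (half - cum[i - 1]) / (cum[i] - cum[i - 1]) * (f[i] - f[i - 1])
}

#' Generate a synthetic MVC EMG + force trial
#'
#' The EMG channel is Gaussian noise shaped by a 4th-order Butterworth
#' band-pass whose corner frequencies are solved numerically so the envelope's
#' spectral median equals `target_mpf`; the amplitude envelope is near zero
#' before onset, ramps up over 0.2 s with the force, and is scaled so the
#' plateau-section RMS equals `rms_scale` exactly. The force channel is zero
#' until `onset_time`, ramps linearly over 0.2 s to `peak_force`, holds for
#' `plateau_duration`, then decays over 0.3 s.
#'
#' @param spec an [emg_spec()].
#' @param trial_id,session_tag passed through to [emg_trial()].
#' @return an [emg_trial()] carrying `spec` as its `ground_truth`.
#' @export
make_emg_trial <- function(spec, trial_id = "trial",
                           session_tag = NA_character_) {
  validate_emg_spec(spec)
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  ramp <- 0.2
  decay <- 0.3
  t_on <- spec$onset_time
  t_plat0 <- t_on + ramp
  t_plat1 <- t_plat0 + spec$plateau_duration

  force <- numeric(n)
  force[tt >= t_on & tt < t_plat0] <-
    spec$peak_force * (tt[tt >= t_on & tt < t_plat0] - t_on) / ramp
  force[tt >= t_plat0 & tt < t_plat1] <- spec$peak_force
  dec <- tt >= t_plat1 & tt < t_plat1 + decay
  force[dec] <- spec$peak_force * (1 - (tt[dec] - t_plat1) / decay)

  env <- rep(0.01, n)                       # resting baseline, ~1% of MVC
  env[tt >= t_on & tt < t_plat0] <-
    0.01 + 0.99 * (tt[tt >= t_on & tt < t_plat0] - t_on) / ramp
  env[tt >= t_plat0 & tt < t_plat1] <- 1
  env[dec] <- 0.01 + 0.99 * (1 - (tt[dec] - t_plat1) / decay)

  shaping <- solve_emg_shaping(spec$target_mpf, fs)
  emg <- with_seed(spec$seed, {
    as.numeric(signal::filter(shaping, stats::rnorm(n)))
  }) * env
  plat <- tt >= t_plat0 & tt < t_plat1
  emg <- emg * (spec$rms_scale / sqrt(mean(emg[plat]^2)))

  emg_trial(emg, force, fs, trial_id = trial_id, session_tag = session_tag,
            ground_truth = spec)
}
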