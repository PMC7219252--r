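#!/usr/bin/env Rscript
# Simulates the synthetic rehabilitation study analyzed by the rest of the
# workflow: 5 subjects x 3 protocols (CMT, ACMT, SCMT) x 2 sessions. Each
# session has pre/post resting EEG (3 min at 256 Hz, Cz/C3/C4, blink/
# muscle-burst/movement artifacts injected), a clean 1-min calibration
# baseline, and 3 before/after MVC EMG + force trials at 2 kHz.
#
# Planted ground truth: the synchronous protocol (SCMT) suppresses mu-band
# power to 0.78 of its pre-session value and shifts the EMG toward fatigue
# (median frequency x0.9, RMS x1.1); CMT and ACMT have no effect. Subject
# count and recording lengths are scaled down from a full 7 x 4-session,
# 6-min-EEG design to keep the workflow quick to rerun; the planted effects
# and all pipeline parameters are unchanged.
#
# Output: scratch/study/ (EDF + CSV + ground_truth.json).

library(musupp)

seed <- 20260926L
spec <- study_spec(
  subjects = 5,
  protocols = list(CMT = list(), ACMT = list(),
                   SCMT = list(mu_factor = 0.78, mpf_factor = 0.9,
                               rms_factor = 1.1)),
  sessions = 2,
  eeg_duration = 180,
  baseline_duration = 60,
  emg_trials = 3,
  eeg = list(band_amplitudes = c(theta = 3, mu = 8, beta = 2.5, gamma = 1),
             background_scale = 2))

message("simulating study into scratch/study (seed ", seed, ") ...")
t0 <- Sys.time()
layout <- simulate_study(spec, "scratch/study", seed = seed)
n_eeg <- 5 * 3 * 2 * 3   # pre + post + baseline per session
n_emg <- 5 * 3 * 2 * 2 * 3
message(sprintf("wrote %d EEG recordings and %d EMG/force trial pairs in %.1f s",
                n_eeg, n_emg, as.numeric(Sys.time() - t0, units = "secs")))
message("ground truth sidecar: scratch/study/ground_truth.json")
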