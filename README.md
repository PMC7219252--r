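# musupp

Quantifying EEG mu-rhythm suppression and surface-EMG muscle fatigue in
before/after rehabilitation designs.

The mu rhythm is an 8–13 Hz oscillation of the sensorimotor cortex whose
suppression (power decrease) indexes sensorimotor activation; it is the
standard electrophysiological readout for mirror-therapy and robot-assisted
rehabilitation protocols. `musupp` implements the complete measurement chain
for resting-state recordings on Cz/C3/C4 — artifact cleaning, band-power
spectral statistics, and a paired statistical layer — together with the
companion muscle-fatigue analysis of maximum-voluntary-contraction (MVC)
surface EMG. Because such studies rarely release raw recordings, the package
also ships synthetic EEG/EMG generators with known ground truth, so every
stage is verifiable by parameter recovery: plant an effect, run the full
pipeline, and check that it comes back out.

It is aimed at biomedical-signal-processing researchers who need a tested,
scriptable reimplementation of this analysis rather than a GUI toolbox.

## The analysis

**EEG chain** (256 Hz, channels Cz/C3/C4, µV): the first and last minute of
each resting recording are discarded; a zero-phase Hamming windowed-sinc FIR
high-pass at 1 Hz removes drift; artifact subspace reconstruction (ASR),
calibrated on a separate 1-min clean baseline via the geometric median of
sliding-window covariances, removes high-amplitude blink / muscle-burst /
movement artifacts using 250 ms windows and a 5 SD component threshold,
without channel rejection; the signal is cut into 2-s epochs and epochs are
rejected by peak-to-peak amplitude (< 30 or > 3000 µV) or by sample kurtosis
more than 5 SD above the across-epoch mean. Surviving epochs give an
epoch-averaged Hamming periodogram (Welch) PSD, integrated over the
contiguous partition θ [4,8), µ [8,14), β [14,31), γ [31,50] Hz.

The statistics are band-power ratios:

    relative PSD        = PSD_mu / PSD_total                  (per electrode)
    session ratio       = value_after / value_before          (per session)
    treatment change %  = (ratio_last / ratio_first − 1) × 100

reported per electrode for the relative mu share and the absolute θ/µ/β/γ
powers.

**EMG chain** (2 kHz, biceps MVC trials with a load-cell force channel): a
60 Hz notch plus a 5–500 Hz 4th-order Butterworth band-pass, both applied
forward–backward (zero phase); contraction onset is the first sample at
which force reaches 10% of its peak; the 6.5 s of EMG from onset give the
median power frequency (MPF, the frequency splitting the 5–500 Hz spectrum
into equal-power halves) and the RMS amplitude. Muscle fatigue appears as
MPF ↓ and RMS ↑. Per measurement, the five MVC trials are averaged and
after/before ratios formed as above.

**Statistical layer**: Shapiro–Wilk normality check; paired t-test for
relative-PSD comparisons; Wilcoxon signed-rank test for absolute-PSD and
MPF/RMS comparisons, exact (full sign-assignment enumeration, midranked
ties, zeros dropped) up to n = 25; α = 0.05.

## Worked example

Plant a 40% mu-power suppression (factor 0.6) in a matched pair of 6-min
synthetic recordings, then recover it with the full pipeline:

```r
library(musupp)

spec <- eeg_spec(duration = 360,
                 band_amplitudes = c(theta = 3, mu = 8, beta = 2.5, gamma = 1),
                 background_scale = 2, seed = 1)
pair <- make_eeg_pair(spec, mu_power_factor = 0.6, seed = 42)

baseline <- highpass_fir(make_eeg(eeg_spec(duration = 60,
                 band_amplitudes = c(theta = 3, mu = 8, beta = 2.5, gamma = 1),
                 background_scale = 2, seed = 7)))
model <- asr_calibrate(baseline)

analyze <- function(rec) {
  rec <- asr_clean(highpass_fir(trim_edges(rec, 60)), model)
  band_powers(welch_psd(reject_epochs(epoch_recording(rec, 2))))
}
before <- analyze(pair$before)
after  <- analyze(pair$after)

session_ratio(before, after, "absolute_mu", "Cz")
#> <session_ratio> absolute_mu @Cz: 64.15 -> 39.13, ratio 0.6100 (-39.00%)
session_ratio(before, after, "relative_mu", "Cz")
#> <session_ratio> relative_mu @Cz: 0.787 -> 0.6916, ratio 0.8787 (-12.13%)
```

The absolute mu ratio recovers the planted 0.6 to within about 0.01. The
relative ratio is smaller in magnitude because suppressing mu also shrinks
the total-band denominator — exactly the algebra `relative_ratio =
f / (f·r + (1 − r))` for a before-mu-share `r` (here 0.79).

On the EMG side:

```r
trial <- make_emg_trial(emg_spec(target_mpf = 120, rms_scale = 200, seed = 1))
unlist(fatigue_indices(trial)[c("mpf", "rms", "onset_sample")])
#>          mpf          rms onset_sample
#>     119.2449     193.8980    1041.0000
```

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
analysis; each is a thin script over the package functions and writes its
tables under `results/`:

| script | does | writes |
|---|---|---|
| `01_simulate_study.R` | simulates a 5-subject × 3-protocol × 2-session study (EDF + CSV) with a planted synchronous-protocol effect | `scratch/study/` |
| `02_run_pipeline.R` | runs the full EEG + EMG chain and the statistical layer over it | `results/study/` |
| `03_mu_recovery.R` | planted-mu-factor recovery grid {0.4, 0.6, 0.8, 1.0} through the full pipeline | `results/mu_recovery.csv` |
| `04_emg_fatigue.R` | planted MPF/RMS fatigue-shift recovery grid | `results/emg_fatigue.csv` |

`run_study()` / `simulate_study()` expose the same orchestration
programmatically, and `load_config()` reads all pipeline parameters from a
YAML file.

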