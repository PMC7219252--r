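---
title: "Methods: mu-rhythm suppression and EMG fatigue quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mu-rhythm suppression and EMG fatigue quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(musupp)
```

This vignette documents the models, parameter choices and numerical
decisions behind `musupp`, in the spirit of a methods section: what each
stage assumes, which knobs exist and why their defaults are what they are,
and what the synthetic-data tests do and do not demonstrate about real
recordings.

## The measurement model

A resting-state EEG recording on Cz/C3/C4 is modelled as band-limited
oscillatory activity (theta, mu, beta, gamma) superimposed on a broadband
1/f background, contaminated by occasional high-amplitude artifacts
(blinks, muscle bursts, movement). The quantity of interest is the mu-band
(8–13 Hz) power and its share of the total 4–50 Hz power,

\[
\text{relative PSD} = \frac{\mathrm{PSD}_\mu}{\mathrm{PSD}_{\mathrm{total}}},
\qquad
\text{ratio} = \frac{\text{after}}{\text{before}},
\qquad
\text{change} = (\text{ratio} - 1)\times 100\,\%.
\]

Relative PSD reduces inter-subject variance caused by skull/scalp
conductivity differences, but is confounded whenever a *different* band
changes (it shares the denominator); both relative and absolute band powers
are therefore reported. For a single-band power change by factor \(f\) with
before-share \(r\), the relative ratio follows algebraically as
\(f / (f r + 1 - r)\); the end-to-end tests check the pipeline against this
prediction.

Muscle fatigue in MVC surface EMG appears as a downward shift of the power
spectrum — a lower median power frequency (MPF) — together with a higher
RMS amplitude. Both are computed on the 6.5 s of EMG following contraction
onset, detected as the first sample at which the load-cell force reaches
10% of its peak, and aggregated over the repeated MVC trials of a
measurement by their arithmetic mean.

## The EEG cleaning chain and its parameters

Order of operations: trim → high-pass → ASR → epoch → reject. The trim
(default `eeg.trim_s = 60` s per side) removes the settling-in/wrap-up
periods where attention-driven posterior alpha is most likely to
contaminate the mu band. ASR is calibrated on a separately supplied clean
baseline, which is high-passed the same way.

**High-pass** (`eeg.highpass_hz = 1`): Hamming windowed-sinc FIR, built as
delta-minus-low-pass so the DC gain is exactly zero, transition bandwidth
`min(max(cutoff/4, 2), cutoff)` Hz, even order `3.3 / (tbw/fs)` (~846 taps
at 256 Hz). It is applied once with full group-delay compensation (edges
handled by reflection), not forward–backward: the net phase is zero either
way, but single application keeps the designed magnitude response rather
than its square.

**ASR** (`eeg.asr.window_s = 0.25`, `cutoff_sd = 5`, `overlap = 0.5`):
calibration computes per-window sample covariances (64-sample windows at
256 Hz), takes their geometric median by Weiszfeld iteration (relative
tolerance 1e-8, at most 500 iterations, mean initialisation; a coincident
point is regularised by a 1e-12 floor on distances), and uses its principal
square root as the mixing matrix. Baseline windows projected onto the
covariance eigenbasis (eigenvalues sorted ascending) give per-component RMS
amplitudes; the ceiling for component \(i\) is
\(\mu_i + \text{cutoff}\,\sigma_i\). Cleaning eigendecomposes each sliding
window's covariance, maps the calibration ceilings into the window basis as
\(\tau_j^2 = \sum_i t_i^2 (v_i \cdot u_j)^2\), flags components whose
variance exceeds their ceiling, and reconstructs the flagged subspace from
the retained one by least squares through the mixing matrix. When nothing
is flagged this reconstruction is exactly the identity; when everything is
flagged the window reconstructs to zero (degenerate-case totality).
Overlapping windows are blended with a strictly positive raised-cosine
cross-fade, so every sample has nonzero total weight. Channel count and
length are never altered. A rank-deficient calibration covariance (e.g. a
duplicated channel) is refused with advice rather than regularised
silently.

**Epoching and rejection** (`eeg.epoch_s = 2`, `reject.p2p_min_uV = 30`,
`p2p_max_uV = 3000`, `kurtosis_z = 5`): 2-s non-overlapping epochs give
0.5 Hz resolution, adequate for 4–50 Hz band integrals, and enough epochs
(120 per analyzed 4 min) for stable kurtosis statistics. The amplitude
bounds are read as per-epoch, per-channel *peak-to-peak* limits: above
3000 µV is a gross artifact; below 30 µV is a flat or disconnected channel.
An instantaneous-magnitude reading of the lower bound would reject every
zero-crossing sample, so peak-to-peak is the only interpretation under
which both bounds are simultaneously meaningful; this is a documented
reading, not a claim about what any particular lab intended. The kurtosis
rule is a one-sided per-channel z-score of epoch sample kurtosis across
epochs. Two caveats are inherent to z-scoring: at least 8 epochs are
required (enforced), and a single epoch among \(n\) can reach at most
\(z = (n-1)/\sqrt{n}\), so with fewer than ~27 epochs no single epoch can
exceed \(z = 5\); gross epochs are in practice caught first by the
peak-to-peak ceiling. Rejection is a pure filter: surviving epochs are
bit-identical to their inputs.

The 60 Hz line component is assumed to have been removed by acquisition
hardware; no digital notch is applied to EEG.

## Spectral estimation

The PSD estimator is the epoch-averaged Hamming periodogram (Welch with the
window spanning the full epoch — epoching already exists for rejection, so
no further segmentation is introduced). Densities are one-sided and
window-power corrected (\(U = \sum w^2\)), so the integral over frequency
equals the mean signal power. Band powers are trapezoidal integrals of the
density; adjacent bands share boundaries, so the four band powers sum to
the total-band power *exactly* and the four relative shares sum to one.

The printed integer band conventions (4–7, 8–13, 14–30, 31–50 Hz) leave
1 Hz gaps on a continuous axis; the package uses the contiguous partition
θ [4,8), µ [8,14), β [14,31), γ [31,50], which preserves every conventional
lower edge, orphans no frequency bin, and makes the normalisation identity
possible.

## EMG processing

The notch is an RBJ biquad at 60 Hz with quality factor 30 — narrow enough
to spare genuine 55–65 Hz EMG content; the band-pass is a 4th-order
Butterworth at 5–500 Hz. Both run forward–backward, so onset-aligned
segment timing is not skewed by group delay. Onset is the first sample at
or above 10% of peak force, with no sub-sample interpolation: at 2 kHz the
worst-case half-millisecond bias is negligible against a 6.5-s analysis
window. MPF uses Welch with 1-s Hamming windows at 50% overlap (1 Hz
resolution, ~12 averages over 6.5 s) and linear interpolation of the
cumulative power at the half-total crossing over 5–500 Hz. Whether a lab
computes its "power spectrum" as one long periodogram or an average of
sub-windows is usually unstated; the Welch choice is a documented decision
favouring variance reduction.

## The statistical layer

The fixed test assignment — paired t for relative-PSD comparisons, Wilcoxon
signed-rank for absolute-PSD and MPF/RMS — mirrors common practice for this
design (`stats.policy = "paper_fixed"`); a `"normality_gated"` policy that
picks the test by a Shapiro–Wilk check on the differences is also provided.
The Wilcoxon implementation drops zero differences (the classical method,
matching exact tables), midranks ties, and for effective n ≤ 25 computes
the exact two-sided p over the null distribution of all \(2^n\) sign
assignments via a generating-function convolution over doubled midranks —
mathematically identical to full enumeration, polynomial in cost. The
two-sided p is twice the smaller tail, capped at one. Above n = 25 a normal
approximation with tie and continuity corrections is used. With typical
cohort sizes (n ≈ 7) the exact branch always runs. No multiple-testing
correction is applied across electrodes and bands, matching the
per-comparison α = 0.05 convention of this literature; this is a
reproduction choice, not an endorsement.

## What the synthetic generators emulate — and what they do not

`make_eeg()` synthesizes each band as a bank of equal-amplitude sinusoids
with random phases, about one tone per 0.5 Hz of bandwidth, rescaled so the
band's time-domain RMS is exact; the background is Gaussian noise shaped to
\(1/f^\alpha\) (α = 1 by default, flattened below 1 Hz) with an exact total
RMS. Tone *placement* is the delicate part. Epoch-averaged spectral
estimates converge only if every two-tone beat decorrelates across epochs,
so frequencies are stratified-jittered under two constraints: all pairwise
spacings are ≥ 0.1 Hz (no beat slower than ~10 s, hence band power is
stationary over trimmed analysis windows), and spacings are bounded away
from exactly one and two 0.5 Hz analysis bins — under a full-epoch Hamming
window only 1- and 2-bin pairs have nonzero cross terms, and a
grid-resonant spacing would repeat the same beat phase in every epoch
instead of averaging out. Tones also keep a 1 Hz guard from band edges,
because an edge tone leaks ~13% of its power into each adjacent bin.
Without these constraints, planted-factor recovery errors of 0.05–0.6 in
the after/before ratio occur at 4-min durations; with them the tests
observe errors around 0.01–0.02.

Artifacts are additive fixed shapes (Gaussian-derivative biphasic blink,
20–100 Hz tapered noise burst, raised-cosine drift) with exact sample
masks. `make_emg_trial()` shapes Gaussian noise with a 4th-order
Butterworth band-pass whose corners are solved numerically (fixed
two-octave geometry, `uniroot` on the spectrum median) so the envelope's
spectral median equals the requested MPF, with a ramp-and-plateau force
channel and exact plateau RMS.

These generators make every stage testable by parameter recovery, but they
are not biophysical models: there is no volume conduction or channel
correlation structure (synthetic channels are independent, so ASR's
cross-channel reconstruction is exercised only weakly), no event-related
dynamics, no motor-unit structure in the EMG, and artifacts are stylised
templates. Passing recovery tests therefore demonstrates the correctness of
the *computational chain*, not robustness to every pathology of real
scalp/surface recordings.

Two fixture choices deserve explicit statement. First, the recovery tests
use mu-dominant spectra (mu RMS 8 µV against a 2 µV background): the
absolute-ratio ground truth equals the planted factor \(f\) only when the
mu band is dominated by the planted component, since an unchanged floor
with band-share \(b\) biases the measured ratio to
\((f P_\mu + P_b)/(P_\mu + P_b)\). With the chosen fixture this bias is
below 0.01; with a strong floor it would be a property of the *question*,
not a pipeline defect. Second, the simulated studies in `analysis/` are
scaled down (5 subjects, 2 sessions, 3-min recordings trimmed to 2 analyzed
minutes, 3 MVC trials) from the full 7 × 4 × 6-min design; the planted
effects and all pipeline parameters are unchanged, and the acceptance
script's end-to-end recovery runs at the full 4-analyzed-minutes recording
length.

## Degenerate inputs and tie-breaks

Validation errors name the offending field. Notable hard cases: a recording
too short to trim or epoch, an ASR window longer than the recording, all
epochs rejected ("no contamination-free signal"), a before-value of zero in
any ratio, zero-variance differences in the paired t, all-zero differences
in the Wilcoxon test, an all-zero force channel in onset detection, and
zero total power in the MPF. The EDF writer refuses (rather than clips)
samples outside the physical range, and uses a symmetric digital range
(−32767..32767) so 0 µV round-trips exactly; recordings must contain a
whole number of 1-s data records.

## Known limitations

- EDF support is minimal: 16-bit EDF with a uniform sampling rate across
  signals; no EDF+ annotations or vendor formats.
- The treatment-level aggregation reports per-subject session ratios, their
  group means, and last-vs-first treatment changes; cross-study aggregation
  conventions vary, and any published group table built with an unspecified
  aggregation may not be reproducible cell-for-cell from ratios alone.
- ASR here is the windowed-PCA variant described above; it is not a
  re-implementation of any specific toolbox's internals, and calibration
  thresholds are per-component RMS statistics rather than a full threshold
  matrix fit.
- The statistical layer tests each electrode/band at α = 0.05 without
  multiplicity correction (a Holm-style correction can be applied to the
  reported p-values downstream if desired).
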