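# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own code paths: plain-R DTFT evaluation, direct
# projection amplitude estimation, and literal 2^n enumeration for the
# signed-rank null.

# |H(f)| of an FIR filter by direct DTFT evaluation.
fir_gain <- function(h, f, fs) {
  vapply(f, function(ff) {
    Mod(sum(h * exp(-1i * 2 * pi * ff * (seq_along(h) - 1) / fs)))
  }, numeric(1))
}

# |H(f)| of a rational IIR filter by direct evaluation of the transfer
# function.
iir_gain <- function(b, a, f, fs) {
  vapply(f, function(ff) {
    z <- exp(-1i * 2 * pi * ff / fs)
    Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
  }, numeric(1))
}

# Amplitude of the f-Hz component of x by complex projection.
tone_amplitude <- function(x, f, fs) {
  tt <- (seq_along(x) - 1) / fs
  2 * Mod(mean(x * exp(-1i * 2 * pi * f * tt)))
}

# Two-sided exact signed-rank p-value by literal enumeration of all 2^n sign
# assignments (n <= ~15). Zeros dropped, ties midranked.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(W_all >= W - 1e-9), mean(W_all <= W + 1e-9)))
}

# Band power of a raw signal by direct rectangular-window periodogram
# integration over [lo, hi] Hz (no epoching, no Hamming window).
direct_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / (fs * n)
  n_half <- n %/% 2
  p <- p[1:(n_half + 1)]
  dbl <- 2:(n_half + if (n %% 2 == 0) 0 else 1)
  p[dbl] <- 2 * p[dbl]
  f <- (0:n_half) * fs / n
  sel <- f >= lo & f <= hi
  sum(p[sel]) * fs / n
}

# A small clean mu-dominant EEG spec used by several tests.
clean_eeg_spec <- function(duration, seed, background = 2, mu = 8) {
  eeg_spec(duration = duration,
           band_amplitudes = c(theta = 3, mu = mu, beta = 2.5, gamma = 1),
           background_scale = background, seed = seed)
}
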