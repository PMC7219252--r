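#' Frequency-band scheme
#'
#' The analysis partition of the 4-50 Hz range into theta, mu, beta and gamma.
#' The printed integer ranges of the convention (theta 4-7, mu 8-13, beta
#' 14-30, gamma 31-50 Hz) leave gaps on a continuous frequency axis, so the
#' default is the contiguous half-open partition theta [4,8), mu [8,14), beta
#' [14,31), gamma [31,50]: every conventional lower edge is preserved, no bin
#' is orphaned, and relative powers sum to one.
#'
#' @param bands named list of `[low, high]` pairs in Hz; must be contiguous
#'   and non-overlapping.
#' @return an object of class `band_scheme` with elements `bands` (ordered by
#'   lower edge) and `total` (the union).
#' @export
band_scheme <- function(bands = list(theta = c(4, 8), mu = c(8, 14),
                                     beta = c(14, 31), gamma = c(31, 50))) {
  bands <- lapply(bands, as.numeric)
  ord <- order(vapply(bands, `[`, numeric(1), 1))
  bands <- bands[ord]
  lows <- vapply(bands, `[`, numeric(1), 1)
  highs <- vapply(bands, `[`, numeric(1), 2)
  if (any(highs <= lows)) {
    stop("each band must be an increasing [low, high] pair", call. = FALSE)
  }
  if (length(bands) > 1L && any(abs(highs[-length(highs)] - lows[-1]) > 1e-9)) {
    stop("bands must be contiguous and non-overlapping", call. = FALSE)
  }
  structure(list(bands = bands,
                 total = unname(c(lows[1], highs[length(highs)]))),
            class = "band_scheme")
}

#' Welch power spectral density of an epoch set
#'
#' Per-epoch Hamming-windowed periodograms (window spanning the full epoch)
#' averaged across surviving epochs. The one-sided density is window-power
#' corrected so that its integral over frequency equals the mean signal power.
#'
#' @param eset an `epoch_set` (see [epoch_recording()]); only epochs with
#'   `keep_mask` `TRUE` contribute.
#' @return an object of class `psd_result`: frequency grid (Hz), per-channel
#'   density matrix (uV^2/Hz), epochs used and resolution.
#' @export
welch_psd <- function(eset) {
  keep <- which(eset$keep_mask)
  if (!length(keep)) stop("no surviving epochs", call. = FALSE)
  len <- dim(eset$epochs)[3]
  fs <- eset$sampling_rate
  w <- signal::hamming(len)
  u <- sum(w^2)
  n_half <- len %/% 2L
  freqs <- (0:n_half) * fs / len
  nch <- dim(eset$epochs)[2]
  dens <- matrix(0, nrow = nch, ncol = n_half + 1L,
                 dimnames = list(eset$channel_labels, NULL))
  for (ci in seq_len(nch)) {
    X <- t(eset$epochs[keep, ci, , drop = FALSE][, 1, ]) * w  # len x n_epochs
    if (length(keep) == 1L) X <- matrix(eset$epochs[keep, ci, ] * w, ncol = 1L)
    P <- Mod(stats::mvfft(X))^2 / (fs * u)
    one <- P[1:(n_half + 1L), , drop = FALSE]
    dbl <- 2:(n_half + if (len %% 2L == 0L) 0L else 1L)
    one[dbl, ] <- 2 * one[dbl, ]
    dens[ci, ] <- rowMeans(one)
  }
  structure(list(frequencies = freqs, density = dens,
                 n_epochs_used = length(keep), resolution = fs / len,
                 channel_labels = eset$channel_labels),
            class = "psd_result")
}

# Trapezoidal integral of a linearly interpolated density over [a, b].
integrate_density <- function(f, p, a, b) {
  if (a < f[1] - 1e-9 || b > f[length(f)] + 1e-9) {
    stop(sprintf("PSD grid [%g, %g] Hz does not cover [%g, %g] Hz",
                 f[1], f[length(f)], a, b), call. = FALSE)
  }
  knots <- sort(unique(c(a, b, f[f > a & f < b])))
  vals <- stats::approx(f, p, xout = knots)$y
  sum((vals[-1] + vals[-length(vals)]) / 2 * diff(knots))
}

#' Absolute and relative band powers from a PSD
#'
#' Band power is the trapezoidal integral of the density over each band of the
#' scheme; adjacent bands share their boundary so the four powers sum exactly
#' to the total-band power. Relative PSD is each band's share of the total.
#'
#' @param psd a [welch_psd()] result whose grid covers the scheme's total band.
#' @param scheme a [band_scheme()].
#' @return an object of class `band_power_table`: per-channel `absolute`
#'   (uV^2) and `relative` matrices (channels x bands) plus the `total` power
#'   vector.
#' @export
band_powers <- function(psd, scheme = band_scheme()) {
  nch <- nrow(psd$density)
  bn <- names(scheme$bands)
  absolute <- matrix(0, nrow = nch, ncol = length(bn),
                     dimnames = list(psd$channel_labels, bn))
  for (ci in seq_len(nch)) {
    for (b in bn) {
      e <- scheme$bands[[b]]
      absolute[ci, b] <- integrate_density(psd$frequencies, psd$density[ci, ],
                                           e[1], e[2])
    }
  }
  total <- rowSums(absolute)
  structure(list(absolute = absolute, total = total,
                 relative = absolute / total,
                 channel_labels = psd$channel_labels, scheme = scheme),
            class = "band_power_table")
}

session_metrics <- c("relative_mu", "absolute_theta", "absolute_mu",
                     "absolute_beta", "absolute_gamma", "mpf", "rms")

#' After/before session ratio for one spectral metric
#'
#' The before/after comparison of one electrode's band statistic: relative-PSD
#' ratio or absolute-PSD ratio, reported as `ratio = after / before` with its
#' percent-change rendering `(ratio - 1) * 100`.
#'
#' @param before,after [band_powers()] tables from the same channel set and
#'   scheme.
#' @param metric one of `"relative_mu"`, `"absolute_theta"`, `"absolute_mu"`,
#'   `"absolute_beta"`, `"absolute_gamma"`.
#' @param channel channel label present in both tables.
#' @return an object of class `session_ratio`.
#' @export
session_ratio <- function(before, after, metric, channel) {
  if (!metric %in% setdiff(session_metrics, c("mpf", "rms"))) {
    stop(sprintf("unknown spectral metric '%s'", metric), call. = FALSE)
  }
  if (!identical(before$channel_labels, after$channel_labels)) {
    stop("before/after tables have different channels", call. = FALSE)
  }
  pick <- function(tbl) {
    parts <- strsplit(metric, "_", fixed = TRUE)[[1]]
    m <- if (parts[1] == "relative") tbl$relative else tbl$absolute
    if (!channel %in% rownames(m)) {
      stop(sprintf("channel '%s' not in table", channel), call. = FALSE)
    }
    m[channel, parts[2]]
  }
  make_session_ratio(metric, pick(before), pick(after), channel)
}

make_session_ratio <- function(metric, before, after, channel = NA_character_) {
  if (before <= 0) {
    stop(sprintf("undefined ratio: before-value of %s is not positive", metric),
         call. = FALSE)
  }
  ratio <- after / before
  structure(list(metric = metric, channel = channel, before = before,
                 after = after, ratio = ratio,
                 percent_change = (ratio - 1) * 100),
            class = "session_ratio")
}

#' @export
print.session_ratio <- function(x, ...) {
  cat(sprintf("<session_ratio> %s%s: %.4g -> %.4g, ratio %.4f (%+.2f%%)\n",
              x$metric, if (is.na(x$channel)) "" else paste0(" @", x$channel),
              x$before, x$after, x$ratio, x$percent_change))
  invisible(x)
}

#' Percent change across a treatment (last vs first session)
#'
#' Given the session ratios of the first and last sessions of a treatment,
#' returns `(last_ratio / first_ratio - 1) * 100`.
#'
#' @param first,last [session_ratio()] objects for the same metric and channel.
#' @return percent change, a single number.
#' @export
treatment_change <- function(first, last) {
  if (!identical(first$metric, last$metric)) {
    stop(sprintf("metric mismatch: '%s' vs '%s'", first$metric, last$metric),
         call. = FALSE)
  }
  if (!identical(is.na(first$channel), is.na(last$channel)) ||
      (!is.na(first$channel) && first$channel != last$channel)) {
    stop("channel mismatch between session ratios", call. = FALSE)
  }
  (last$ratio / first$ratio - 1) * 100
}
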